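#' Pipeline configuration
#'
#' Collects file paths, unit declarations, and stage options for
#' [run_pipeline()]. Unknown options are rejected (the argument list is the
#' schema), and the full configuration is serialized into the results
#' manifest together with its hash, so a results directory is traceable to
#' the exact settings that produced it.
#'
#' @param dir Directory holding the input CSVs (as written by
#'   [write_trial_csvs()]); individual paths may be overridden.
#' @param retention,conductivity,texture,aggregates,bulk,chemistry Paths to
#'   the input tables; `conductivity` and `chemistry` may be `NA` (stages
#'   depending on them are skipped).
#' @param head_units Units of the head columns: `"cm"` (default) or
#'   `"hPa"` (converted on read, 1 hPa = 1.0197162 cm of water).
#' @param r_min,r_max Structure-index integration bounds, um.
#' @param packing_factor Pore-to-particle radius ratio of the reference
#'   soil; default 0.3.
#' @param theta_s_ref Reference-soil saturated water content; default 0.30.
#' @param dilution_mode `"printed"` or `"exact"`, see [dilution_correct()].
#' @param amendment_bulk_density Bulk density feeding the rock mass balance:
#'   `"profile_mean"` (mean of the bulk-density table) or a number, g/cm^3.
#' @param particle_density Particle density for porosity, g/cm^3.
#' @param n_starts,seed Multistart settings for all curve fits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir = NULL,
                            retention = file.path(dir, "retention.csv"),
                            conductivity = file.path(dir, "conductivity.csv"),
                            texture = file.path(dir, "texture.csv"),
                            aggregates = file.path(dir, "aggregates.csv"),
                            bulk = file.path(dir, "bulk.csv"),
                            chemistry = file.path(dir, "chemistry.csv"),
                            head_units = c("cm", "hPa"),
                            r_min = 0.1, r_max = 1490,
                            packing_factor = 0.3, theta_s_ref = 0.30,
                            dilution_mode = c("printed", "exact"),
                            amendment_bulk_density = "profile_mean",
                            particle_density = 2.65,
                            n_starts = 12L, seed = 42L) {
  head_units <- match.arg(head_units)
  dilution_mode <- match.arg(dilution_mode)
  structure(list(paths = list(retention = retention,
                              conductivity = conductivity,
                              texture = texture, aggregates = aggregates,
                              bulk = bulk, chemistry = chemistry),
                 head_units = head_units, r_min = r_min, r_max = r_max,
                 packing_factor = packing_factor, theta_s_ref = theta_s_ref,
                 dilution_mode = dilution_mode,
                 amendment_bulk_density = amendment_bulk_density,
                 particle_density = particle_density,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "pipeline_config")
}

HPA_TO_CM <- 100 / 98.0665  # cm of water per hPa

#' Write a simulated trial bundle to CSV files
#'
#' Serializes every table of a [simulate_trial()] bundle into `dir` using
#' the pipeline's CSV dialect (comma separator, dot decimal, UTF-8, header
#' row). The truth manifest is written as `truth.csv` for recovery tests.
#'
#' @param bundle A `trial_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_csvs <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trial_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("retention", "conductivity", "texture", "aggregates",
               "bulk", "chemistry", "truth"))
    if (!is.null(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}

read_checked_csv <- function(path, required, what, issues) {
  if (!file.exists(path)) {
    issues$add(sprintf("%s: file not found: %s", what, path))
    return(NULL)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    issues$add(sprintf("%s (%s): missing column(s) %s", what, path,
                       paste(missing, collapse = ", ")))
    return(NULL)
  }
  df
}

issue_collector <- function() {
  msgs <- character()
  list(add = function(m) msgs <<- c(msgs, m),
       any = function() length(msgs) > 0L,
       report = function() paste(msgs, collapse = "\n  "))
}

#' Read and validate the pipeline input tables
#'
#' Reads every configured CSV, checks schemas row-wise (positive heads,
#' water contents in range, non-negative masses, no duplicated keys),
#' normalizes head units to cm of water, and fails with a single
#' consolidated report listing every problem found.
#'
#' @param config A [pipeline_config()].
#' @return A validated input bundle (list of data frames).
#' @export
read_tables <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  iss <- issue_collector()
  p <- config$paths

  ret <- read_checked_csv(p$retention, c("sample_id", "h_cm", "theta"),
                          "retention", iss)
  if (!is.null(ret)) {
    if (config$head_units == "hPa") ret$h_cm <- ret$h_cm * HPA_TO_CM
    bad <- which(!is.finite(ret$h_cm) | ret$h_cm <= 0)
    if (length(bad)) iss$add(sprintf("retention: non-positive head at row(s) %s",
                                     paste(utils::head(bad, 5L), collapse = ", ")))
    bad <- which(ret$theta < 0 | ret$theta > 1)
    if (length(bad)) iss$add(sprintf("retention: theta outside [0,1] at row(s) %s",
                                     paste(utils::head(bad, 5L), collapse = ", ")))
  }

  cond <- NULL
  if (!is.na(p$conductivity) && file.exists(p$conductivity)) {
    cond <- read_checked_csv(p$conductivity,
                             c("sample_id", "h_cm", "K_cm_per_d"),
                             "conductivity", iss)
    if (!is.null(cond) && config$head_units == "hPa")
      cond$h_cm <- cond$h_cm * HPA_TO_CM
    if (!is.null(cond) && any(cond$K_cm_per_d <= 0))
      iss$add("conductivity: non-positive K values")
  }

  tex <- read_checked_csv(p$texture,
                          c("sample_id", "sand", "silt", "clay"),
                          "texture", iss)
  agg <- read_checked_csv(p$aggregates,
                          c("sample_id", "depth", "treatment", "replicate",
                            "class_label", "fraction_mass_g", "sand_mass_g",
                            "oc_mg_per_g"),
                          "aggregates", iss)
  if (!is.null(agg)) {
    if (any(agg$fraction_mass_g < 0) || any(agg$sand_mass_g < 0))
      iss$add("aggregates: negative masses")
    key <- paste(agg$sample_id, agg$replicate, agg$class_label)
    if (anyDuplicated(key))
      iss$add(sprintf("aggregates: duplicated sample/replicate/class row(s): %s",
                      paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
                            collapse = "; ")))
  }
  blk <- read_checked_csv(p$bulk,
                          c("sample_id", "bulk_oc_mg_per_g",
                            "bulk_density_g_cm3"),
                          "bulk", iss)
  if (!is.null(blk) && anyDuplicated(blk$sample_id))
    iss$add(sprintf("bulk: duplicated sample_id(s): %s",
                    paste(unique(blk$sample_id[duplicated(blk$sample_id)]),
                          collapse = ", ")))
  chem <- NULL
  if (!is.na(p$chemistry) && file.exists(p$chemistry))
    chem <- utils::read.csv(p$chemistry, stringsAsFactors = FALSE)

  if (iss$any())
    stop("input validation failed:\n  ", iss$report(), call. = FALSE)
  list(retention = ret, conductivity = cond, texture = tex,
       aggregates = agg, bulk = blk, chemistry = chem)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Chains every stage over a validated input bundle: per-sample bimodal
#' Kosugi fits (retention plus conductivity where available), water points
#' from the fitted curves and bulk densities, structured and
#' texture-referenced pore-size distributions and the KL structure index,
#' aggregate summaries (sand-corrected fractions, OC contributions, E_OC),
#' the rock dilution mass balance, texture classification, and group
#' statistics. Results are written to `out_dir` as CSV/JSON together with a
#' manifest (package version, seed, configuration and its hash). Re-running
#' with identical inputs and configuration is deterministic. On stage
#' failure, partially written outputs are removed and the error names the
#' stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param schedule An [amendment_schedule()] for the dilution stage;
#'   default [energy_farm_schedule()] (bulk density replaced per
#'   `config$amendment_bulk_density`).
#' @return Invisibly, a list of the result tables.
#' @export
run_pipeline <- function(config, out_dir,
                         schedule = energy_farm_schedule()) {
  inputs <- run_stage("read", read_tables(config))
  fit_cfg <- fit_config(n_starts = config$n_starts, seed = config$seed)

  samples <- unique(inputs$retention$sample_id)
  fits <- list(); fit_rows <- NULL; kld_rows <- NULL; wp_rows <- NULL
  run_stage("hydraulics", for (sid in samples) {
    r <- inputs$retention[inputs$retention$sample_id == sid, ]
    cd <- NULL
    if (!is.null(inputs$conductivity)) {
      ck <- inputs$conductivity[inputs$conductivity$sample_id == sid, ]
      if (nrow(ck) > 0L) cd <- conductivity_data(ck$h_cm, ck$K_cm_per_d)
    }
    f <- fit_kosugi_bimodal(retention_data(r$h_cm, r$theta), cd, fit_cfg)
    fits[[sid]] <- f
    pp <- f$params
    fit_rows <- rbind(fit_rows, data.frame(
      sample_id = sid, treatment = r$treatment[1], depth = r$depth[1],
      theta_r = pp$theta_r, theta_s = pp$theta_s, w = pp$w,
      hm1_cm = pp$hm1, sigma1 = pp$sigma1, hm2_cm = pp$hm2,
      sigma2 = pp$sigma2, Ks_cm_per_d = pp$Ks, tau = pp$tau,
      rmse_theta = f$rmse_theta, rmse_logK = f$rmse_logK,
      converged = f$converged))
  })

  run_stage("water_points", for (sid in samples) {
    bd <- inputs$bulk$bulk_density_g_cm3[inputs$bulk$sample_id == sid]
    if (length(bd) != 1L) stop("no unique bulk density for sample ", sid)
    wp <- water_points(fits[[sid]]$params, bd,
                       particle_density = config$particle_density)
    wp_rows <- rbind(wp_rows, data.frame(
      sample_id = sid, Fc_vol_pct = wp$Fc, PWP_vol_pct = wp$PWP,
      Wa_vol_pct = wp$Wa, porosity = wp$phi))
  })

  run_stage("structure_index", for (sid in samples) {
    tx <- inputs$texture[inputs$texture$sample_id == sid, ]
    if (nrow(tx) != 1L) stop("no unique texture row for sample ", sid)
    pars <- fits[[sid]]$params
    p <- psd_from_retention(pars, config$r_min, config$r_max)
    spec <- reference_soil_spec(
      texture_to_cumulative(tx$sand, tx$silt, tx$clay),
      theta_r_fixed = pars$theta_r, theta_s_ref = config$theta_s_ref,
      packing_factor = config$packing_factor)
    q <- reference_psd(spec, config$r_min, config$r_max, seed = config$seed)
    kld_rows <- rbind(kld_rows, data.frame(
      sample_id = sid, treatment = tx$treatment, depth = tx$depth,
      kld = kl_divergence(p, q),
      r_min_um = config$r_min, r_max_um = config$r_max,
      psd_kind = "dSe_dr"))
  })

  agg_out <- run_stage("aggregates", {
    rows <- NULL
    agg <- inputs$aggregates
    for (sid in unique(agg$sample_id)) {
      a <- agg[agg$sample_id == sid, ]
      bo <- inputs$bulk$bulk_oc_mg_per_g[inputs$bulk$sample_id == sid]
      fs <- lapply(split(a, a$replicate), function(ar) {
        ar <- ar[match(aggregate_classes(), ar$class_label), ]
        aggregate_fractionation(ar$fraction_mass_g, ar$sand_mass_g,
                                ar$oc_mg_per_g, bulk_oc = bo,
                                replicate_id = ar$replicate[1],
                                depth = ar$depth[1],
                                treatment = ar$treatment[1])
      })
      s <- average_fractionations(fs)
      s$sample_id <- sid
      rows <- rbind(rows, s)
    }
    rows
  })

  dil_out <- run_stage("dilution", {
    bd_amend <- if (identical(config$amendment_bulk_density, "profile_mean"))
      mean(inputs$bulk$bulk_density_g_cm3)
    else as.numeric(config$amendment_bulk_density)
    sch <- amendment_schedule(schedule$applications, schedule$grain_size,
                              schedule$incorporation_depth, bd_amend)
    B <- basalt_contribution(sch)
    shares <- tapply(agg_out$mass_fraction, agg_out$class_label, mean)
    shares <- shares[aggregate_classes()] / sum(shares)
    per_class <- fraction_basalt_contribution(sch, as.numeric(shares))
    soc <- agg_out$oc_mg_per_g  # per-class example correction
    list(B = B, per_class = per_class,
         corrected = data.frame(
           sample_id = agg_out$sample_id, class_label = agg_out$class_label,
           oc_mg_per_g = soc,
           oc_corrected_mg_per_g = dilution_correct(soc, B,
                                                    config$dilution_mode)))
  })

  tex_out <- run_stage("texture", {
    tx <- inputs$texture
    tx$texture_class <- classify_texture(tx$sand, tx$silt, tx$clay)
    tx
  })

  stats_out <- run_stage("stats", {
    tab <- merge(merge(fit_rows[, c("sample_id", "treatment", "depth",
                                    "rmse_theta")],
                       wp_rows, by = "sample_id"),
                 kld_rows[, c("sample_id", "kld")], by = "sample_id")
    vars <- c("Fc_vol_pct", "PWP_vol_pct", "Wa_vol_pct", "porosity", "kld")
    group_tests(tab, vars, "treatment")
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    wr(fit_rows, "fits.csv")
    wr(wp_rows, "water_points.csv")
    wr(kld_rows, "kld.csv")
    wr(agg_out, "aggregates_summary.csv")
    wr(dil_out$per_class, "dilution_per_class.csv")
    wr(dil_out$corrected, "dilution_corrected.csv")
    wr(tex_out, "texture_class.csv")
    wr(stats_out$tests, "stats_tests.csv")
    wr(stats_out$groups, "stats_groups.csv")
    manifest <- list(package = "emwsoil",
                     version = as.character(utils::packageVersion("emwsoil")),
                     seed = config$seed,
                     bulk_B = dil_out$B,
                     config = unclass(config),
                     config_hash = config_hash(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(c(written, file.path(out_dir, "manifest.json")))
    stop(sprintf("pipeline stage 'write' failed: %s", conditionMessage(e)),
         call. = FALSE)
  })

  invisible(list(fits = fit_rows, water_points = wp_rows, kld = kld_rows,
                 aggregates = agg_out, dilution = dil_out,
                 texture = tex_out, stats = stats_out))
}
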