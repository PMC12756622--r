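#' Default "true" hydraulic parameters of the simulated trial
#'
#' Ground-truth bimodal Kosugi parameters resembling a tilled silt loam:
#' saturated water content about 0.50 at 1-6 cm and 0.45 at 15-20 cm
#' (matching silt-loam porosities), a textural lognormal pore domain around
#' hm = 600-700 cm (equivalent pore radius ~2 um, consistent with the pores
#' implied by silt-loam particle packing), and a coarse structural domain
#' around hm = 30-60 cm whose weight shrinks with depth (compaction). Treatment effects enter as
#' an enhancement of the structural domain: its weight grows and its median
#' head falls (larger structural pores), more strongly for lime than for
#' basalt, so the structure index has a signal to detect.
#'
#' @param treatment `"control"`, `"basalt"` or `"lime"`.
#' @param depth `"1-6"` or `"15-20"` (cm interval labels).
#' @param effects Effect-size list as in [trial_design()]; `NULL` uses the
#'   design defaults.
#' @return A [kosugi_params()] object (with `Ks`, `tau` set).
#' @export
default_truth_params <- function(treatment = "control", depth = "1-6",
                                 effects = NULL) {
  if (is.null(effects)) effects <- trial_design()$effects
  surface <- identical(depth, "1-6")
  theta_s <- if (surface) 0.50 else 0.45
  w <- if (surface) 0.25 else 0.15
  hm1 <- if (surface) 30 else 60
  shift <- switch(treatment,
                  control = c(dw = 0, fhm = 1),
                  basalt = c(dw = effects$w_shift_basalt,
                             fhm = effects$hm1_factor_basalt),
                  lime = c(dw = effects$w_shift_lime,
                           fhm = effects$hm1_factor_lime),
                  stop("unknown treatment: ", treatment, call. = FALSE))
  if (!surface && treatment == "basalt") shift <- c(dw = 0, fhm = 1)
  kosugi_params(theta_r = 0.05, theta_s = theta_s,
                w = min(w + shift[["dw"]], 0.95),
                hm1 = hm1 * shift[["fhm"]], sigma1 = 0.9,
                hm2 = if (surface) 600 else 700, sigma2 = 1.6,
                Ks = 200, tau = 0.5)
}

#' Simulate a laboratory retention (and conductivity) dataset
#'
#' Emulates the measurement protocol of an evaporation-method drying run
#' (near-saturation to about pF 3.5) plus dewpoint dry-range points to
#' pF 4.2: `n_points - 3` heads log-spaced over pF 0-3.5 and 3 dry points at
#' pF 3.8/4.0/4.2. Water contents are the true curve plus Gaussian noise
#' (`noise_sd`), clamped to `[0, 1]`; conductivities (optional) carry
#' multiplicative lognormal noise. Pure function of `(params, seed)`: the
#' same seed reproduces the dataset byte-identically and the caller's RNG
#' stream is left untouched.
#'
#' @param params True [kosugi_params()].
#' @param n_points Number of retention points (>= 9); default 100.
#' @param noise_sd Gaussian water-content noise sd; default 0.003.
#' @param seed Integer seed.
#' @param conductivity If `TRUE`, also simulate `n_k` conductivity points.
#' @param n_k Number of conductivity points (pF 0.5-3, log-spaced).
#' @param k_noise_sdlog Lognormal noise sd of conductivity; default 0.1.
#' @return A list with `retention` ([retention_data()]) and `conductivity`
#'   ([conductivity_data()] or `NULL`).
#' @export
simulate_retention_dataset <- function(params, n_points = 100L,
                                       noise_sd = 0.003, seed = 1L,
                                       conductivity = FALSE, n_k = 20L,
                                       k_noise_sdlog = 0.1) {
  validate_kosugi_params(params, require_K = conductivity)
  if (n_points < 9L) stop("need n_points >= 9", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  pf <- c(seq(0, 3.5, length.out = n_points - 3L), c(3.8, 4.0, 4.2))
  h <- 10^pf
  with_local_seed(seed, {
    theta <- theta_of_h(h, params) + stats::rnorm(length(h), 0, noise_sd)
    theta <- pmin(pmax(theta, 0), 1)
    cond <- NULL
    if (conductivity) {
      hk <- 10^seq(0.5, 3, length.out = n_k)
      K <- K_of_h(hk, params) *
        exp(stats::rnorm(n_k, 0, k_noise_sdlog))
      cond <- conductivity_data(hk, K)
    }
    list(retention = retention_data(h, theta), conductivity = cond)
  })
}

#' Trial design for the synthetic field experiment
#'
#' Encodes the layout the generator emulates: 3 treatments (control, basalt,
#' lime) x 3 blocks x 2 sampling depths (1-6 and 15-20 cm), with effect
#' sizes in measurement units. Chemistry effects follow the magnitude of the
#' field observations (pH 6.1 control, 7.2 basalt, 6.7 lime; available Ca
#' about 560 and 510 mg/kg above control); structural effects are expressed
#' as a shift of the coarse pore domain's weight and median head. Setting
#' all effects to zero (`null_effects()`) yields exchangeable treatments for
#' type-I-error checks.
#'
#' @param seed Integer master seed.
#' @param n_blocks Number of field blocks; default 3.
#' @param effects Named list of effect sizes; see Details.
#' @param noise Named list: `theta_sd` (retention noise, cm^3/cm^3),
#'   `oc_cv` (OC measurement coefficient of variation), `chem_cv`
#'   (chemistry cv), `texture_sd` (percentage-point texture noise).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(seed = 1L, n_blocks = 3L,
                         effects = list(
                           ph_shift_basalt = 1.1, ph_shift_lime = 0.6,
                           ca_shift_basalt = 563, ca_shift_lime = 514,
                           w_shift_basalt = 0.04, w_shift_lime = 0.08,
                           hm1_factor_basalt = 0.85, hm1_factor_lime = 0.7),
                         noise = list(theta_sd = 0.003, oc_cv = 0.05,
                                      chem_cv = 0.1, texture_sd = 2)) {
  structure(list(treatments = c("control", "basalt", "lime"),
                 depths = c("1-6", "15-20"), n_blocks = as.integer(n_blocks),
                 seed = as.integer(seed), effects = effects, noise = noise),
            class = "trial_design")
}

#' @rdname trial_design
#' @export
null_effects <- function() {
  list(ph_shift_basalt = 0, ph_shift_lime = 0,
       ca_shift_basalt = 0, ca_shift_lime = 0,
       w_shift_basalt = 0, w_shift_lime = 0,
       hm1_factor_basalt = 1, hm1_factor_lime = 1)
}

#' Simulate a full trial input bundle
#'
#' Generates every table the pipeline consumes, with the statistical
#' structure the analysis assumes: per-sample retention (and conductivity)
#' data from treatment- and depth-specific true parameters, silt-loam
#' texture triplets, four-replicate aggregate fractionations with a
#' depth-dependent OC pattern (S+C fraction depleted at the surface,
#' enriched at depth), bulk densities with depth stratification, and a
#' chemistry table with the design's treatment effects. A manifest of the
#' true hydraulic parameters is included for recovery tests. Deterministic
#' given the design (seeded; sub-seeds are derived per sample and kept below
#' 2^31).
#'
#' @param design A [trial_design()].
#' @param n_points Retention points per sample; default 60 (keeps the
#'   full-pipeline runtime modest; use 100 to mirror the laboratory density).
#' @param conductivity Simulate conductivity datasets too? Default `TRUE`.
#' @return A list of class `trial_bundle` with data frames `retention`,
#'   `conductivity`, `texture`, `aggregates`, `bulk`, `chemistry`, and
#'   `truth` (true parameters per sample).
#' @export
simulate_trial <- function(design = trial_design(), n_points = 60L,
                           conductivity = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  eff <- design$effects; noi <- design$noise
  grid <- expand.grid(treatment = design$treatments,
                      depth = design$depths,
                      block = seq_len(design$n_blocks),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_b%d", grid$treatment,
                            gsub("-", "_", grid$depth), grid$block)

  retention <- conductivity_tab <- texture <- aggregates <- NULL
  bulk <- chemistry <- truth <- NULL
  # E_OC depth pattern: surface S+C depleted, deep S+C enriched
  eoc_target <- list(`1-6` = c(1.10, 0.95, 0.90, 0.86),
                     `15-20` = c(1.02, 1.00, 0.95, 1.12))
  base_frac <- list(`1-6` = c(0.55, 0.15, 0.18, 0.12),
                    `15-20` = c(0.45, 0.22, 0.21, 0.12))
  base_chem <- c(pH = 6.1, Ca = 1608, SOC = 15, P = 19, K = 126, Mg = 306)

  for (i in seq_len(nrow(grid))) {
    tr <- grid$treatment[i]; dp <- grid$depth[i]; bl <- grid$block[i]
    sid <- grid$sample_id[i]
    sub_seed <- (design$seed * 10007L + i * 7919L) %% 2147483647L
    p_true <- default_truth_params(tr, dp, eff)
    sim <- simulate_retention_dataset(p_true, n_points = n_points,
                                      noise_sd = noi$theta_sd,
                                      seed = sub_seed,
                                      conductivity = conductivity)
    retention <- rbind(retention, data.frame(
      sample_id = sid, treatment = tr, depth = dp, block = bl,
      h_cm = sim$retention$h, theta = sim$retention$theta))
    if (conductivity)
      conductivity_tab <- rbind(conductivity_tab, data.frame(
        sample_id = sid, h_cm = sim$conductivity$h,
        K_cm_per_d = sim$conductivity$K))

    with_local_seed(sub_seed + 1L, {
      # texture: silt loam around 24/65/11 with noise, renormalized
      tx <- c(24, 65, 11) + stats::rnorm(3, 0, noi$texture_sd)
      tx <- pmax(tx, 1); tx <- 100 * tx / sum(tx)
      texture <- rbind(texture, data.frame(
        sample_id = sid, treatment = tr, depth = dp, block = bl,
        sand = tx[1], silt = tx[2], clay = tx[3]))

      bd <- (if (dp == "1-6") 1.31 else 1.42) + stats::rnorm(1, 0, 0.03)
      bulk_oc <- base_chem[["SOC"]] *
        exp(stats::rnorm(1, 0, noi$oc_cv))
      bulk <- rbind(bulk, data.frame(
        sample_id = sid, bulk_oc_mg_per_g = bulk_oc,
        bulk_density_g_cm3 = bd))

      fr <- base_frac[[dp]]
      for (rep_i in 1:4) {
        frac <- fr * exp(stats::rnorm(4, 0, 0.08))
        frac <- frac / sum(frac)
        input_mass <- 10
        recovered <- input_mass * stats::runif(1, 0.985, 1.0)
        fmass <- frac * recovered
        sand_m <- c(fmass[1:3] * stats::runif(3, 0.2, 0.35), 0)
        oc <- eoc_target[[dp]] * bulk_oc * exp(stats::rnorm(4, 0, noi$oc_cv))
        aggregates <- rbind(aggregates, data.frame(
          sample_id = sid, treatment = tr, depth = dp, block = bl,
          replicate = rep_i, class_label = aggregate_classes(),
          fraction_mass_g = fmass, sand_mass_g = sand_m,
          oc_mg_per_g = oc, input_mass_g = input_mass))
      }

      ph <- base_chem[["pH"]] +
        switch(tr, control = 0, basalt = eff$ph_shift_basalt,
               lime = eff$ph_shift_lime) + stats::rnorm(1, 0, 0.15)
      ca <- base_chem[["Ca"]] +
        switch(tr, control = 0, basalt = eff$ca_shift_basalt,
               lime = eff$ca_shift_lime)
      chemistry <- rbind(chemistry, data.frame(
        sample_id = sid, treatment = tr, depth = dp, block = bl,
        pH = ph,
        Ca_mg_per_kg = ca * exp(stats::rnorm(1, 0, noi$chem_cv)),
        SOC_mg_per_g = bulk_oc,
        P_mg_per_kg = base_chem[["P"]] * exp(stats::rnorm(1, 0, noi$chem_cv)),
        K_mg_per_kg = base_chem[["K"]] * exp(stats::rnorm(1, 0, noi$chem_cv)),
        Mg_mg_per_kg = base_chem[["Mg"]] * exp(stats::rnorm(1, 0, noi$chem_cv))))
    })

    truth <- rbind(truth, data.frame(
      sample_id = sid, treatment = tr, depth = dp, block = bl,
      theta_r = p_true$theta_r, theta_s = p_true$theta_s, w = p_true$w,
      hm1 = p_true$hm1, sigma1 = p_true$sigma1,
      hm2 = p_true$hm2, sigma2 = p_true$sigma2,
      Ks = p_true$Ks, tau = p_true$tau))
  }

  structure(list(retention = retention, conductivity = conductivity_tab,
                 texture = texture, aggregates = aggregates, bulk = bulk,
                 chemistry = chemistry, truth = truth, design = design),
            class = "trial_bundle")
}
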