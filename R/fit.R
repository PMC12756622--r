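#' Retention and conductivity datasets
#'
#' Light validated containers for the laboratory measurements of one soil
#' core: `retention_data` holds (h, theta) pairs from evaporation-method
#' drying plus dewpoint dry-range points; `conductivity_data` holds (h, K)
#' pairs. Heads are stored as positive suction magnitudes in cm of water
#' (pF = log10(h)).
#'
#' @param h Pressure-head magnitudes, cm; positive.
#' @param theta Volumetric water contents in `[0, 1]`.
#' @return A data frame of class `retention_data` (columns `h`, `theta`).
#' @export
retention_data <- function(h, theta) {
  if (length(h) != length(theta) || length(h) == 0L)
    stop("`h` and `theta` must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("all heads must be positive and finite", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1))
    stop("all water contents must lie in [0, 1]", call. = FALSE)
  structure(data.frame(h = h, theta = theta),
            class = c("retention_data", "data.frame"))
}

#' @rdname retention_data
#' @param K Hydraulic conductivities, cm/d; positive.
#' @export
conductivity_data <- function(h, K) {
  if (length(h) != length(K) || length(h) == 0L)
    stop("`h` and `K` must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("all heads must be positive and finite", call. = FALSE)
  if (any(!is.finite(K)) || any(K <= 0))
    stop("all conductivities must be positive and finite", call. = FALSE)
  structure(data.frame(h = h, K = K),
            class = c("conductivity_data", "data.frame"))
}

#' Parameter search bounds for the bimodal Kosugi fit
#'
#' Box constraints used by [fit_kosugi_bimodal()]. Median heads and
#' saturated conductivity are searched on the log10 scale. The defaults span
#' published mineral-soil ranges: `theta_r` in \[0, 0.25\], `theta_s` in
#' \[0.25, 0.65\], `w` in \[0.01, 0.99\], `hm` in \[1, 1e5\] cm, `sigma` in
#' \[0.1, 3.5\], `Ks` in \[1e-3, 1e4\] cm/d, `tau` in \[-2, 3\].
#'
#' @return A list with `lower` and `upper` named numeric vectors over
#'   `(theta_r, theta_s, w, lhm1, sigma1, lhm2, sigma2, lKs, tau)`, where
#'   `lhm*`/`lKs` are log10-transformed.
#' @export
kosugi_bounds <- function() {
  nm <- c("theta_r", "theta_s", "w", "lhm1", "sigma1", "lhm2", "sigma2",
          "lKs", "tau")
  lower <- c(0, 0.25, 0.01, 0, 0.1, 0, 0.1, -3, -2)
  upper <- c(0.25, 0.65, 0.99, 5, 3.5, 5, 3.5, 4, 3)
  names(lower) <- names(upper) <- nm
  list(lower = lower, upper = upper)
}

#' Fit configuration
#'
#' @param n_starts Number of multistart points (1 heuristic + `n_starts - 1`
#'   Latin-hypercube draws over the bounds).
#' @param seed Integer seed for the Latin-hypercube design; fixed default so
#'   fits are deterministic given data and bounds.
#' @param lambda Weight of the squared log10-conductivity residuals relative
#'   to the squared water-content residuals in the joint objective. `NULL`
#'   (default) sets `lambda = n_theta / n_K` so both blocks carry comparable
#'   leverage.
#' @param bounds Box constraints, see [kosugi_bounds()].
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 16L, seed = 42L, lambda = NULL,
                       bounds = kosugi_bounds(), maxiter = 250L) {
  stopifnot(n_starts >= 1L, maxiter >= 1L)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 lambda = lambda, bounds = bounds,
                 maxiter = as.integer(maxiter)),
            class = "fit_config")
}

# run code under a temporary RNG state so fitting never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

vec_to_params <- function(v, fit_K) {
  kosugi_params(theta_r = v[["theta_r"]], theta_s = v[["theta_s"]],
                w = v[["w"]],
                hm1 = 10^v[["lhm1"]], sigma1 = v[["sigma1"]],
                hm2 = 10^v[["lhm2"]], sigma2 = v[["sigma2"]],
                Ks = if (fit_K) 10^v[["lKs"]] else NA_real_,
                tau = if (fit_K) v[["tau"]] else NA_real_)
}

# theta from the raw search vector without constructor overhead (hot path)
theta_of_h_vec <- function(h, v) {
  dtheta <- v[["theta_s"]] - v[["theta_r"]]
  v[["theta_r"]] + dtheta *
    (v[["w"]] * se_domain(h, 10^v[["lhm1"]], v[["sigma1"]]) +
     (1 - v[["w"]]) * se_domain(h, 10^v[["lhm2"]], v[["sigma2"]]))
}

#' Fit the bimodal Kosugi model to retention (and conductivity) data
#'
#' Bounded Levenberg-Marquardt least squares with a deterministic seeded
#' multistart. The objective is the sum of squared water-content residuals
#' plus `lambda` times the sum of squared log10-conductivity residuals
#' (`lambda = n_theta / n_K` by default; see [fit_config()]). Median heads
#' and `Ks` are searched on the log10 scale. After fitting, the two pore
#' domains are sorted so that `hm1 <= hm2` (coarse/structural domain first),
#' resolving the label-switching ambiguity of the mixture.
#'
#' When no conductivity data are supplied, `Ks` and `tau` do not enter the
#' objective and are reported as `NA` (non-identified).
#'
#' @param ret A [retention_data()] object with at least 9 points spanning at
#'   least 2 decades of head.
#' @param cond An optional [conductivity_data()] object.
#' @param config A [fit_config()].
#' @return An object of class `kosugi_fit`: `params` ([kosugi_params()]),
#'   `rmse_theta`, `rmse_logK` (`NA` without conductivity data), `n_theta`,
#'   `n_K`, `converged`, `ssr` (joint objective at the optimum), `lambda`,
#'   `seed`, `n_starts`.
#' @export
fit_kosugi_bimodal <- function(ret, cond = NULL, config = fit_config()) {
  if (!inherits(ret, "retention_data"))
    ret <- retention_data(ret$h, ret$theta)
  if (nrow(ret) < 9L)
    stop("need at least 9 retention points", call. = FALSE)
  if (diff(range(log10(ret$h))) < 2)
    stop("retention heads must span at least 2 decades", call. = FALSE)
  fit_K <- !is.null(cond) && nrow(cond) > 0L
  if (fit_K && !inherits(cond, "conductivity_data"))
    cond <- conductivity_data(cond$h, cond$K)

  b <- config$bounds
  keep <- if (fit_K) names(b$lower) else setdiff(names(b$lower), c("lKs", "tau"))
  lower <- b$lower[keep]; upper <- b$upper[keep]
  npar <- length(keep)

  lambda <- config$lambda
  if (is.null(lambda)) lambda <- if (fit_K) nrow(ret) / nrow(cond) else 0
  sqrtl <- sqrt(lambda)

  resid_fn <- function(v) {
    names(v) <- keep
    r <- theta_of_h_vec(ret$h, v) - ret$theta
    if (fit_K) {
      p <- vec_to_params(v, TRUE)
      rk <- suppressWarnings(log10(pmax(K_of_h(cond$h, p), 1e-300)) -
                               log10(cond$K))
      r <- c(r, sqrtl * rk)
    }
    r
  }

  # heuristic start from the data, clamped inside the box
  lh <- log10(ret$h)
  start0 <- c(theta_r = max(min(ret$theta) * 0.5, lower[["theta_r"]]),
              theta_s = min(max(ret$theta), upper[["theta_s"]]),
              w = 0.6,
              lhm1 = unname(stats::quantile(lh, 0.35)), sigma1 = 1,
              lhm2 = unname(stats::quantile(lh, 0.85)), sigma2 = 1)
  if (fit_K) start0 <- c(start0, lKs = 2, tau = 0.5)
  start0 <- pmin(pmax(start0[keep], lower + 1e-6), upper - 1e-6)

  starts <- matrix(start0, nrow = 1L)
  if (config$n_starts > 1L) {
    u <- with_local_seed(config$seed,
                         lhs::randomLHS(config$n_starts - 1L, npar))
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`))
  }

  ctl <- minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                    ftol = 1e-15, ptol = 1e-15, gtol = 0)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn, control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- fit$deviance
    if (fit$info %in% 1:4) any_conv <- TRUE
    if (is.null(best) || ssr < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all multistart fits failed", call. = FALSE)

  v <- best$par
  names(v) <- keep
  # sort domains: coarse (small hm) first
  if (v[["lhm1"]] > v[["lhm2"]]) {
    v[c("lhm1", "sigma1", "lhm2", "sigma2")] <-
      v[c("lhm2", "sigma2", "lhm1", "sigma1")]
    v[["w"]] <- 1 - v[["w"]]
  }
  # the box allows w on [0.01, 0.99]; after swap it stays inside
  params <- vec_to_params(v, fit_K)

  rt <- rmse(ret$theta, theta_of_h(ret$h, params))
  rk <- if (fit_K) rmse(log10(cond$K), log10(pmax(K_of_h(cond$h, params), 1e-300)))
        else NA_real_

  structure(list(params = params, rmse_theta = rt, rmse_logK = rk,
                 n_theta = nrow(ret), n_K = if (fit_K) nrow(cond) else 0L,
                 converged = any_conv && is.finite(best$deviance),
                 ssr = best$deviance, lambda = lambda,
                 seed = config$seed, n_starts = config$n_starts),
            class = "kosugi_fit")
}

#' @export
print.kosugi_fit <- function(x, ...) {
  cat(sprintf("Bimodal Kosugi fit (%d theta points, %d K points)\n",
              x$n_theta, x$n_K))
  print(x$params)
  cat(sprintf("  RMSE theta = %.5f", x$rmse_theta))
  if (is.finite(x$rmse_logK)) cat(sprintf(", RMSE log10 K = %.4f", x$rmse_logK))
  cat(sprintf("\n  converged: %s (%d starts, seed %d)\n",
              x$converged, x$n_starts, x$seed))
  invisible(x)
}
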