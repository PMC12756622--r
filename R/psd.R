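#' Young-Laplace pore radius / pressure head transform
#'
#' Capillary equivalence between pressure-head magnitude and pore radius,
#' `r[cm] = 0.149 / h[cm]`, returned in micrometers: `r[um] = 1490 / h[cm]`.
#' The relation is strictly decreasing: h = 1 cm corresponds to the maximum
#' structural radius 1490 um, and the wilting-point head (h near 14,900 cm,
#' pF 4.17) to 0.1 um. `head_from_radius()` is the exact inverse.
#'
#' @param h Pressure-head magnitude(s), cm; positive.
#' @return Equivalent pore radius(es), um.
#' @export
radius_from_head <- function(h) {
  if (any(!is.finite(h)) || any(h <= 0))
    stop("pressure head `h` must be positive and finite", call. = FALSE)
  1490 / h
}

#' @rdname radius_from_head
#' @param r Pore radius(es), um; positive.
#' @export
head_from_radius <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("pore radius `r` must be positive and finite", call. = FALSE)
  1490 / r
}

new_psd <- function(kind, weights, meanlog, sdlog, r_min, r_max,
                    source_params = NULL, fit = NULL) {
  mass <- sum(weights * (stats::pnorm((log(r_max) - meanlog) / sdlog) -
                         stats::pnorm((log(r_min) - meanlog) / sdlog)))
  if (mass < 1e-6)
    stop("degenerate truncation: less than 1e-6 of the pore-volume density ",
         "lies inside [r_min, r_max]", call. = FALSE)
  structure(list(kind = kind, weights = weights, meanlog = meanlog,
                 sdlog = sdlog, r_min = r_min, r_max = r_max, mass = mass,
                 source_params = source_params, fit = fit),
            class = "psd")
}

#' Pore-size density of a `psd` object
#'
#' Evaluates the truncated-renormalized lognormal-mixture density p(r)
#' (units 1/um) of a pore-size distribution; zero outside
#' `[r_min, r_max]`. The density integrates to 1 over the support.
#'
#' @param p A `psd` object (see [psd_from_retention()], [reference_psd()]).
#' @param r Pore radius(es), um.
#' @return Density value(s), 1/um.
#' @export
psd_density <- function(p, r) {
  stopifnot(inherits(p, "psd"))
  d <- numeric(length(r))
  inside <- r >= p$r_min & r <= p$r_max & r > 0
  if (any(inside)) {
    ri <- r[inside]
    di <- 0
    for (i in seq_along(p$weights))
      di <- di + p$weights[i] * stats::dlnorm(ri, p$meanlog[i], p$sdlog[i])
    d[inside] <- di / p$mass
  }
  d
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("Pore-size distribution (%s) on [%.3g, %.3g] um\n",
              x$kind, x$r_min, x$r_max))
  for (i in seq_along(x$weights))
    cat(sprintf("  mode %d: weight %.3f, median %.3g um, sigma %.3f\n",
                i, x$weights[i], exp(x$meanlog[i]), x$sdlog[i]))
  invisible(x)
}

#' Pore-size distribution implied by a fitted retention curve
#'
#' Under the Young-Laplace transform, the bimodal Kosugi retention curve is
#' a two-component lognormal mixture in pore radius: component medians
#' `radius_from_head(hm1)` and `radius_from_head(hm2)`, spreads `sigma1`,
#' `sigma2`, weights `(w, 1 - w)`. The density is the effective-saturation
#' density dSe/dr (a proper probability density independent of the
#' `theta_s - theta_r` scaling), truncated to `[r_min, r_max]` and
#' renormalized to integrate to 1.
#'
#' @param params A valid [kosugi_params()] object.
#' @param r_min,r_max Truncation bounds, um. Defaults 0.1 um (equivalent
#'   radius at the wilting point, assumed structure-independent) and 1490 um
#'   (radius at h = 1 cm).
#' @return A `psd` object of kind `"structured"`.
#' @export
psd_from_retention <- function(params, r_min = 0.1, r_max = 1490) {
  validate_kosugi_params(params)
  if (!(r_min > 0 && r_min < r_max))
    stop("need 0 < r_min < r_max", call. = FALSE)
  new_psd(kind = "structured",
          weights = c(params$w, 1 - params$w),
          meanlog = log(radius_from_head(c(params$hm1, params$hm2))),
          sdlog = c(params$sigma1, params$sigma2),
          r_min = r_min, r_max = r_max, source_params = params)
}

#' Reference (structureless) soil specification
#'
#' Describes the hypothetical same-texture soil without structural pores
#' against which the structure index is scored. The reference pore space is
#' derived from the particle-size distribution: the equivalent pore radius
#' of a particle of radius `R` is `packing_factor * R`, and the cumulative
#' mass fraction below a particle size maps to the water content
#' `theta_r_fixed + F * (theta_s_ref - theta_r_fixed)`. The pore-to-particle
#' scaling is the module's largest approximation: `packing_factor` (default
#' 0.3, of the order implied by dense random packing of spheres) is a free
#' configuration knob and should be held fixed across samples that are
#' compared.
#'
#' @param particle_size Data frame with columns `size_um` (particle
#'   diameter, um) and `cum_fraction` (cumulative mass fraction, reaching
#'   1 at the largest size); at least 3 distinct sizes. See
#'   [texture_to_cumulative()] for building one from a sand/silt/clay
#'   triplet.
#' @param theta_r_fixed Residual water content carried over from the
#'   structured-soil fit (assumed texture-determined, structure-free).
#' @param theta_s_ref Saturated water content of the reference soil;
#'   default 0.30.
#' @param packing_factor Pore radius per unit particle radius; default 0.3.
#' @return A list of class `reference_soil_spec`.
#' @export
reference_soil_spec <- function(particle_size, theta_r_fixed,
                                theta_s_ref = 0.30, packing_factor = 0.3) {
  stopifnot(is.data.frame(particle_size),
            all(c("size_um", "cum_fraction") %in% names(particle_size)))
  ps <- particle_size[order(particle_size$size_um), , drop = FALSE]
  if (length(unique(ps$size_um)) < 3L)
    stop("need at least 3 distinct particle-size classes", call. = FALSE)
  if (any(diff(ps$cum_fraction) < -1e-9))
    stop("cumulative particle-size distribution must be non-decreasing",
         call. = FALSE)
  if (abs(ps$cum_fraction[nrow(ps)] - 1) > 1e-6)
    stop("cumulative particle-size distribution must end at 1", call. = FALSE)
  if (!is.finite(theta_r_fixed) || theta_r_fixed < 0 ||
      theta_r_fixed >= theta_s_ref)
    stop("need 0 <= theta_r_fixed < theta_s_ref", call. = FALSE)
  structure(list(particle_size = ps, theta_r_fixed = theta_r_fixed,
                 theta_s_ref = theta_s_ref, packing_factor = packing_factor),
            class = "reference_soil_spec")
}

#' Cumulative particle-size curve from a texture triplet
#'
#' Expands sand/silt/clay percentages into cumulative (size, mass fraction)
#' pairs at the class boundaries, with a fine anchor below the clay range so
#' the curve starts at zero.
#'
#' @param sand,silt,clay Percentages of fine earth (should sum to ~100).
#' @param bounds Upper diameters (um) of the clay and silt classes and the
#'   fine-earth limit; default `c(2, 53, 2000)` (53 um silt boundary
#'   matching the aggregate sieve; use 63 for the FAO convention).
#' @param anchor_um Size (um) at which the cumulative curve is anchored at
#'   zero; default 0.05.
#' @return Data frame with columns `size_um`, `cum_fraction`.
#' @export
texture_to_cumulative <- function(sand, silt, clay, bounds = c(2, 53, 2000),
                                  anchor_um = 0.05) {
  tot <- sand + silt + clay
  if (!is.finite(tot) || abs(tot - 100) > 0.5)
    stop("sand + silt + clay must sum to 100 (+/- 0.5)", call. = FALSE)
  data.frame(size_um = c(anchor_um, bounds),
             cum_fraction = c(0, clay, clay + silt, tot) / tot)
}

#' Reference-soil pore-size distribution
#'
#' Builds (equivalent pore radius, effective saturation) pairs from the
#' particle-size distribution as described in [reference_soil_spec()],
#' densifies sparse class data by monotone interpolation on the log-size
#' axis, and fits the same two-component lognormal mixture used for the
#' structured soil (residual water content fixed, saturated water content
#' set to `theta_s_ref`) with a deterministic seeded multistart. Returns the
#' implied truncated-normalized pore-size density.
#'
#' @param spec A [reference_soil_spec()].
#' @param r_min,r_max Truncation bounds, um (defaults as in
#'   [psd_from_retention()]).
#' @param n_starts,seed Multistart settings for the bounded
#'   Levenberg-Marquardt fit.
#' @return A `psd` object of kind `"reference"`; its `fit` element carries
#'   `rmse_theta` (water-content RMSE of the mixture against the constructed
#'   pairs) and the equivalent [kosugi_params()].
#' @export
reference_psd <- function(spec, r_min = 0.1, r_max = 1490,
                          n_starts = 8L, seed = 42L) {
  stopifnot(inherits(spec, "reference_soil_spec"))
  ps <- spec$particle_size
  # equivalent pore radius: packing_factor x particle radius (diameter/2)
  r <- spec$packing_factor * ps$size_um / 2
  Fv <- ps$cum_fraction
  if (nrow(ps) < 8L) {
    # densify class-bound data on the log-size axis (monotone linear)
    lr <- seq(min(log(r)), max(log(r)), length.out = 25L)
    Fv <- stats::approx(log(r), Fv, xout = lr, ties = "ordered")$y
    r <- exp(lr)
  }

  lower <- c(w = 0.01, lrm1 = -4, s1 = 0.1, lrm2 = -4, s2 = 0.1)
  upper <- c(w = 0.99, lrm1 = 4, s1 = 3.5, lrm2 = 4, s2 = 3.5)
  resid_fn <- function(v) {
    v["w"] * stats::pnorm((log(r) - log(10) * v["lrm1"]) / v["s1"]) +
      (1 - v["w"]) * stats::pnorm((log(r) - log(10) * v["lrm2"]) / v["s2"]) -
      Fv
  }
  start0 <- c(w = 0.5, lrm1 = log10(stats::median(r)) - 0.5, s1 = 1,
              lrm2 = log10(stats::median(r)) + 0.5, s2 = 1)
  starts <- matrix(start0, nrow = 1L, dimnames = list(NULL, names(lower)))
  if (n_starts > 1L) {
    u <- with_local_seed(seed, lhs::randomLHS(n_starts - 1L, 5L))
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`))
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200L, ftol = 1e-15, ptol = 1e-15)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn, control = ctl),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("reference-PSD fit failed", call. = FALSE)
  v <- best$par
  names(v) <- names(lower)
  if (v[["lrm1"]] < v[["lrm2"]]) {  # coarse mode first, as for structured soil
    v[c("lrm1", "s1", "lrm2", "s2")] <- v[c("lrm2", "s2", "lrm1", "s1")]
    v[["w"]] <- 1 - v[["w"]]
  }
  rm1 <- 10^v[["lrm1"]]; rm2 <- 10^v[["lrm2"]]
  eq_params <- kosugi_params(theta_r = spec$theta_r_fixed,
                             theta_s = spec$theta_s_ref, w = v[["w"]],
                             hm1 = head_from_radius(rm1), sigma1 = v[["s1"]],
                             hm2 = head_from_radius(rm2), sigma2 = v[["s2"]])
  rmse_se <- sqrt(best$deviance / length(r))
  new_psd(kind = "reference",
          weights = c(v[["w"]], 1 - v[["w"]]),
          meanlog = log(c(rm1, rm2)), sdlog = c(v[["s1"]], v[["s2"]]),
          r_min = r_min, r_max = r_max, source_params = eq_params,
          fit = list(rmse_theta = rmse_se * (spec$theta_s_ref - spec$theta_r_fixed),
                     rmse_se = rmse_se, params = eq_params))
}

#' Kullback-Leibler soil-structure index
#'
#' Relative entropy between the structured soil's pore-size density `p` and
#' the texture-derived reference density `q`,
#' \deqn{D_{KL}(p\,\|\,q) = \int_{r_{min}}^{r_{max}} p(r)\,
#'   \ln\frac{p(r)}{q(r)}\,dr,}
#' computed by adaptive quadrature on the ln r axis (absolute tolerance
#' `1e-8`). A larger value indicates a pore system further from the
#' single-grain packing of the same texture, i.e. greater structural
#' development. The result is clamped to `[0, Inf)`; truncation-induced
#' negative noise below `-1e-8` is an error.
#'
#' @param p,q `psd` objects normalized on the same support.
#' @param r_min,r_max Integration bounds, um; default the common support of
#'   `p` and `q` (the two must agree).
#' @param abs_tol Absolute quadrature tolerance.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p, q, r_min = p$r_min, r_max = p$r_max,
                          abs_tol = 1e-8) {
  stopifnot(inherits(p, "psd"), inherits(q, "psd"))
  if (abs(p$r_min - q$r_min) > 1e-9 * max(1, p$r_min) ||
      abs(p$r_max - q$r_max) > 1e-9 * p$r_max)
    stop("`p` and `q` must be normalized on the same [r_min, r_max] support",
         call. = FALSE)
  # support check: q must not underflow where p carries mass
  grid <- exp(seq(log(r_min), log(r_max), length.out = 257L))
  pg <- psd_density(p, grid); qg <- psd_density(q, grid)
  if (any(pg > 1e-12 & qg < 1e-300))
    stop("reference density underflows to 0 where p > 1e-12: ",
         "KL divergence undefined on this support", call. = FALSE)
  integrand <- function(u) {
    r <- exp(u)
    pr <- psd_density(p, r)
    qr <- psd_density(q, r)
    out <- numeric(length(r))
    pos <- pr > 0
    out[pos] <- pr[pos] * r[pos] * (log(pr[pos]) - log(qr[pos]))
    out
  }
  val <- stats::integrate(integrand, log(r_min), log(r_max),
                          abs.tol = abs_tol, rel.tol = abs_tol,
                          subdivisions = 1000L, stop.on.error = TRUE)$value
  if (val < -1e-8)
    stop(sprintf("KL integral evaluated to %.3g < -1e-8; numerical failure",
                 val), call. = FALSE)
  max(val, 0)
}
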