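#' Bimodal Kosugi hydraulic parameter set
#'
#' Bundles the nine parameters of the bimodal Kosugi soil water retention
#' curve (SWRC) and the associated Mualem-type hydraulic conductivity curve
#' (HCC). The retention model superposes two lognormal pore domains with
#' weight `w`: domain 1 with median head `hm1` (cm) and spread `sigma1`,
#' domain 2 with `hm2`, `sigma2`. By convention in this package domain 1 is
#' the coarser (structural) domain, i.e. `hm1 <= hm2`; [fit_kosugi_bimodal()]
#' enforces this ordering after fitting.
#'
#' `Ks` (saturated conductivity, cm/d) and `tau` (tortuosity/connectivity
#' exponent) are only needed for conductivity predictions and may be `NA`
#' when conductivity data are absent; they are then reported as
#' non-identified by the fit.
#'
#' Note on nomenclature: the median parameters `hm1`, `hm2` enter the
#' retention function as pressure heads (cm of suction). They map one-to-one
#' to median pore radii through the Young-Laplace relation
#' ([radius_from_head()]), and some literature labels them as radii.
#'
#' @param theta_r Residual water content (cm^3/cm^3).
#' @param theta_s Saturated water content (cm^3/cm^3).
#' @param w Weight of pore domain 1, in (0, 1).
#' @param hm1,hm2 Median pressure heads of domains 1 and 2 (cm, positive).
#' @param sigma1,sigma2 Lognormal spreads of domains 1 and 2 (dimensionless).
#' @param Ks Saturated hydraulic conductivity (cm/d), or `NA`.
#' @param tau Tortuosity/connectivity exponent, or `NA`.
#' @return An object of class `kosugi_params` (a named list).
#' @examples
#' p <- kosugi_params(0.05, 0.50, 0.7, 50, 0.8, 2000, 1.2)
#' theta_of_h(c(1, 50, 1000), p)
#' @export
kosugi_params <- function(theta_r, theta_s, w, hm1, sigma1, hm2, sigma2,
                          Ks = NA_real_, tau = NA_real_) {
  p <- structure(
    list(theta_r = theta_r, theta_s = theta_s, w = w,
         hm1 = hm1, sigma1 = sigma1, hm2 = hm2, sigma2 = sigma2,
         Ks = Ks, tau = tau),
    class = "kosugi_params")
  validate_kosugi_params(p)
  p
}

#' Validate a bimodal Kosugi parameter set
#'
#' Checks the parameter invariants (`0 <= theta_r < theta_s <= 1`,
#' `0 < w < 1`, positive heads and spreads, positive `Ks` when given) and
#' stops with an informative error on violation.
#'
#' @param p A [kosugi_params()] object.
#' @param require_K If `TRUE`, additionally require finite `Ks > 0` and
#'   finite `tau` (needed for conductivity predictions).
#' @return `p`, invisibly.
#' @export
validate_kosugi_params <- function(p, require_K = FALSE) {
  if (!inherits(p, "kosugi_params"))
    stop("`p` must be a kosugi_params object", call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  with(p, {
    if (!num1(theta_r) || !num1(theta_s) || theta_r < 0 || theta_r >= theta_s ||
        theta_s > 1)
      stop("invalid water contents: need 0 <= theta_r < theta_s <= 1",
           call. = FALSE)
    if (!num1(w) || w <= 0 || w >= 1)
      stop("invalid domain weight: need 0 < w < 1", call. = FALSE)
    if (!num1(hm1) || !num1(hm2) || hm1 <= 0 || hm2 <= 0)
      stop("median heads hm1, hm2 must be positive", call. = FALSE)
    if (!num1(sigma1) || !num1(sigma2) || sigma1 <= 0 || sigma2 <= 0)
      stop("spreads sigma1, sigma2 must be positive", call. = FALSE)
  })
  if (require_K) {
    if (!is.finite(p$Ks) || p$Ks <= 0)
      stop("Ks must be a positive finite number for conductivity predictions",
           call. = FALSE)
    if (!is.finite(p$tau))
      stop("tau must be finite for conductivity predictions", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kosugi_params <- function(x, ...) {
  cat("Bimodal Kosugi parameters\n")
  cat(sprintf("  theta_r = %.4f, theta_s = %.4f, w = %.4f\n",
              x$theta_r, x$theta_s, x$w))
  cat(sprintf("  domain 1: hm = %.4g cm, sigma = %.4f\n", x$hm1, x$sigma1))
  cat(sprintf("  domain 2: hm = %.4g cm, sigma = %.4f\n", x$hm2, x$sigma2))
  if (is.finite(x$Ks))
    cat(sprintf("  Ks = %.4g cm/d, tau = %.4f\n", x$Ks, x$tau))
  else
    cat("  Ks, tau: not identified (no conductivity data)\n")
  invisible(x)
}

# per-domain effective saturation Se_i(h) = 0.5 * erfc(ln(h/hm_i) / (sigma_i * sqrt(2)))
se_domain <- function(h, hm, sigma) {
  0.5 * pracma::erfc(log(h / hm) / (sigma * sqrt(2)))
}

#' Bimodal Kosugi water retention curve
#'
#' Volumetric water content as a function of pressure-head magnitude
#' (positive suction, cm of water):
#' \deqn{\theta(h) = \theta_r + w(\theta_s-\theta_r)\,
#'   \tfrac{1}{2}\mathrm{erfc}\!\left[\frac{\ln(h/h_{m1})}{\sigma_1\sqrt2}\right]
#'   + (1-w)(\theta_s-\theta_r)\,
#'   \tfrac{1}{2}\mathrm{erfc}\!\left[\frac{\ln(h/h_{m2})}{\sigma_2\sqrt2}\right]}
#'
#' @param h Pressure-head magnitude(s), cm of water; must be positive.
#' @param params A valid [kosugi_params()] object.
#' @return Volumetric water content(s) in `[theta_r, theta_s]`.
#' @export
theta_of_h <- function(h, params) {
  validate_kosugi_params(params)
  if (!is.numeric(h) || length(h) == 0L || any(!is.finite(h)) || any(h <= 0))
    stop("pressure head `h` must be positive and finite", call. = FALSE)
  dtheta <- params$theta_s - params$theta_r
  params$theta_r +
    dtheta * (params$w       * se_domain(h, params$hm1, params$sigma1) +
              (1 - params$w) * se_domain(h, params$hm2, params$sigma2))
}

#' Effective saturation
#'
#' `Se = (theta - theta_r) / (theta_s - theta_r)`, clamped to `[0, 1]` when
#' numerical noise pushes it marginally outside (a warning is emitted if the
#' excursion exceeds `1e-10`).
#'
#' @param theta Volumetric water content(s).
#' @param params A valid [kosugi_params()] object.
#' @return Effective saturation(s) in `[0, 1]`.
#' @export
effective_saturation <- function(theta, params) {
  validate_kosugi_params(params)
  se <- (theta - params$theta_r) / (params$theta_s - params$theta_r)
  if (any(se < -1e-10 | se > 1 + 1e-10))
    warning("effective saturation outside [0, 1]; clamping", call. = FALSE)
  pmin(pmax(se, 0), 1)
}

#' Bimodal Kosugi hydraulic conductivity curve
#'
#' Mualem-type conductivity prediction for the bimodal Kosugi retention
#' model:
#' \deqn{K(h) = K_s\,S_e^{\tau}\,
#'   \frac{\left[a\,\mathrm{erfc}\!\left(\frac{\sigma_1}{\sqrt2} +
#'     \mathrm{erfc}^{-1}(2S_{e1})\right) +
#'     b\,\mathrm{erfc}\!\left(\frac{\sigma_2}{\sqrt2} +
#'     \mathrm{erfc}^{-1}(2S_{e2})\right)\right]^2}{4\,(a+b)^2}}
#' with capillarity weights \eqn{a = (w/h_{m1})\exp(\sigma_1^2/2)},
#' \eqn{b = ((1-w)/h_{m2})\exp(\sigma_2^2/2)}, overall effective saturation
#' \eqn{S_e} and per-domain saturations \eqn{S_{e1}, S_{e2}}. For the
#' lognormal domains \eqn{\mathrm{erfc}^{-1}(2S_{ei}) =
#' \ln(h/h_{mi})/(\sigma_i\sqrt2)}, which is used directly for numerical
#' stability. `K` tends to `Ks` at saturation and to 0 in the dry limit.
#'
#' @param h Pressure-head magnitude(s), cm; positive.
#' @param params A valid [kosugi_params()] object with finite `Ks`, `tau`.
#' @return Hydraulic conductivity(ies), cm/d, in `[0, Ks]`.
#' @export
K_of_h <- function(h, params) {
  validate_kosugi_params(params, require_K = TRUE)
  if (!is.numeric(h) || length(h) == 0L || any(!is.finite(h)) || any(h <= 0))
    stop("pressure head `h` must be positive and finite", call. = FALSE)
  a <- params$w / params$hm1 * exp(params$sigma1^2 / 2)
  b <- (1 - params$w) / params$hm2 * exp(params$sigma2^2 / 2)
  se <- effective_saturation(theta_of_h(h, params), params)
  # erfcinv(2 * Se_i) expressed analytically in h
  arg1 <- params$sigma1 / sqrt(2) + log(h / params$hm1) / (params$sigma1 * sqrt(2))
  arg2 <- params$sigma2 / sqrt(2) + log(h / params$hm2) / (params$sigma2 * sqrt(2))
  term <- a * pracma::erfc(arg1) + b * pracma::erfc(arg2)
  K <- params$Ks * se^params$tau * term^2 / (4 * (a + b)^2)
  pmin(pmax(K, 0), params$Ks)
}

#' Root-mean-square error
#'
#' `sqrt(mean((measured - predicted)^2))`, the fit-quality statistic used
#' for both water-content and log10-conductivity residuals.
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) == 0L || length(measured) != length(predicted))
    stop("`measured` and `predicted` must be non-empty and of equal length",
         call. = FALSE)
  sqrt(mean((measured - predicted)^2))
}

#' Standard water points from a fitted retention curve
#'
#' Field capacity is read off the retention curve at pF 1.8
#' (h = 10^1.8 cm), the permanent wilting point at pF 4.2, both expressed in
#' vol-%; plant-available water is their difference. Total porosity is
#' computed from bulk density as `phi = 1 - bd / particle_density`, with the
#' standard mineral-soil particle density 2.65 g/cm^3 as default.
#'
#' @param params A valid [kosugi_params()] object.
#' @param bd Bulk density, g/cm^3.
#' @param particle_density Particle density, g/cm^3 (default 2.65).
#' @param pf_fc,pf_pwp pF values defining field capacity and wilting point
#'   (defaults 1.8 and 4.2).
#' @return A list of class `water_points`: `Fc`, `PWP`, `Wa` (vol-%), `phi`.
#' @export
water_points <- function(params, bd, particle_density = 2.65,
                         pf_fc = 1.8, pf_pwp = 4.2) {
  validate_kosugi_params(params)
  if (!is.finite(bd) || bd <= 0 || !is.finite(particle_density) ||
      bd >= particle_density)
    stop("need 0 < bd < particle_density", call. = FALSE)
  Fc <- 100 * theta_of_h(10^pf_fc, params)
  PWP <- 100 * theta_of_h(10^pf_pwp, params)
  structure(list(Fc = Fc, PWP = PWP, Wa = Fc - PWP,
                 phi = 1 - bd / particle_density),
            class = "water_points")
}

#' @export
print.water_points <- function(x, ...) {
  cat(sprintf("Fc = %.1f vol-%%, PWP = %.1f vol-%%, Wa = %.1f vol-%%, phi = %.2f\n",
              x$Fc, x$PWP, x$Wa, x$phi))
  invisible(x)
}
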