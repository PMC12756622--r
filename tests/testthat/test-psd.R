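test_that("Young-Laplace transform matches its anchor points and inverts", {
  expect_equal(radius_from_head(1), 1490, tolerance = 1e-14)
  expect_equal(radius_from_head(14900), 0.1, tolerance = 1e-14)
  expect_equal(radius_from_head(149), 10, tolerance = 1e-14)
  set.seed(5)
  h <- 10^runif(50, -2, 6)
  expect_equal(head_from_radius(radius_from_head(h)), h, tolerance = 1e-12)
  expect_error(radius_from_head(0), "positive")
  expect_error(head_from_radius(-1), "positive")
})

test_that("retention-derived PSD is a normalized lognormal mixture", {
  # near-degenerate single mode: median radius 10 um for hm = 149 cm
  p1 <- psd_from_retention(kosugi_params(0.05, 0.5, 0.5, 149, 0.8, 149, 0.8),
                           r_min = 1e-4, r_max = 1e7)
  below <- stats::integrate(function(r) psd_density(p1, r), 1e-4, 10,
                            subdivisions = 500L)$value
  expect_equal(below, 0.5, tolerance = 1e-6)
  # normalization contract for arbitrary valid params and truncation
  set.seed(33)
  for (i in 1:10) {
    pp <- random_valid_params()
    ps <- psd_from_retention(pp, r_min = 0.1, r_max = 1490)
    total <- stats::integrate(function(r) psd_density(ps, r), 0.1, 1490,
                              subdivisions = 1000L, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(psd_from_retention(ref_params(), r_min = 1e6, r_max = 1e7),
               "degenerate truncation")
})

test_that("PSD quantiles agree with Monte-Carlo draws from the mixture", {
  p <- ref_params()
  ps <- psd_from_retention(p, r_min = 1e-6, r_max = 1e9)  # wide: no truncation
  set.seed(99)
  n <- 1e6
  comp <- sample(1:2, n, replace = TRUE, prob = ps$weights)
  draws <- stats::rlnorm(n, ps$meanlog[comp], ps$sdlog[comp])
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  emp <- stats::quantile(draws, probs)
  cdf <- function(r) sum(ps$weights * stats::pnorm((log(r) - ps$meanlog) /
                                                     ps$sdlog))
  theo <- vapply(probs, function(pr)
    stats::uniroot(function(r) cdf(r) - pr, c(1e-6, 1e9),
                   tol = 1e-10)$root, numeric(1))
  expect_lt(max(abs(emp - theo) / theo), 0.01)
})

test_that("KL divergence matches the closed lognormal form and is a divergence", {
  wide <- c(1e-5, 1e8)
  near_one <- c(1 - 1e-9, 1e-9)
  p <- emwsoil:::new_psd("structured", near_one, log(c(10, 10)), c(0.8, 0.8),
                         wide[1], wide[2])
  q <- emwsoil:::new_psd("reference", near_one, log(c(5, 5)), c(1.2, 1.2),
                         wide[1], wide[2])
  # closed form: ln(s2/s1) + (s1^2 + (mu1-mu2)^2) / (2 s2^2) - 1/2
  expect_equal(kl_divergence(p, q), 0.29451129349642877, tolerance = 1e-4)
  expect_identical(kl_divergence(p, p), 0)
  expect_gt(kl_divergence(q, p), 0)  # Gibbs: any p != q
})

test_that("KL is non-negative, zero iff equal, and quadrature-converged", {
  set.seed(44)
  for (i in 1:8) {
    pa <- random_valid_params(); pb <- random_valid_params()
    p <- psd_from_retention(pa); q <- psd_from_retention(pb)
    kl <- kl_divergence(p, q)
    expect_gte(kl, 0)
    expect_gt(kl_divergence(p, q) + kl_divergence(q, p), 0)
    # tightening the tolerance tenfold moves the value by < 1e-5
    expect_lt(abs(kl - kl_divergence(p, q, abs_tol = 1e-9)), 1e-5)
    expect_identical(kl_divergence(p, p), 0)
  }
})

test_that("KL rejects mismatched supports", {
  p <- psd_from_retention(ref_params(), 0.1, 1490)
  q <- psd_from_retention(ref_params(), 0.1, 1000)
  expect_error(kl_divergence(p, q), "same")
})

test_that("reference PSD is deterministic and tracks texture coarseness", {
  spec <- reference_soil_spec(texture_to_cumulative(24, 65, 11),
                              theta_r_fixed = 0.05)
  q1 <- reference_psd(spec); q2 <- reference_psd(spec)
  expect_identical(q1$weights, q2$weights)
  expect_identical(q1$meanlog, q2$meanlog)
  # coarse (sandy) texture implies larger pores than a clayey one
  sandy <- reference_psd(reference_soil_spec(
    texture_to_cumulative(90, 7, 3), theta_r_fixed = 0.05))
  clayey <- reference_psd(reference_soil_spec(
    texture_to_cumulative(5, 25, 70), theta_r_fixed = 0.05))
  med <- function(ps) {
    cdf <- function(r) stats::integrate(function(x) psd_density(ps, x),
                                        ps$r_min, r,
                                        subdivisions = 500L)$value
    stats::uniroot(function(r) cdf(r) - 0.5, c(ps$r_min, ps$r_max))$root
  }
  expect_gt(med(sandy), med(clayey))
  # the fitted curve passes through the constructed pairs
  expect_lte(q1$fit$rmse_theta, 0.01)
  expect_error(reference_soil_spec(
    data.frame(size_um = c(2, 2000), cum_fraction = c(0.3, 1)),
    theta_r_fixed = 0.05), "3 distinct")
})

test_that("an added coarse-pore mode raises the structure index", {
  # same texture-derived reference; structured soil with and without an
  # enhanced structural domain
  spec <- reference_soil_spec(texture_to_cumulative(24, 65, 11),
                              theta_r_fixed = 0.05)
  q <- reference_psd(spec)
  without <- kosugi_params(0.05, 0.50, 0.15, 60, 0.9, 600, 1.6)
  with_mode <- kosugi_params(0.05, 0.50, 0.35, 25, 0.9, 600, 1.6)
  kl0 <- kl_divergence(psd_from_retention(without), q)
  kl1 <- kl_divergence(psd_from_retention(with_mode), q)
  expect_gt(kl1, kl0)
})
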