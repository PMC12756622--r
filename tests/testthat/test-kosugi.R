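test_that("retention curve hits its analytical limits and the frozen oracle", {
  p <- ref_params()
  # saturation limit: erfc argument -> -Inf, erfc -> 2
  expect_equal(theta_of_h(1e-12, p), p$theta_s, tolerance = 1e-9)
  # median symmetry: with both domains identical the curve is unimodal and
  # theta(hm) sits exactly mid-way between theta_r and theta_s (erfc(0) = 1)
  pu <- kosugi_params(0.05, 0.50, 0.5, 50, 0.8, 50, 0.8)
  expect_equal(theta_of_h(50, pu), 0.05 + (0.50 - 0.05) / 2, tolerance = 1e-14)
  # high-precision direct-substitution value (50-digit arithmetic)
  expect_equal(theta_of_h(50, p), 0.34235746527088627838, tolerance = 1e-13)
})

test_that("retention curve is monotone and bounded for random parameters", {
  set.seed(101)
  h <- 10^seq(-2, 5, length.out = 300)
  for (i in 1:25) {
    p <- random_valid_params()
    th <- theta_of_h(h, p)
    expect_true(all(diff(th) <= 1e-12))
    expect_true(all(th >= p$theta_r - 1e-12 & th <= p$theta_s + 1e-12))
  }
})

test_that("conductivity curve hits its limits and the frozen oracle", {
  p <- ref_params(Ks = 100, tau = 0.5)
  expect_equal(K_of_h(1e-12, p), 100, tolerance = 1e-9)  # saturated limit
  expect_lt(K_of_h(1e7, p), 1e-10)                       # dry limit
  # 50-digit direct substitution of the bimodal Mualem expression
  expect_equal(K_of_h(200, p), 0.017516258608269771789, tolerance = 1e-12)
  expect_equal(K_of_h(10, p), 78.412353394632208984, tolerance = 1e-12)
})

test_that("conductivity is non-increasing in h and bounded by Ks", {
  set.seed(202)
  h <- 10^seq(-2, 5, length.out = 200)
  for (i in 1:15) {
    p <- random_valid_params()
    # monotonicity is a property of the Mualem form for non-negative
    # tortuosity exponents; negative tau can lift K in the dry range
    p$tau <- abs(p$tau)
    K <- K_of_h(h, p)
    expect_true(all(diff(K) <= 1e-9 * p$Ks))
    expect_true(all(K >= 0 & K <= p$Ks + 1e-12))
  }
})

test_that("domain and validation errors are raised", {
  p <- ref_params()
  expect_error(theta_of_h(0, p), "positive")
  expect_error(theta_of_h(-5, p), "positive")
  expect_error(kosugi_params(0.5, 0.4, 0.5, 10, 1, 100, 1), "theta_r")
  expect_error(kosugi_params(0.05, 0.5, 1.2, 10, 1, 100, 1), "weight")
  expect_error(kosugi_params(0.05, 0.5, 0.5, -10, 1, 100, 1), "positive")
  expect_error(K_of_h(10, ref_params()), "Ks")
})

test_that("rmse follows the definition", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.01, -0.01), c(0, 0)), 0.01)
  expect_equal(rmse(0.02, 0), 0.02)
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("water points derive consistently from the curve and bulk density", {
  p <- ref_params()
  wp <- water_points(p, bd = 1.4)
  expect_equal(wp$Fc, 100 * theta_of_h(10^1.8, p), tolerance = 1e-14)
  expect_equal(wp$PWP, 100 * theta_of_h(10^4.2, p), tolerance = 1e-14)
  expect_equal(wp$Wa, wp$Fc - wp$PWP, tolerance = 1e-12)
  expect_lte(wp$PWP, wp$Fc)
  expect_equal(wp$phi, 1 - 1.4 / 2.65, tolerance = 1e-14)
  expect_error(water_points(p, bd = 2.7), "particle_density")
  expect_error(water_points(p, bd = 2.65), "particle_density")
})
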