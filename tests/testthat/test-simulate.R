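test_that("retention simulator is exact at zero noise and seed-stable", {
  p <- ref_params()
  s0 <- simulate_retention_dataset(p, n_points = 30, noise_sd = 0, seed = 4)
  expect_equal(s0$retention$theta, theta_of_h(s0$retention$h, p),
               tolerance = 1e-14)
  s1 <- simulate_retention_dataset(p, n_points = 30, noise_sd = 0.003, seed = 4)
  s2 <- simulate_retention_dataset(p, n_points = 30, noise_sd = 0.003, seed = 4)
  expect_identical(s1, s2)
  s3 <- simulate_retention_dataset(p, n_points = 30, noise_sd = 0.003, seed = 5)
  expect_false(identical(s1$retention$theta, s3$retention$theta))
  expect_error(simulate_retention_dataset(p, noise_sd = -1), "non-negative")
  expect_error(simulate_retention_dataset(p, n_points = 8), "n_points")
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_retention_dataset(ref_params(), seed = 77))
  expect_identical(.Random.seed, before)
  invisible(simulate_trial(trial_design(seed = 3), n_points = 12,
                           conductivity = FALSE))
  expect_identical(.Random.seed, before)
})

test_that("trial bundles are byte-identical under a fixed seed", {
  b1 <- simulate_trial(trial_design(seed = 21), n_points = 15,
                       conductivity = FALSE)
  b2 <- simulate_trial(trial_design(seed = 21), n_points = 15,
                       conductivity = FALSE)
  expect_identical(b1$retention, b2$retention)
  expect_identical(b1$aggregates, b2$aggregates)
  expect_identical(b1$chemistry, b2$chemistry)
})

test_that("noisy simulated retention data are recovered at the calibrated level", {
  # tolerances frozen from a 30-replicate Monte-Carlo calibration:
  # max curve RMSE 0.0014, rmse_theta max 0.0034
  p <- default_truth_params("control", "1-6")
  for (s in c(301, 302, 303)) {
    sim <- simulate_retention_dataset(p, n_points = 100, noise_sd = 0.003,
                                      seed = s)
    f <- fit_kosugi_bimodal(sim$retention)
    hg <- 10^seq(0, 4.2, length.out = 120)
    expect_lt(rmse(theta_of_h(hg, p), theta_of_h(hg, f$params)), 0.005)
    expect_lte(f$rmse_theta, 0.01)
  }
})

test_that("zero effect sizes yield null-level treatment differences", {
  sig <- logical(0)
  for (s in 1:30) {
    b <- simulate_trial(trial_design(seed = 1000 + s,
                                     effects = null_effects()),
                        n_points = 12, conductivity = FALSE)
    res <- group_tests(b$chemistry, c("pH", "Ca_mg_per_kg"), "treatment")
    sig <- c(sig, res$tests$kw_p <= 0.05)
  }
  # per-variable type-I behaviour: significant in at most ~10% of tests
  expect_lte(mean(sig), 0.10)
})

test_that("built-in effects leave a detectable chemistry signal", {
  b <- simulate_trial(trial_design(seed = 6), n_points = 12,
                      conductivity = FALSE)
  res <- group_tests(b$chemistry, "pH", "treatment")
  expect_lt(res$tests$kw_p, 0.05)
  mean_ph <- tapply(b$chemistry$pH, b$chemistry$treatment, mean)
  expect_gt(mean_ph[["basalt"]], mean_ph[["control"]])
})

test_that("the aggregate OC depth pattern matches the intended gradient", {
  b <- simulate_trial(trial_design(seed = 17), n_points = 12,
                      conductivity = FALSE)
  sc <- b$aggregates[b$aggregates$class_label == "lt53", ]
  bulk <- b$bulk$bulk_oc_mg_per_g[match(sc$sample_id, b$bulk$sample_id)]
  eoc <- enrichment_factor(sc$oc_mg_per_g, bulk)
  # surface S+C depleted, deep S+C enriched
  expect_lt(mean(eoc[sc$depth == "1-6"]), 1)
  expect_gt(mean(eoc[sc$depth == "15-20"]), 1)
})
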