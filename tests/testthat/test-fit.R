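test_that("noiseless retention data recover the generating parameters", {
  p <- ref_params()
  sim <- simulate_retention_dataset(p, n_points = 60, noise_sd = 0, seed = 7)
  f <- fit_kosugi_bimodal(sim$retention)
  expect_true(f$converged)
  nm <- c("theta_r", "theta_s", "w", "hm1", "sigma1", "hm2", "sigma2")
  truth <- unlist(p[nm]); est <- unlist(f$params[nm])
  expect_lt(max(abs(est - truth) / abs(truth)), 1e-4)
  # Ks/tau not identified without conductivity data
  expect_true(is.na(f$params$Ks) && is.na(f$params$tau))
  expect_true(is.na(f$rmse_logK))
})

test_that("joint theta + K fit recovers all nine parameters noiselessly", {
  p <- ref_params(Ks = 100, tau = 0.5)
  sim <- simulate_retention_dataset(p, n_points = 60, noise_sd = 0, seed = 7,
                                    conductivity = TRUE, k_noise_sdlog = 0)
  f <- fit_kosugi_bimodal(sim$retention, sim$conductivity)
  nm <- c("theta_r", "theta_s", "w", "hm1", "sigma1", "hm2", "sigma2",
          "Ks", "tau")
  truth <- unlist(p[nm]); est <- unlist(f$params[nm])
  expect_lt(max(abs(est - truth) / abs(truth)), 1e-4)
  expect_lt(f$rmse_logK, 1e-6)
})

test_that("data from a unimodal curve are matched to 1e-6 in theta", {
  # unimodal Kosugi curve (single lognormal domain), computed directly
  h <- 10^seq(0, 4.2, length.out = 60)
  theta_uni <- 0.05 + (0.48 - 0.05) *
    0.5 * pracma::erfc(log(h / 300) / (1.1 * sqrt(2)))
  f <- fit_kosugi_bimodal(retention_data(h, theta_uni))
  # curve equivalence is the contract; parameter values may differ
  expect_lt(max(abs(theta_of_h(h, f$params) - theta_uni)), 1e-6)
})

test_that("fit quality on noisy data stays at the reported level", {
  p <- ref_params()
  sim <- simulate_retention_dataset(p, n_points = 100, noise_sd = 0.003,
                                    seed = 31)
  f <- fit_kosugi_bimodal(sim$retention)
  expect_lte(f$rmse_theta, 0.01)
  # curve recovery within the Monte-Carlo-calibrated band (30-replicate
  # calibration: max curve RMSE 0.0014, max relative errors per parameter
  # well inside the bounds below)
  hg <- 10^seq(0, 4.2, length.out = 120)
  expect_lt(rmse(theta_of_h(hg, p), theta_of_h(hg, f$params)), 0.004)
  nm <- c("theta_s", "w", "hm1", "sigma1", "hm2")
  expect_lt(max(abs(unlist(f$params[nm]) - unlist(p[nm])) / unlist(p[nm])),
            0.15)
})

test_that("fitting is deterministic and orders the pore domains", {
  p <- ref_params()
  sim <- simulate_retention_dataset(p, n_points = 60, noise_sd = 0.003,
                                    seed = 12)
  f1 <- fit_kosugi_bimodal(sim$retention)
  f2 <- fit_kosugi_bimodal(sim$retention)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_lte(f1$params$hm1, f1$params$hm2)
})

test_that("the optimum is locally optimal in the rmse sense", {
  p <- ref_params()
  sim <- simulate_retention_dataset(p, n_points = 60, noise_sd = 0.003,
                                    seed = 9)
  f <- fit_kosugi_bimodal(sim$retention)
  base <- rmse(sim$retention$theta, theta_of_h(sim$retention$h, f$params))
  set.seed(77)
  for (i in 1:20) {
    q <- f$params
    q$theta_s <- q$theta_s * (1 + rnorm(1, 0, 0.02))
    q$w <- min(max(q$w * (1 + rnorm(1, 0, 0.05)), 0.01), 0.99)
    q$hm1 <- q$hm1 * exp(rnorm(1, 0, 0.05))
    q$sigma2 <- q$sigma2 * (1 + rnorm(1, 0, 0.05))
    pert <- rmse(sim$retention$theta, theta_of_h(sim$retention$h, q))
    expect_gte(pert, base)
  }
})

test_that("input guards reject unusable retention datasets", {
  p <- ref_params()
  h <- 10^seq(0, 3, length.out = 8)
  expect_error(fit_kosugi_bimodal(retention_data(h, theta_of_h(h, p))),
               "at least 9")
  h2 <- seq(10, 90, length.out = 20)  # < 2 decades
  expect_error(fit_kosugi_bimodal(retention_data(h2, theta_of_h(h2, p))),
               "decades")
})
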