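frac_fixture <- function(fraction_mass = c(5, 2, 2, 1),
                         sand_mass = c(1, 0.5, 0.5, 0),
                         oc = c(18, 14, 12, 16), bulk_oc = 15, ...) {
  aggregate_fractionation(fraction_mass, sand_mass, oc, bulk_oc, ...)
}

test_that("sand correction subtracts and renormalizes", {
  f <- frac_fixture()
  expect_equal(as.numeric(sand_corrected_fractions(f)),
               c(4, 1.5, 1.5, 1) / 8, tolerance = 1e-14)
  # zero sand: identity with raw fractions
  f0 <- frac_fixture(sand_mass = c(0, 0, 0, 0))
  expect_equal(as.numeric(sand_corrected_fractions(f0)),
               c(5, 2, 2, 1) / 10, tolerance = 1e-14)
  # class fully sand: zero fraction, others renormalize
  fz <- frac_fixture(sand_mass = c(5, 0, 0, 0))
  cf <- sand_corrected_fractions(fz)
  expect_identical(unname(cf[1]), 0)
  expect_equal(sum(cf), 1, tolerance = 1e-14)
  expect_error(frac_fixture(sand_mass = c(6, 0, 0, 0)), "exceeds")
  expect_error(frac_fixture(sand_mass = c(1, 0.5, 0.5, 0.2)), "<53")
})

test_that("corrected fractions sum to 1 and are permutation-equivariant", {
  set.seed(8)
  for (i in 1:10) {
    m <- runif(4, 0.5, 5)
    s <- c(runif(3, 0, 0.4), 0) * m
    f <- frac_fixture(fraction_mass = m, sand_mass = s)
    cf <- sand_corrected_fractions(f)
    expect_equal(sum(cf), 1, tolerance = 1e-12)
    # permuting the first three classes permutes the fractions identically
    perm <- c(3, 1, 2, 4)
    fp <- frac_fixture(fraction_mass = m[perm], sand_mass = s[perm])
    expect_equal(as.numeric(sand_corrected_fractions(fp)),
                 as.numeric(cf)[perm], tolerance = 1e-12)
  }
})

test_that("enrichment factor is the OC ratio with its invariances", {
  expect_identical(enrichment_factor(15, 15), 1)
  expect_equal(enrichment_factor(13.2, 15), 0.88, tolerance = 1e-12)
  expect_identical(enrichment_factor(0, 15), 0)
  expect_error(enrichment_factor(10, 0), "positive")
  # scale invariance: multiplying all OC by k leaves E_OC unchanged
  oc <- c(18, 14, 12, 16)
  expect_equal(enrichment_factor(3.7 * oc, 3.7 * 15),
               enrichment_factor(oc, 15), tolerance = 1e-14)
})

test_that("OC contributions follow the mass weighting and conserve", {
  expect_identical(oc_contribution(0, 12), 0)
  expect_equal(oc_contribution(c(0.5, 0.2, 0.2, 0.1), rep(11, 4)),
               c(0.5, 0.2, 0.2, 0.1) * 11)
  contrib <- oc_contribution(c(0.6, 0.2, 0.15, 0.05), c(18, 14, 12, 16))
  expect_equal(contrib, c(10.8, 2.8, 1.8, 0.8), tolerance = 1e-12)
  expect_equal(sum(contrib), 16.2, tolerance = 1e-12)
  expect_error(oc_contribution(1.2, 10), "\\[0, 1\\]")
})

test_that("summary conserves mass-weighted OC and flags imbalance", {
  f <- frac_fixture()
  s <- aggregate_summary(f)
  mf <- sand_corrected_fractions(f)
  expect_equal(sum(s$oc_contribution_mg_per_g),
               sum(mf * f$oc_conc), tolerance = 1e-12)
  expect_false(attr(s, "oc_balance_flag"))
  # strongly inconsistent bulk OC trips the 15% diagnostic flag
  s2 <- aggregate_summary(frac_fixture(bulk_oc = 40))
  expect_true(attr(s2, "oc_balance_flag"))
})

test_that("replicate averaging happens after sand correction", {
  f1 <- frac_fixture()
  f2 <- frac_fixture(fraction_mass = 2 * c(5, 2, 2, 1),
                     sand_mass = 2 * c(1, 0.5, 0.5, 0))
  avg <- average_fractionations(list(f1, f2))
  # per-run input-mass scaling cancels: averaged corrected fractions equal
  # each run's corrected fractions
  expect_equal(avg$mass_fraction, as.numeric(sand_corrected_fractions(f1)),
               tolerance = 1e-12)
})
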