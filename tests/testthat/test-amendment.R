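test_that("areal soil mass converts units correctly", {
  expect_equal(soil_mass_areal(1.4, 18), 2520, tolerance = 1e-12)
  expect_equal(soil_mass_areal(1.0, 10), 1000, tolerance = 1e-12)
  expect_error(soil_mass_areal(1.4, 0), "positive")
  expect_error(soil_mass_areal(-1, 10), "positive")
})

test_that("rock mass balance reproduces the field schedule arithmetic", {
  sch <- energy_farm_schedule(bulk_density = 1.4)
  # 4 x 50 + 2 x 40 = 280 t/ha over 1.4 g/cm3 x 18 cm = 2520 t/ha soil
  expect_equal(basalt_contribution(sch), 280 / 2800, tolerance = 1e-12)
  # empty schedule
  empty <- amendment_schedule(
    data.frame(year = integer(), rate_t_per_ha = numeric(),
               rock = character()),
    sch$grain_size)
  expect_identical(basalt_contribution(empty), 0)
  # doubling applied mass: strictly increasing, concave
  sch2 <- amendment_schedule(transform(sch$applications,
                                       rate_t_per_ha = 2 * rate_t_per_ha),
                             sch$grain_size, 18, 1.4)
  expect_equal(basalt_contribution(sch2), 560 / 3080, tolerance = 1e-12)
  expect_lt(basalt_contribution(sch2), 2 * basalt_contribution(sch))
})

test_that("B is monotone in applied mass and soil mass", {
  sch <- energy_farm_schedule()
  B <- basalt_contribution(sch)
  expect_true(B >= 0 && B < 1)
  heavier <- amendment_schedule(sch$applications, sch$grain_size, 18, 1.8)
  expect_lt(basalt_contribution(heavier), B)  # more soil dilutes the rock
})

test_that("dilution correction behaves in both modes", {
  expect_identical(dilution_correct(15, 0), 15)
  expect_equal(dilution_correct(15, 0.1), 16.5, tolerance = 1e-12)
  expect_equal(dilution_correct(15, 0.1, mode = "exact"), 15 / 0.9,
               tolerance = 1e-12)
  # linear in C; modes agree to first order in B
  expect_equal(dilution_correct(c(2, 4), 0.1), 2 * dilution_correct(c(1, 2), 0.1))
  B <- 0.01
  expect_lt(abs(dilution_correct(1, B) - dilution_correct(1, B, "exact")),
            2 * B^2)
  expect_error(dilution_correct(15, 1), "\\[0, 1\\)")
  expect_error(dilution_correct(15, -0.1), "\\[0, 1\\)")
})

test_that("per-class allocation conserves mass and aggregates to bulk B", {
  sch <- energy_farm_schedule(bulk_density = 1.4)
  shares <- c(0.5, 0.2, 0.2, 0.1)
  per <- fraction_basalt_contribution(sch, shares)
  expect_equal(sum(per$rock_mass_t_per_ha), 280, tolerance = 1e-12)
  # amended-mass-weighted per-class B reproduces the bulk value exactly
  expect_equal(sum(per$amended_share * per$B_class), attr(per, "bulk_B"),
               tolerance = 1e-12)
  # all-fines rock: everything lands in the <53 um class
  gs <- matrix(c(0, 0, 0, 1), nrow = 1,
               dimnames = list("fines", sieve_classes()))
  fine_sch <- amendment_schedule(
    data.frame(year = 2020, rate_t_per_ha = 50, rock = "fines"), gs)
  pf <- fraction_basalt_contribution(fine_sch, shares)
  expect_equal(pf$rock_mass_t_per_ha, c(0, 0, 0, 50))
  expect_true(all(pf$B_class[1:3] == 0) && pf$B_class[4] > 0)
  expect_error(fraction_basalt_contribution(sch, c(0.5, 0.5, 0.2, -0.2)),
               "shares")
})

test_that("schedule validation enforces the grain-size simplex", {
  gs_bad <- matrix(c(0.1, 0.2, 0.3, 0.3), nrow = 1,
                   dimnames = list("r", sieve_classes()))
  expect_error(amendment_schedule(
    data.frame(year = 2020, rate_t_per_ha = 10, rock = "r"), gs_bad),
    "sum to 1")
})
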