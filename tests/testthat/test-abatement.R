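test_that("modeled abatement follows the two-oxidant exponential law", {
  expect_equal(predict_abatement(0, 0, 1e-4, 1e-10), 0)
  # saturation: highly ozone-reactive compound at a low-dose plant
  expect_equal(round(predict_abatement(1e7, 3e9, 1.3e-6, 2.26e-11), 1),
               100.0)
  # intermediate case with hand-computed exponent 0.0996
  expect_equal(predict_abatement(1e2, 1e9, 2.2e-4, 7.76e-11),
               (1 - exp(-(1e2 * 2.2e-4 + 1e9 * 7.76e-11))) * 100,
               tolerance = 1e-12)
  expect_equal(predict_abatement(1e2, 1e9, 2.2e-4, 7.76e-11), 9.480,
               tolerance = 1e-3)
  expect_error(predict_abatement(-1, 0, 0, 0), ">= 0")
})

test_that("modeled abatement is monotone nondecreasing in every parameter", {
  base <- c(k_o3 = 1e3, k_oh = 5e9, o3_exposure = 2.2e-4,
            oh_exposure = 7.76e-11)
  a0 <- do.call(predict_abatement, as.list(base))
  for (p in names(base)) {
    up <- base; up[p] <- up[p] * 1.5
    expect_gte(do.call(predict_abatement, as.list(up)), a0)
  }
})

test_that("measured abatement applies the half-LOQ rule for censored effluent", {
  expect_equal(measured_abatement(c_in = 100, c_out = 30), 70)
  expect_equal(measured_abatement(c_in = 100, c_out = 100), 0)
  expect_equal(measured_abatement(c_in = 100, censored = TRUE, loq = 10),
               95)
  expect_error(measured_abatement(c_in = 0, c_out = 1), "c_in")
  expect_error(measured_abatement(c_in = 1, censored = TRUE), "loq")
})

test_that("field data generated without noise invert to the model prediction", {
  sc <- read_scenarios()[["Neugut"]]
  ks <- c(slowish = 50, mid = 1e3, fast = 1e5)
  recs <- lapply(names(ks), function(n)
    reactivity_record(n, species_k_o3 = unname(ks[n]), k_oh = 4e9))
  d <- generate_wwtp_dataset(recs, sc, loq = 1e-30, noise_cv = 0,
                             n_days = 1, seed = 1)
  expect_false(any(d$censored))
  meas <- measured_abatement(d$c_in, d$c_out, d$loq, d$censored)
  modeled <- predict_abatement(ks[d$compound_id], 4e9, sc$o3_exposure,
                               sc$oh_exposure)
  expect_equal(meas, unname(modeled), tolerance = 1e-9)
})

test_that("Monte Carlo with zero spreads reproduces the point value exactly", {
  specs <- list(distribution_spec("k_o3", "point", 1e3),
                distribution_spec("k_oh", "normal", 5e9, 0),
                distribution_spec("o3_exposure", "point", 2.2e-4),
                distribution_spec("oh_exposure", "point", 7.76e-11))
  mc <- monte_carlo_abatement(specs, n_draws = 500, seed = 3)
  expect_identical(mc$mc_mean, mc$point_abatement)
  expect_identical(mc$mc_sd, 0)
  expect_equal(unname(mc$interval), rep(mc$point_abatement, 2))
})

test_that("uniform ozone-exposure draws stay within +/- 80% of the center", {
  specs <- list(distribution_spec("k_o3", "point", 1e3),
                distribution_spec("k_oh", "point", 5e9),
                distribution_spec("o3_exposure", "uniform_pm_fraction",
                                  2.2e-4, 0.8),
                distribution_spec("oh_exposure", "point", 7.76e-11))
  mc <- monte_carlo_abatement(specs, n_draws = 1e5, seed = 9)
  drawn <- mc$draws[, "o3_exposure"]
  expect_gte(min(drawn), 0.2 * 2.2e-4)
  expect_lte(max(drawn), 1.8 * 2.2e-4)
  expect_true(mc$interval[1] <= mc$mc_mean && mc$mc_mean <= mc$interval[2])
})

test_that("truncated normal draws are nonnegative and seed-reproducible", {
  specs <- list(distribution_spec("k_o3", "normal", 10, 40),
                distribution_spec("k_oh", "normal", 5e9, 2e9),
                distribution_spec("o3_exposure", "point", 2.2e-4),
                distribution_spec("oh_exposure", "normal", 7.76e-11,
                                  7.76e-11))
  mc1 <- monte_carlo_abatement(specs, n_draws = 2000, seed = 5)
  mc2 <- monte_carlo_abatement(specs, n_draws = 2000, seed = 5)
  expect_true(all(mc1$draws >= 0))
  expect_identical(mc1$draws, mc2$draws)
  expect_false(identical(
    mc1$draws, monte_carlo_abatement(specs, n_draws = 2000, seed = 6)$draws))
})

test_that("Monte Carlo mean is stable across seeds at large draw counts", {
  specs <- list(distribution_spec("k_o3", "normal", 1e3, 100),
                distribution_spec("k_oh", "normal", 5e9, 5e8),
                distribution_spec("o3_exposure", "uniform_pm_fraction",
                                  2.2e-4, 0.8),
                distribution_spec("oh_exposure", "normal", 7.76e-11,
                                  5e-12))
  a <- monte_carlo_abatement(specs, n_draws = 1e5, seed = 1)
  b <- monte_carlo_abatement(specs, n_draws = 1e5, seed = 2)
  expect_lt(abs(a$mc_mean - b$mc_mean), 3 * a$mc_sd / sqrt(1e5) * 2)
})

test_that("a missing parameter specification is rejected", {
  specs <- list(distribution_spec("k_o3", "point", 1e3),
                distribution_spec("k_oh", "point", 5e9),
                distribution_spec("o3_exposure", "point", 2.2e-4))
  expect_error(monte_carlo_abatement(specs, 10, 1), "oh_exposure")
})

test_that("model-field regression recovers exact linear relations", {
  mod <- c(10, 35, 60, 85, 99)
  fit <- compare_model_vs_field(mod, mod)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  off <- compare_model_vs_field(mod, mod + 5)
  expect_equal(off$slope, 1, tolerance = 1e-12)
  expect_equal(off$intercept, 5, tolerance = 1e-10)
  expect_error(compare_model_vs_field(c(1, 2), c(1, 2)), "3 complete")
})

test_that("model_abatement excludes flagged compounds and returns intervals", {
  sc <- read_scenarios()[["Neugut"]]
  recs <- list(
    reactivity_record("parent", species_k_o3 = 1e4, k_o3_sd = 1e3,
                      k_oh = 5e9, k_oh_sd = 5e8),
    reactivity_record("phase1_met", species_k_o3 = 1e3, k_oh = 5e9))
  out <- model_abatement(recs, sc, n_draws = 500, seed = 2,
                         exclude_ids = "phase1_met")
  expect_equal(out$compound_id, "parent")
  expect_true(out$lo95 <= out$mc_mean && out$mc_mean <= out$hi95)
  expect_true(out$point_abatement > 0 && out$point_abatement < 100)
})
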