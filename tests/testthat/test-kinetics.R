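test_that("log depletions use the zero-dose reference per replicate", {
  e <- noiseless_experiment(k_target = 500, k_comp = 1000)
  pts <- log_depletions(e, "tgt")
  # A = A0 at dose 0 is excluded; depletion matches -k * exposure
  expect_true(all(pts$dose_index > 0))
  expect_equal(pts$log_depletion,
               -500 * unname(e$vial_exposures[as.character(pts$dose_index)]),
               tolerance = 1e-12)
  expect_equal(pts$abatement_fraction, 1 - exp(pts$log_depletion))
  expect_error(log_depletions(e, "nope"), "not present")
})

test_that("log depletion arithmetic is exact on hand values", {
  df <- data.frame(dose_index = c(0L, 1L), replicate = 1L,
                   compound_id = "x", area = c(100, 50), area0 = 100)
  e <- structure(list(data = df, competitor_k = NULL),
                 class = "experiment_table")
  pts <- log_depletions(e, "x")
  expect_equal(pts$log_depletion, log(0.5), tolerance = 1e-12)
  expect_equal(pts$abatement_fraction, 0.5, tolerance = 1e-12)
})

test_that("abatement window keeps 10-90% and drops the rest", {
  pts <- data.frame(dose_index = 1:5, replicate = 1,
                    log_depletion = log(1 - c(0.05, 0.10, 0.50, 0.90, 0.95)),
                    abatement_fraction = c(0.05, 0.10, 0.50, 0.90, 0.95))
  kept <- abatement_window_filter(pts)
  expect_equal(kept$abatement_fraction, c(0.10, 0.50, 0.90))
})

test_that("pair regression recovers the rate-constant ratio", {
  e <- noiseless_experiment(k_target = 500, k_comp = 1000)
  tp <- log_depletions(e, "tgt"); cp <- log_depletions(e, "cmp")
  reg <- fit_pair(tp, cp, 1000, "tgt", "cmp")
  expect_equal(reg$slope, 0.5, tolerance = 1e-10)
  expect_equal(reg$intercept, 0, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  expect_equal(reg$k_estimate, 500, tolerance = 1e-7)
  # a compound against itself: slope 1
  self <- fit_pair(cp, cp, 1000, "cmp", "cmp")
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_equal(self$k_estimate, 1000, tolerance = 1e-9)
})

test_that("regression matches the brute-force OLS oracle", {
  set.seed(21)
  for (i in 1:10) {
    k_t <- 10^stats::runif(1, 1, 4)
    k_c <- k_t * 10^stats::runif(1, -0.8, 0.8)
    mix <- mixture_spec(data.frame(compound_id = "t", k_true = k_t))
    e <- generate_competition_experiment(
      mix, list(simple_record("c", k_c)), noise_cv = 0.05,
      seed = 100 + i)
    tp <- log_depletions(e, "t"); cp <- log_depletions(e, "c")
    reg <- fit_pair(tp, cp, k_c, "t", "c")
    # rebuild the matched in-window point set and fit by direct summation
    tw <- abatement_window_filter(tp); cw <- abatement_window_filter(cp)
    m <- merge(tw, cw, by = c("dose_index", "replicate"))
    oracle <- ols_brute(m$log_depletion.y, m$log_depletion.x)
    expect_equal(reg$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(reg$intercept, oracle$intercept, tolerance = 1e-10)
  }
})

test_that("swapping target and competitor inverts the slope on noiseless data", {
  e <- noiseless_experiment(k_target = 700, k_comp = 2000)
  tp <- log_depletions(e, "tgt"); cp <- log_depletions(e, "cmp")
  ab <- fit_pair(tp, cp, 2000, "tgt", "cmp")
  ba <- fit_pair(cp, tp, 700, "cmp", "tgt")
  expect_equal(ab$slope * ba$slope, 1, tolerance = 1e-9)
})

test_that("each QC gate trips individually on constructed regressions", {
  expect_true(qc_evaluate(make_reg())$pass)
  v <- qc_evaluate(make_reg(n_points = 9L))
  expect_false(v$pass); expect_false(v$gates[["n_points"]])
  expect_true(all(v$gates[c("r_squared", "intercept", "slope")]))
  v <- qc_evaluate(make_reg(r_squared = 0.85))
  expect_false(v$pass); expect_false(v$gates[["r_squared"]])
  v <- qc_evaluate(make_reg(slope = 0.05))
  expect_false(v$pass); expect_false(v$gates[["slope"]])
  v <- qc_evaluate(make_reg(slope = 20))
  expect_false(v$pass); expect_false(v$gates[["slope"]])
  # boundary slopes are inside the gate
  expect_true(qc_evaluate(make_reg(slope = 0.1))$gates[["slope"]])
  expect_true(qc_evaluate(make_reg(slope = 10))$gates[["slope"]])
  # intercept rule as printed: |intercept| < 10 * |slope|
  v <- qc_evaluate(make_reg(slope = 0.5, intercept = 6))
  expect_false(v$pass); expect_false(v$gates[["intercept"]])
  expect_true(qc_evaluate(make_reg(slope = 0.5, intercept = 4))$pass)
  # strict variant: |intercept| < 0.1 * |slope|
  v <- qc_evaluate(make_reg(slope = 0.5, intercept = 0.2),
                   strict_intercept = TRUE)
  expect_false(v$gates[["intercept"]])
  expect_true(qc_evaluate(make_reg(slope = 0.5, intercept = 0.04),
                          strict_intercept = TRUE)$pass)
  # both readings are reported either way
  expect_true(v$values$intercept_loose)
  expect_false(v$values$intercept_strict)
})

test_that("competitor averaging reports mean and standard deviation", {
  # two competitors engineered to give slightly different estimates:
  # verify against a hand-built experiment where truth is exact
  mix <- mixture_spec(data.frame(compound_id = "t", k_true = 500))
  comps <- list(simple_record("c1", 480 / 0.5), simple_record("c2",
                                                              520 / 0.5))
  # noiseless: estimates are 500 from both (exact first-order), so instead
  # check the averaging arithmetic directly on the documented contract
  est <- estimate_k(generate_competition_experiment(mix, comps,
                                                    noise_cv = 0, seed = 2),
                    "t")
  expect_equal(est$k_app, 500, tolerance = 1e-9)
  expect_equal(est$k_sd, 0, tolerance = 1e-6)
  expect_equal(est$n_competitors, 2L)
  expect_identical(est$status, "ok")
})

test_that("targets without a competitor within one order fail gate (iv)", {
  mix <- mixture_spec(data.frame(compound_id = "t", k_true = 100))
  comps <- list(simple_record("c1", 1e4))
  e <- generate_competition_experiment(mix, comps, noise_cv = 0, seed = 3,
                                       dose_design = "members")
  est <- estimate_k(e, "t", window = "target")
  expect_identical(est$status, "failed")
  qc <- est$regressions[["c1"]]$qc
  expect_false(qc$gates[["slope"]])
})

test_that("unreactive targets are flagged below determinable", {
  mix <- mixture_spec(data.frame(compound_id = "inert", k_true = 1e-4),
                      reactivity_window = c(1e-5, 1))
  comps <- list(simple_record("c1", 1e3))
  # doses tuned to the competitor panel: the inert target barely abates
  expo <- exp(seq(log(-log(0.9) / 1e3), log(-log(0.02) / 1e3),
                  length.out = 12))
  e <- generate_competition_experiment(mix, comps, noise_cv = 0, seed = 5,
                                       exposures = expo)
  est <- estimate_k(e, "inert", window = "target")
  expect_identical(est$status, "below_determinable")
})

test_that("noisy estimates recover truth within the reported uncertainty", {
  mix <- mixture_spec(data.frame(compound_id = "t", k_true = 800))
  comps <- list(simple_record("c1", 500), simple_record("c2", 1500))
  e <- generate_competition_experiment(mix, comps, noise_cv = 0.05,
                                       seed = 42)
  est <- estimate_k(e, "t")
  expect_identical(est$status, "ok")
  expect_lt(abs(log10(est$k_app / 800)), 0.05)
  expect_lt(abs(est$k_app - 800), 2 * est$k_se + 2 * est$k_sd + 1e-9)
})
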