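test_that("pCBA depletion inverts to the hydroxyl-radical exposure", {
  expect_equal(oh_exposure_from_pcba(1)$exposure, 0)
  expect_equal(oh_exposure_from_pcba(exp(-0.52))$exposure, 1e-10,
               tolerance = 1e-12)
  res <- oh_exposure_from_pcba(0.88912)
  expect_equal(res$exposure, -log(0.88912) / 5.2e9, tolerance = 1e-12)
  expect_equal(res$exposure, 2.259e-11, tolerance = 1e-3)
  expect_error(oh_exposure_from_pcba(1.2), "\\(0, 1\\]")
  expect_error(oh_exposure_from_pcba(0), "\\(0, 1\\]")
})

test_that("pCBA assay and exposure recovery are exact inverses at zero noise", {
  for (true_exp in c(2.26e-11, 7.76e-11, 2.24e-10)) {
    f <- generate_pcba_assay(true_exp, noise_cv = 0, n_replicates = 3,
                             seed = 1)
    rec <- oh_exposure_from_pcba(f)
    expect_equal(rec$exposure, true_exp, tolerance = 1e-12)
    expect_equal(rec$sd, 0)
  }
})

test_that("scavenging shares sum to 100 and follow k*[S] proportions", {
  consts <- data.frame(species = c("DOM", "bicarbonate", "carbonate",
                                   "nitrite", "bromide"),
                       basis = c("per_mg_C", rep("per_M", 4)),
                       k = c(2.5e4, 8.5e6, 3.9e8, 1.0e10, 1.1e10))
  # single scavenger: 100%
  s1 <- scavenging_shares(
    data.frame(species = "DOM", concentration = 5, unit = "mg_C_per_L"),
    ph = 7, constants = consts)
  expect_equal(s1$share_pct, 100)
  # two scavengers with equal k*[S]: 50/50
  consts2 <- data.frame(species = c("nitrite", "bromide"),
                        basis = "per_M", k = c(1e10, 1e10))
  s2 <- scavenging_shares(
    data.frame(species = c("nitrite", "bromide"),
               concentration = c(1e-6, 1e-6),
               unit = "mol_per_L"),
    ph = 7, constants = consts2)
  expect_equal(s2$share_pct, c(50, 50))
  # full inventory against an independent term-by-term hand summation
  scav <- data.frame(
    species = c("DOM", "alkalinity", "nitrite", "bromide"),
    concentration = c(6.6, 4.2, 23.9, 0.06),
    unit = c("mg_C_per_L", "mmol_per_L", "ug_N_per_L", "mg_per_L"))
  sh <- scavenging_shares(scav, ph = 8.0, constants = consts)
  r <- 10^(8.0 - 10.33)
  hco3 <- 4.2e-3 / (1 + 2 * r); co3 <- hco3 * r
  terms <- c(DOM = 2.5e4 * 6.6,
             bicarbonate = 8.5e6 * hco3,
             carbonate = 3.9e8 * co3,
             nitrite = 1.0e10 * 23.9e-6 / 14.0067,
             bromide = 1.1e10 * 0.06e-3 / 79.904)
  expect_equal(sum(sh$share_pct), 100, tolerance = 1e-9)
  expect_equal(sh$share_pct[match(names(terms), sh$species)],
               unname(terms / sum(terms) * 100), tolerance = 1e-9)
  # dissolved organic matter dominates the budget in this inventory
  expect_gt(sh$share_pct[sh$species == "DOM"], 50)
})

test_that("carbonate split follows the second dissociation equilibrium", {
  consts <- data.frame(species = c("bicarbonate", "carbonate"),
                       basis = "per_M", k = c(8.5e6, 3.9e8))
  alk <- data.frame(species = "alkalinity", concentration = 2,
                    unit = "mmol_per_L")
  # far below pKa2: all alkalinity is bicarbonate
  low <- scavenging_shares(alk, ph = 6, constants = consts)
  expect_equal(low$concentration_molar[low$species == "bicarbonate"],
               2e-3, tolerance = 1e-3)
  expect_lt(low$concentration_molar[low$species == "carbonate"] / 2e-3,
            1e-4)
  # at pH = pKa2: equal molar amounts; carbonate carries twice the charge,
  # so the equivalents split carbonate:bicarbonate is 2:1
  at <- scavenging_shares(alk, ph = 10.33, constants = consts)
  hco3 <- at$concentration_molar[at$species == "bicarbonate"]
  co3 <- at$concentration_molar[at$species == "carbonate"]
  expect_equal(co3 / hco3, 1, tolerance = 1e-12)
  expect_equal((2 * co3) / hco3, 2, tolerance = 1e-12)
  expect_equal(hco3 + 2 * co3, 2e-3, tolerance = 1e-12) # ANC conserved
})

test_that("ozone stock molarity follows Beer-Lambert", {
  expect_equal(ozone_stock_concentration(3.2, 1, 3200), 1e-3)
  expect_equal(ozone_stock_concentration(6.4), 2e-3) # typical stock range
  expect_equal(ozone_stock_concentration(0.64, path_length_cm = 2), 1e-4)
  expect_error(ozone_stock_concentration(-1), "absorbance")
})

test_that("dose-exposure correlation is exact on power-law references", {
  # two points: prediction interpolates through them exactly
  ref <- data.frame(dose = c(0.44, 0.58), exposure = c(2.2e-4, 2.8e-4))
  fit <- fit_dose_exposure_correlation(ref, 0.44)
  expect_equal(fit$exposure, 2.2e-4, tolerance = 1e-12)
  # power-law round trip: exposure = c * dose^b recovered to 1e-10
  b <- 1.7; cc <- 3.2e-4
  ref2 <- data.frame(dose = c(0.1, 0.2, 0.4, 0.8),
                     exposure = cc * c(0.1, 0.2, 0.4, 0.8)^b)
  fit2 <- fit_dose_exposure_correlation(ref2, 0.3)
  expect_equal(fit2$slope, b, tolerance = 1e-10)
  expect_equal(exp(fit2$intercept), cc, tolerance = 1e-10)
  expect_equal(fit2$exposure, cc * 0.3^b, tolerance = 1e-10)
  # constant exposures: constant prediction
  ref3 <- data.frame(dose = c(0.1, 0.5, 1), exposure = rep(1e-4, 3))
  expect_equal(fit_dose_exposure_correlation(ref3, 0.25)$exposure, 1e-4,
               tolerance = 1e-12)
  expect_error(fit_dose_exposure_correlation(ref[1, ], 0.3), "2 reference")
})

test_that("bundled plant scenarios load with exposures and scavengers", {
  sc <- read_scenarios()
  expect_named(sc, c("Altenrhein", "Neugut", "Werdhoelzli"))
  expect_equal(sc$Neugut$o3_exposure, 2.2e-4)
  expect_equal(sc$Neugut$oh_exposure, 7.76e-11)
  expect_equal(sc$Altenrhein$o3_exposure, 1.3e-6)
  expect_equal(sc$Werdhoelzli$specific_ozone_dose, 0.6)
  for (s in sc) {
    expect_s3_class(s, "wwtp_scenario")
    shares <- scavenging_shares(s$scavengers, ph = s$ph)
    expect_equal(sum(shares$share_pct), 100, tolerance = 1e-9)
  }
})
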