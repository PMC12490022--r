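test_that("classification bands are exhaustive and mutually exclusive", {
  set.seed(41)
  ratios <- c(10^stats::runif(200, -6, 6), 0.5, 2, 1)
  for (r in ratios) {
    parent <- simple_record("p", 1000)
    met <- simple_record("m", 1000 * r)
    pr <- reactivity_ratio_class(parent, met)
    hits <- c(faster = r > 2, slower = r < 0.5,
              similar = r >= 0.5 && r <= 2)
    expect_equal(sum(hits), 1)
    expect_identical(pr$classification, names(which(hits)))
  }
})

test_that("ratio computation uses apparent constants and flags the floor", {
  parent <- simple_record("p", 1000)
  expect_identical(reactivity_ratio_class(parent,
                                          simple_record("m", 1000))$classification,
                   "similar")
  # speciation-driven ratio: neutral-amine compound with two pKa values
  k_n <- 5.5e5
  met <- reactivity_record("m", species_k_o3 = c(0, k_n), pka_values = 9.14)
  par2 <- reactivity_record("p2", species_k_o3 = c(0, k_n),
                            pka_values = 11.8)
  pr <- reactivity_ratio_class(par2, met)
  expect_identical(pr$classification, "faster")
  expect_equal(pr$log10_ratio, 2.6569, tolerance = 1e-4)
  # below-determinable metabolite: floor in the numerator
  bd <- reactivity_record("m2", below_determinable = TRUE)
  p3 <- simple_record("p3", 3.2e4)
  pr2 <- reactivity_ratio_class(p3, bd)
  expect_true(pr2$floored)
  expect_equal(pr2$ratio, 0.1 / 3.2e4, tolerance = 1e-12)
  expect_identical(pr2$classification, "slower")
  # configurable floor
  pr3 <- reactivity_ratio_class(p3, bd, floor = 0.05)
  expect_equal(pr3$ratio, 0.05 / 3.2e4, tolerance = 1e-12)
  expect_error(reactivity_ratio_class(bd, bd), "undefined")
})

test_that("flowchart rules give the expected directions per reaction class", {
  fp <- function(rc, sr, ...) {
    flowchart_predict(metabolite_pair("p", "m", rc, sr), ...)
  }
  v <- fp("aromatic_hydroxylation", "creates_new_reactive_group")
  expect_identical(v$direction, "faster")
  v <- fp("aromatic_hydroxylation", "creates_new_reactive_group",
          dominant_other_site = TRUE)
  expect_identical(v$direction, "similar")
  expect_identical(fp("alkyl_hydroxylation",
                      "remote_from_most_reactive_site")$direction, "similar")
  v <- fp("n_oxidation", "at_most_reactive_site")
  expect_identical(v$direction, "slower")
  expect_identical(v$magnitude_hint, "ge_2_orders")
  expect_identical(fp("n_oxidation",
                      "remote_from_most_reactive_site")$direction, "similar")
  expect_identical(fp("carboxylic_acid_formation",
                      "remote_from_most_reactive_site")$direction, "similar")
  v <- fp("carboxylic_acid_formation", "remote_from_most_reactive_site",
          conjugated_to_olefin = TRUE)
  expect_identical(v$direction, "faster")
  expect_identical(v$magnitude_hint, "about_1_order")
  expect_identical(fp("acetylation", "at_most_reactive_site")$direction,
                   "slower")
  expect_identical(fp("sulfation", "at_most_reactive_site")$direction,
                   "slower")
  expect_identical(fp("glucuronidation", "at_most_reactive_site")$direction,
                   "slower")
  expect_identical(fp("glucuronidation",
                      "remote_from_most_reactive_site")$direction, "similar")
  v <- fp("n_dealkylation", "at_most_reactive_site")
  expect_identical(v$direction, "slower")
  expect_identical(v$magnitude_hint, "up_to_2_orders")
  expect_identical(fp("o_dealkylation",
                      "creates_new_reactive_group")$direction, "faster")
  expect_identical(fp("o_dealkylation", "creates_new_reactive_group",
                      dominant_other_site = TRUE)$direction, "similar")
  # uncovered class: indeterminate with no magnitude, never an error
  v <- fp("glutathione_conjugation", "remote_from_most_reactive_site")
  expect_identical(v$direction, "indeterminate")
  expect_identical(v$magnitude_hint, "none")
})

test_that("group summary reports n, median and range of log ratios", {
  mk <- function(r, rc) {
    pr <- reactivity_ratio_class(simple_record("p", 1000),
                                 simple_record("m", 1000 * r),
                                 pair = metabolite_pair(
                                   "p", "m", rc, "creates_new_reactive_group"))
    pr
  }
  # hydroxylated aromatics spanning 40- to 70000-fold
  ratios <- list(mk(40, "aromatic_hydroxylation"),
                 mk(1000, "aromatic_hydroxylation"),
                 mk(70000, "aromatic_hydroxylation"),
                 mk(0.8, "alkyl_hydroxylation"))
  s <- pair_group_summary(ratios)
  arow <- s[s$reaction_class == "aromatic_hydroxylation", ]
  expect_equal(arow$n, 3)
  expect_equal(arow$min_log10_ratio, log10(40), tolerance = 1e-12)
  expect_equal(arow$min_log10_ratio, 1.602, tolerance = 1e-3)
  expect_equal(arow$max_log10_ratio, log10(70000), tolerance = 1e-12)
  expect_equal(arow$max_log10_ratio, 4.845, tolerance = 1e-3)
  expect_equal(arow$frac_faster, 1)
  # classes with no pairs are absent
  expect_false("n_oxidation" %in% s$reaction_class)
  # single pair: its own statistics
  s1 <- pair_group_summary(ratios[4])
  expect_equal(s1$median_log10_ratio, log10(0.8), tolerance = 1e-12)
  expect_equal(s1$frac_similar, 1)
})

test_that("every curated worked pair gets the reference direction", {
  tab <- read_pairs_table(system.file("extdata", "worked_pairs.csv",
                                      package = "ozonekin"))
  expect_gt(nrow(tab), 20)
  verdicts <- vapply(seq_len(nrow(tab)), function(i)
    flowchart_predict(tab$pair[[i]],
                      dominant_other_site = tab$dominant_other_site[i],
                      conjugated_to_olefin = tab$conjugated_to_olefin[i])$direction,
    character(1))
  expect_identical(verdicts, tab$expected_direction)
})
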