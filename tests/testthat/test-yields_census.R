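# The 0 hr APF MARCM solution, used as the running example.
freqs_0h <- lineage_frequencies(0.63, 0.13, 0.05, 0.19)

test_that("double-lineage composition inside pure categories", {
  ec <- category_pair_composition(freqs_0h, 0.3, "EC_only")
  expect_near(ec$w_same, 0.624, 0.001)
  expect_near(ec$w_cross, 0.376, 0.001)
  expect_near(ec$lineages_per_ovariole, 1.44, 0.005)
  fsc <- category_pair_composition(freqs_0h, 0.3, "FSC_only")
  expect_near(fsc$w_same, 0.116, 0.001)
  expect_near(fsc$w_cross, 0.884, 0.001)
  expect_near(fsc$lineages_per_ovariole, 1.08, 0.005)
  # all-single: exactly one lineage per category ovariole
  expect_equal(category_pair_composition(freqs_0h, 1,
                                         "EC_only")$lineages_per_ovariole, 1)
  expect_error(
    category_pair_composition(lineage_frequencies(0, 1, 0, 0), 0.3, "EC_only"),
    "undefined composition")
})

test_that("per-lineage yields divide observed means by lineage multiplicity", {
  expect_near(per_lineage_yield(2.53, 1.44), 1.76, 0.005)
  expect_near(per_lineage_yield(14 / 3, 1.08), 4.32, 0.005)
  expect_equal(per_lineage_yield(3.7, 1), 3.7)
  expect_error(per_lineage_yield(2, 0), "> 0")
})

test_that("EC/FSC yields by subtraction reproduce the published accounting", {
  table0 <- load_experiment("marcm_0h")
  r0 <- run_full_census(table0, sigma = 0.3)
  expect_near(r0$yields$ec_per_ec_lineage, 1.76, 0.1)
  expect_near(r0$yields$fsc_per_fsc_lineage, 4.32, 0.1)
  expect_near(r0$yields$ec_per_ecfsc_lineage, 3.15, 0.1)
  expect_near(r0$yields$fsc_per_ecfsc_lineage, 3.47, 0.1)
  expect_equal(r0$total_lineages, 166.6)

  # multicolor accounting, from the worked observation vector (the published
  # raw row lists one more FC-only ovariole than the worked chain used)
  smc <- solve_lineage_frequencies(aggregated_frequencies(0.50, 0.154, 0.077),
                                   0.7)
  base <- per_lineage_yields(
    per_lineage_yield(38 / 13, category_pair_composition(
      smc, 0.7, "EC_only")$lineages_per_ovariole),
    per_lineage_yield(4, category_pair_composition(
      smc, 0.7, "FSC_only")$lineages_per_ovariole))
  ymc <- ecfsc_yields_by_subtraction(load_experiment("multicolor"), smc, 0.7,
                                     base)
  expect_near(ymc$ec_per_ecfsc_lineage, 2.79, 0.1)
  expect_near(ymc$fsc_per_ecfsc_lineage, 2.27, 0.1)

  # the accounting identity holds exactly: attributed EC output sums back
  # to the experiment total
  L <- r0$total_lineages
  f <- r0$freqs
  y <- r0$yields
  expect_equal(L * (f$p_ec * y$ec_per_ec_lineage +
                    f$p_ecfsc * y$ec_per_ecfsc_lineage),
               table0$total_ec, tolerance = 1e-9)
  expect_equal(L * (f$p_fsc * y$fsc_per_fsc_lineage +
                    f$p_ecfsc * y$fsc_per_ecfsc_lineage),
               table0$total_fsc, tolerance = 1e-9)
})

test_that("subtraction guards against impossible totals", {
  table <- load_experiment("marcm_0h")
  yields <- per_lineage_yields(ec_per_ec_lineage = 50, fsc_per_fsc_lineage = 4)
  expect_error(ecfsc_yields_by_subtraction(table, freqs_0h, 0.3, yields),
               "negative")
})

test_that("precursor census conserves type counts and FSC output", {
  y <- per_lineage_yields(1.76, 4.32, 3.15, 3.47)
  census <- precursor_census(freqs_0h, y)
  expect_equal(census$n_ec + census$n_ecfsc + census$n_fsc + census$n_fc,
               census$n_total, tolerance = 1e-9)
  # implied FSC output per germarium is exactly the normalization constant
  expect_equal(census$n_ecfsc * 3.47 + census$n_fsc * 4.32, 16,
               tolerance = 1e-9)
  # degenerate: a single type producing 16 FSCs per lineage
  one <- precursor_census(lineage_frequencies(0, 1, 0, 0),
                          per_lineage_yields(0, 0, 2, 16))
  expect_equal(one$n_total, 1)
  expect_error(precursor_census(lineage_frequencies(1, 0, 0, 0),
                                per_lineage_yields(2, 0, 1, 0)),
               "no FSC production")
})

test_that("per-germarium production estimates match the published table", {
  p2 <- germarium_production(20, 37, 69)
  expect_near(c(p2$r1_made, p2$r2a_made, p2$ec_made), c(4.6, 8.6, 13.2), 0.05)
  p6 <- germarium_production(356, 253, 295)
  expect_near(c(p6$r1_made, p6$r2a_made, p6$ec_made), c(19.3, 13.7, 33.0), 0.05)
  expect_equal(germarium_production(0, 0, 10)$ec_made, 0)
  expect_equal(p2$ec_made, p2$r1_made + p2$r2a_made, tolerance = 1e-9)
  expect_error(germarium_production(1, 1, 0), "z_fsc")

  prod <- table2_production(load_production_totals())
  expect_near(prod$ec_made[prod$days_before_eclosion == 4], 28.2, 0.05)
})

test_that("non-dividing EC precursors from the drop in EC production", {
  early <- germarium_production(356, 253, 295)  # ~33 ECs made per germarium
  late3 <- germarium_production(41, 46, 93)     # ~15 at -3d
  expect_near(nondividing_ec_estimate(early, late3), 18, 0.1)
  late4 <- germarium_production(156, 80, 134)   # ~28.2 at -4d
  expect_near(nondividing_ec_estimate(early, late4), 4.8, 0.1)
  expect_equal(nondividing_ec_estimate(early, early), 0)
  expect_warning(nondividing_ec_estimate(late3, early), "negative")
})
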