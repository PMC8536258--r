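test_that("forward model matches exhaustive pair enumeration", {
  # spot value from enumeration of the 0 hr APF MARCM solution
  f <- lineage_frequencies(0.63, 0.13, 0.05, 0.19)
  fwd <- forward_category_frequencies(f, 0.3)
  expect_near(fwd$f_ec, 0.634, 0.001)
  expect_near(fwd$f_fc, 0.250, 0.001)
  expect_near(fwd$f_ecfc, 0.168, 0.001)
  # oracle equivalence over random frequency vectors and sigmas
  set.seed(5)
  for (i in 1:25) {
    freqs <- random_freqs()
    sigma <- runif(1)
    fwd <- forward_category_frequencies(freqs, sigma)
    oracle <- enum_category_frequencies(freqs, sigma)
    for (nm in c("f_ec", "f_fc", "f_fsc", "f_ecfc")) {
      expect_near(fwd[[nm]], oracle[[nm]], 1e-12)
    }
  }
})

test_that("forward model limiting cases", {
  f <- lineage_frequencies(0.2, 0.3, 0.4, 0.1)
  one <- forward_category_frequencies(f, 1)  # all single: identity
  expect_equal(c(one$f_ec, one$f_fc, one$f_fsc, one$f_ecfc),
               c(0.2, 0.1, 0.4, 0))
  pure <- forward_category_frequencies(lineage_frequencies(1, 0, 0, 0), 0)
  expect_equal(c(pure$f_ec, pure$f_fc, pure$f_fsc, pure$f_ecfc), c(1, 0, 0, 0))
})

test_that("deconvolution reproduces the published solutions", {
  # 0 hr APF MARCM, sigma = 0.3
  s0 <- solve_lineage_frequencies(aggregated_frequencies(0.63, 0.25, 0.03), 0.3)
  expect_near(s0$p_ec, 0.63, 0.01)
  expect_near(s0$p_ecfsc, 0.13, 0.01)
  expect_near(s0$p_fsc, 0.050, 0.01)
  expect_near(s0$p_fc, 0.19, 0.01)
  # 36 hr APF MARCM, all doubles
  s36 <- solve_lineage_frequencies(aggregated_frequencies(0.645, 0.529, 0.033), 0)
  expect_near(s36$p_ec, 0.51, 0.01)
  expect_near(s36$p_ecfsc, 0.07, 0.01)
  expect_near(s36$p_fsc, 0.041, 0.01)
  expect_near(s36$p_fc, 0.38, 0.01)
  # multicolor, sigma = 0.7; p_ecfsc is the complement of the exact
  # components, which differs from the published complement-of-rounded 0.245
  smc <- solve_lineage_frequencies(aggregated_frequencies(0.50, 0.154, 0.077), 0.7)
  expect_near(smc$p_ec, 0.52, 0.01)
  expect_near(smc$p_fsc, 0.095, 0.01)
  expect_near(smc$p_fc, 0.14, 0.01)
  expect_equal(smc$p_ecfsc, 1 - smc$p_ec - smc$p_fsc - smc$p_fc,
               tolerance = 1e-12)
  expect_near(smc$p_ecfsc, 0.232, 0.001)
})

test_that("solve is the exact inverse of the forward model", {
  set.seed(17)
  for (i in 1:40) {
    freqs <- random_freqs()
    sigma <- runif(1)
    obs <- forward_category_frequencies(freqs, sigma)
    back <- solve_lineage_frequencies(obs, sigma)
    for (nm in c("p_ec", "p_ecfsc", "p_fsc", "p_fc")) {
      expect_near(back[[nm]], freqs[[nm]], 1e-8)
    }
  }
})

test_that("solved p_fsc is monotone in the observed FSC-only frequency", {
  f_fsc_grid <- seq(0.005, 0.2, by = 0.005)
  solved <- sapply(f_fsc_grid, function(ff) {
    solve_lineage_frequencies(aggregated_frequencies(0.5, 0.2, ff), 0.3)$p_fsc
  })
  expect_true(all(diff(solved) > 0))
})

test_that("infeasible observations raise named errors", {
  expect_error(
    solve_lineage_frequencies(aggregated_frequencies(1, 1, 0.6), 0.5),
    "infeasible")
  expect_error(solve_all_double_ecfc_anchored(0, 0.2, 0), "infeasible")
  expect_error(lineage_frequencies(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("EC+FC-anchored all-double variant solves the category-exclusive system", {
  s <- solve_all_double_ecfc_anchored(0.3836, 0.0959, 0.0137)
  expect_near(s$p_ec, 0.619, 0.001)
  expect_near(s$p_fc, 0.0775, 0.001)
  expect_near(s$p_fsc, 0.0629, 0.001)
  expect_near(s$p_ecfsc, 0.240, 0.001)
  # forced by complement when only two classes are populated
  s2 <- solve_all_double_ecfc_anchored(0.25, 0, 0)
  expect_equal(c(s2$p_ec, s2$p_ecfsc, s2$p_fsc, s2$p_fc), c(0.5, 0.5, 0, 0))
  expect_equal(solve_all_double_ecfc_anchored(0.3836, 0.0959, 0)$p_fsc, 0)
})

test_that("sigma grid estimation minimizes the EC+FC residual", {
  obs <- aggregated_frequencies(0.63, 0.25, 0.03, 0.163)
  est <- estimate_single_fraction(obs)
  expect_equal(est$sigma, 0.30)
  expect_equal(est$mode, "grid_estimated")
  # winning residual is the grid minimum (brute-force check of the table)
  grid <- est$grid
  expect_equal(est$residual, min(grid$residual[grid$feasible]))
  # every feasible grid row's prediction agrees with the forward model
  for (i in which(grid$feasible)) {
    f <- solve_lineage_frequencies(obs, grid$sigma[i])
    expect_near(grid$predicted_f_ecfc[i],
                forward_category_frequencies(f, grid$sigma[i])$f_ecfc, 1e-9)
  }
})

test_that("sigma estimation edge cases", {
  # no EC+FC ovarioles at all: doubles are unnecessary, sigma = 1
  obs0 <- aggregated_frequencies(0.6, 0.3, 0.05, 0)
  expect_equal(estimate_single_fraction(obs0)$sigma, 1)
  # ties break toward larger sigma: with p_fc = 0 every sigma predicts 0
  tie <- aggregated_frequencies(0.6, 0, 0.2, 0)
  expect_equal(estimate_single_fraction(tie)$sigma, 1)
  expect_error(estimate_single_fraction(aggregated_frequencies(0.5, 0.2, 0.1)),
               "f_ecfc")
  expect_error(estimate_single_fraction(obs0, grid_step = 0.03), "evenly")
})
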