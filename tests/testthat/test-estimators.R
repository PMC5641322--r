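test_that("printed headline rates are internally consistent", {
  # 15NO2- treatment slopes at undiluted label: A = 3.5, D = 0.7
  est <- estimate_rates_nitrite_label(production_rates(3.5, 0.7),
                                      labeled_fraction(F_nitrite = 1))
  expect_equal(est$total, 4.2, tolerance = 1e-12)
  expect_equal(est$contribution, 3.5 / 4.2, tolerance = 1e-12)
  expect_equal(round(100 * est$contribution), 83)
})

test_that("nitrite-label estimator handles diluted label and null input", {
  # forward(A = 0, D = 4, Fn = 0.5) gives (P29, P30) = (2, 1)
  F <- labeled_fraction(F_nitrite = 0.5)
  est <- estimate_rates_nitrite_label(production_rates(2, 1), F)
  expect_equal(est$anammox, 0, tolerance = 1e-12)
  expect_equal(est$denitrification, 4, tolerance = 1e-12)

  est0 <- estimate_rates_nitrite_label(
    production_rates(0, 0, se_P29 = 0.1, se_P30 = 0.1, df = 13), F)
  expect_equal(est0$anammox, 0)
  expect_false(est0$detected_A)
  expect_false(est0$detected_D)

  expect_error(estimate_rates_nitrite_label(production_rates(1, 1),
                                            labeled_fraction(F_nitrite = 0)),
               "not identifiable")
})

test_that("delta-method errors follow the linear slope combination", {
  Fn <- 0.5
  se29 <- 0.3; se30 <- 0.2
  P <- production_rates(2, 1, se_P29 = se29, se_P30 = se30, df = 13)
  est <- estimate_rates_nitrite_label(P, labeled_fraction(F_nitrite = Fn))
  expect_equal(est$se_D, se30 / Fn^2)
  expect_equal(est$se_A,
               sqrt((se29 / Fn)^2 + (2 * (1 - Fn) / Fn^2 * se30)^2))
  # shared P30 dependence: se_total < se_A + se_D
  expect_lt(est$se_total, est$se_A + est$se_D)
})

test_that("negative anammox estimates are reported, flagged, never truncated", {
  est <- estimate_rates_nitrite_label(
    production_rates(0.1, 1, se_P29 = 0.05, se_P30 = 0.05, df = 13),
    labeled_fraction(F_nitrite = 0.5))
  expect_lt(est$anammox, 0)
  expect_false(est$detected_A)
  expect_match(est$warnings, "negative anammox", all = FALSE)
  expect_match(est$warnings, "outside", all = FALSE)
  # with the clamp enabled the contribution is pulled into [0, 1], flagged
  est2 <- estimate_rates_nitrite_label(
    production_rates(0.1, 1, se_P29 = 0.05, se_P30 = 0.05, df = 13),
    labeled_fraction(F_nitrite = 0.5), clamp_contribution = TRUE)
  expect_equal(est2$contribution, 0)
  expect_match(est2$warnings, "clamped", all = FALSE)
})

test_that("ammonium-label estimator recovers A and flags model violations", {
  expect_equal(estimate_rate_ammonium_label(
    production_rates(4.7, 0), labeled_fraction(F_ammonium = 1))$anammox, 4.7)
  expect_equal(estimate_rate_ammonium_label(
    production_rates(2.5, 0), labeled_fraction(F_ammonium = 0.625))$anammox, 4)
  expect_equal(estimate_rate_ammonium_label(
    production_rates(0, 0), labeled_fraction(F_ammonium = 1))$anammox, 0)

  est <- estimate_rate_ammonium_label(production_rates(4.7, 0),
                                      labeled_fraction(F_ammonium = 1))
  expect_true(is.na(est$denitrification))
  expect_true(is.na(est$contribution))

  # significant 30N2 in the 15NH4+ treatment contradicts unlabeled nitrite
  P <- production_rates(4.7, 0.5, se_P29 = 0.1, se_P30 = 0.05, df = 13)
  P$p_30 <- 0.001
  est <- estimate_rate_ammonium_label(P, labeled_fraction(F_ammonium = 1))
  expect_match(est$warnings, "model violation", all = FALSE)

  expect_error(estimate_rate_ammonium_label(production_rates(1, 0),
                                            labeled_fraction()),
               "not identifiable")
})

test_that("bootstrap uncertainty agrees with the delta method under OLS noise", {
  spec <- simulation_spec(noise_sd = 0.5, seed = 77)
  s <- simulate_incubation(spec)
  F <- labeled_fraction(F_nitrite = 1)
  bt <- bootstrap_rates(s, F, n_boot = 300)
  est <- estimate_rates_nitrite_label(fit_production_rates(s), F)
  expect_equal(bt$estimate, c(est$anammox, est$denitrification))
  # same order of magnitude as the delta-method errors (bootstrap over 15
  # bottles is itself noisy; a factor-2 band is a sanity check, not a
  # calibration claim)
  expect_gt(bt$se[1], est$se_A / 2)
  expect_lt(bt$se[1], est$se_A * 2)
  expect_true(all(bt$lower <= bt$estimate & bt$estimate <= bt$upper))
  # fixed default seed: reproducible
  expect_identical(bootstrap_rates(s, F, n_boot = 50),
                   bootstrap_rates(s, F, n_boot = 50))
})

test_that("contribution and total handle edge cases", {
  ct <- contribution_and_total(3.5, 0.7)
  expect_equal(ct$total, 4.2)
  expect_equal(ct$contribution, 0.8333333, tolerance = 1e-6)
  expect_equal(contribution_and_total(0, 5)$contribution, 0)
  expect_equal(contribution_and_total(5, 0)$contribution, 1)
  ct0 <- contribution_and_total(0, 0)
  expect_true(is.na(ct0$contribution))
  expect_match(ct0$warnings, "undefined")
})
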