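test_that("hzsA/amoA ratio sums the archaeal and bacterial components", {
  expect_equal(hzsa_amoa_ratio(one_well_table(), "gene")$hzsa_amoa, 1)
  expect_equal(hzsa_amoa_ratio(one_well_table(hzsa = 50), "gene")$hzsa_amoa,
               0.5)
  tt <- one_well_table(hzsa = 1.0874e6, aoa = 600, aob = 400,
                       molecule = "transcript")
  expect_equal(hzsa_amoa_ratio(tt, "transcript")$hzsa_amoa, 1087.4)
})

test_that("below-detection rules exclude or degrade the hzsA/amoA ratio", {
  # both amoA domains below detection -> excluded, no numeric ratio
  r <- hzsa_amoa_ratio(one_well_table(aoa_bd = TRUE, aob_bd = TRUE), "gene")
  expect_true(r$excluded)
  expect_true(is.na(r$hzsa_amoa))
  expect_match(r$reason, "amoA below detection")
  # hzsA below detection -> excluded
  r2 <- hzsa_amoa_ratio(one_well_table(hzsa_bd = TRUE), "gene")
  expect_true(r2$excluded)
  expect_match(r2$reason, "hzsA")
  # one domain below detection -> partial ratio against the quantified one
  r3 <- hzsa_amoa_ratio(one_well_table(aoa_bd = TRUE), "gene")
  expect_false(r3$excluded)
  expect_true(r3$partial)
  expect_equal(r3$hzsa_amoa, 100 / 50)
  # missing hzsA row entirely is an error, not an exclusion
  tab <- one_well_table()
  expect_error(hzsa_amoa_ratio(tab[tab$marker != "hzsA", ], "gene"),
               "no hzsA")
})

test_that("nirS/16S gene ratio and its edge cases", {
  expect_equal(nirs_16s_ratio(one_well_table())$nirs_16s, 0.095)
  expect_equal(nirs_16s_ratio(one_well_table(nirs = 0))$nirs_16s, 0)
  expect_equal(nirs_16s_ratio(one_well_table(nirs = 1e8))$nirs_16s, 1)
  r <- nirs_16s_ratio(one_well_table(ssu = 0))
  expect_true(r$excluded)
  expect_true(is.na(r$nirs_16s))
})

test_that("ratios are invariant to a per-well scaling of all copies", {
  tab <- one_well_table(hzsa = 123, aoa = 45, aob = 67, nirs = 890,
                        ssu = 12345)
  tab2 <- tab
  tab2$copies <- tab2$copies * 7.3
  expect_equal(hzsa_amoa_ratio(tab2, "gene")$hzsa_amoa,
               hzsa_amoa_ratio(tab, "gene")$hzsa_amoa)
  expect_equal(nirs_16s_ratio(tab2)$nirs_16s, nirs_16s_ratio(tab)$nirs_16s)
})

test_that("Spearman correlation: reversed ranks, exact p, exclusions", {
  # hand example with reversed ranks
  v <- c(a = 3, b = 2, c = 1)
  o <- c(a = 1, b = 2, c = 3)
  sp <- spearman_with_exclusions(v, o)
  expect_equal(sp$rho, -1)
  # perfectly decreasing index over 6 wells: exact two-sided p = 2/720
  v6 <- c(A = 10, B = 5, C = 2, D = 1, E = 0.5, F = 0.1)
  o6 <- c(A = 1, B = 2, C = 3, D = 4, E = 5, F = 6)
  sp6 <- spearman_with_exclusions(v6, o6)
  expect_equal(sp6$rho, -1)
  expect_equal(sp6$p, 2 / factorial(6))
  expect_equal(sp6$method, "exact")
  # agrees with the independent base-R rho on non-trivial data
  set.seed(8)
  v8 <- setNames(rnorm(8), letters[1:8])
  o8 <- setNames(rnorm(8), letters[1:8])
  sp8 <- spearman_with_exclusions(v8, o8)
  expect_equal(sp8$rho,
               unname(cor(v8, o8, method = "spearman")))
  # excluding wells drops them from the test and is recorded
  spx <- spearman_with_exclusions(v6, o6, exclude = c("A", "B"))
  expect_equal(spx$n, 4)
  expect_equal(spx$excluded, c("A", "B"))
  expect_error(spearman_with_exclusions(v6, o6,
                                        exclude = c("A", "B", "C", "D")),
               "fewer than 3")
  # constant index: degenerate, no rho
  spc <- spearman_with_exclusions(c(a = 1, b = 1, c = 1), o)
  expect_true(spc$degenerate)
  expect_true(is.na(spc$rho))
})

test_that("Spearman p is invariant under strictly monotone transforms", {
  set.seed(31)
  v <- setNames(rlnorm(7), paste0("W", 1:7))
  o <- setNames(runif(7, 0, 100), paste0("W", 1:7))
  a <- spearman_with_exclusions(v, o)
  b <- spearman_with_exclusions(log(v), o)
  d <- spearman_with_exclusions(v, sqrt(o))
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)
  expect_equal(a$rho, d$rho)
  expect_equal(a$p, d$p)
})

test_that("permutation p agrees with the t approximation at n = 10", {
  set.seed(12)
  v <- setNames(rnorm(10), paste0("W", 1:10))
  o <- setNames(rnorm(10), paste0("W", 1:10))
  sp <- spearman_with_exclusions(v, o)  # Monte-Carlo branch at n = 10
  expect_equal(sp$method, "monte-carlo")
  tval <- sp$rho * sqrt((10 - 2) / (1 - sp$rho^2))
  p_t <- 2 * pt(-abs(tval), df = 8)
  expect_lt(abs(sp$p - p_t), 0.02)
})

test_that("ladderane relative concentrations and detection flags", {
  pk <- data.frame(well = c("H53", "H51", "H31"),
                   date = "2015-11-01",
                   area_ladderane3 = c(2, 0.03, 0),
                   area_ladderane5 = c(3, 0.04, 0),
                   area_C19_IS = 10)
  rel <- ladderane_relative_concentration(pk)
  expect_equal(rel$rel_conc, c(0.5, 0.007, 0))
  expect_equal(rel$below_detection, c(FALSE, TRUE, TRUE))
  pk$area_C19_IS <- 0
  expect_error(ladderane_relative_concentration(pk), "internal standard")
})

test_that("well contrast factor compares quantified wells only", {
  rel <- data.frame(well = c("H53", "H53", "H51", "H31"),
                    rel_conc = c(3.0, 4.0, 0.1, 0.005),
                    below_detection = c(FALSE, FALSE, FALSE, TRUE))
  ct <- well_contrast_factor(rel, "H53", "H51")
  expect_equal(ct$factor, 35)  # mean(3, 4) / 0.1
  expect_equal(well_contrast_factor(rel, "H53", "H53")$factor, 1)
  # denominator below detection -> undefined contrast
  ct2 <- well_contrast_factor(rel, "H53", "H31")
  expect_true(ct2$undefined)
  expect_true(is.na(ct2$factor))
  expect_true(well_contrast_factor(c(A = 1, B = 0), "A", "B")$undefined)
})
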