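test_that("progression fit recovers an exact exponential gradient with degenerate CIs", {
  dist <- c(1, 3, 5, 7, 9, 11)
  pref <- 2^(0.3 * dist + 0.1)
  bins <- data.frame(bin_lo = dist - 1, bin_hi = dist + 1, mid = dist,
                     mean = pref, se = 0, n = 5)
  pf <- progression_fit(bins, n_boot = 500, n_perm = 999, seed = 1)
  expect_equal(pf$slope, 0.3, tolerance = 1e-12)
  expect_equal(pf$intercept, 0.1, tolerance = 1e-12)
  expect_equal(pf$slope_med, 0.3, tolerance = 1e-12)
  expect_equal(diff(pf$ci_slope), 0, tolerance = 1e-12)   # noiseless: zero width
  expect_lt(pf$p_perm, 0.01)
  expect_gte(pf$p_perm, 1 / 1000)                          # permutation floor
  expect_error(progression_fit(bins[1:2, ]), "3")
})

test_that("large-preference proportions land in the right subranges", {
  expect_true(all(as.matrix(proportion_large(runif(30), runif(30, 1, 7))[, -(1:3)]) == 0))
  pl <- proportion_large(rep(0.95, 5), rep(20, 5))
  expect_equal(pl$prop_16_32, 1)
  expect_equal(pl$prop_7_16, 0)
  expect_equal(pl$bin_lo, 0.9)
})

test_that("map size versus maximal preference uses a plain Pearson correlation", {
  expect_equal(size_vs_max(c(10, 20, 30, 40), c(1, 2, 3, 4))$r, 1)
  r3 <- size_vs_max(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r3$r, 1)
  expect_equal(r3$df, 1)
  expect_error(size_vs_max(rep(5, 4), 1:4), "constant")
  expect_error(size_vs_max(1:2, 1:2), "3 maps")
})

test_that("percentage deviation maps the slope onto the 0-1 calibration scale", {
  x <- c(1, 2, 4, 7)
  # identical preferences: the unity line scores 0
  d0 <- preference_comparison(x, x)
  expect_equal(d0$slope, 1)
  expect_equal(d0$pct_dev, 0)
  # the steepest calibration line through (1,1) and (7,64) scores 1
  d1 <- preference_comparison(x, 10.5 * x - 9.5)
  expect_equal(d1$slope, 10.5)
  expect_equal(d1$pct_dev, 1)
  # linear midpoint of the formula
  d5 <- preference_comparison(x, 5.75 * x - 2)
  expect_equal(d5$pct_dev, 0.5)
  # the deviation depends on the slope only, never the fitted intercept
  for (b in c(-3, 0, 11)) {
    expect_equal(preference_comparison(x, 2 * x + b)$pct_dev,
                 pct_deviation(2))
  }
  expect_error(preference_comparison(c(1, 2), c(1, 2)), "3 pairs")
})

test_that("upsampling correction shrinks the effective n of the correlation test", {
  set.seed(121)
  x <- runif(40, 1, 7)
  y <- x + rnorm(40, sd = 0.8)
  d <- preference_comparison(x, y, upsample_factor = 4)
  expect_equal(d$n_eff, 10)
  r <- cor(x, y)
  tval <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(d$p_corr, 2 * pt(-abs(tval), 8))
  # correcting n makes the test more conservative
  expect_gt(d$p_corr, preference_comparison(x, y)$p_corr)
})

test_that("group tests flag consistent deviations and deviant participants", {
  tab <- expand.grid(map = paste0("m", 1:6), participant = paste0("p", 1:8))
  tab$pct_dev <- 0.05
  gt <- deviation_group_tests(tab)
  expect_lt(gt$wilcoxon$p, 0.001)
  expect_gt(gt$wilcoxon$z, 0)

  # symmetric deviations: no evidence of a shift
  tab2 <- tab
  tab2$pct_dev <- rep(c(-0.05, 0.05), length.out = nrow(tab2))
  expect_gt(deviation_group_tests(tab2)$wilcoxon$p, 0.9)

  # one participant shifted: post hoc isolates it, ANOVA sees the factor
  set.seed(131)
  tab3 <- tab
  tab3$pct_dev <- rnorm(nrow(tab3), 0.02, 0.01)
  tab3$pct_dev[tab3$participant == "p6"] <- rnorm(6, 0.10, 0.01)
  gt3 <- deviation_group_tests(tab3)
  expect_lt(gt3$anova$p[gt3$anova$factor == "participant"], 0.001)
  ph <- gt3$posthoc
  involves6 <- outer(rownames(ph), colnames(ph),
                     function(a, b) a == "p6" | b == "p6")
  expect_lt(max(ph[involves6 & !is.na(ph)]), 0.05)
  expect_gt(min(ph[!involves6 & !is.na(ph)]), 0.05)
})

test_that("width scaling fit is SE-weighted and exact on linear width laws", {
  set.seed(141)
  pref <- runif(400, 1, 7)
  width <- 6 + 2 * pref            # exact linear law
  wf <- width_vs_preference(pref, width, n_boot = 300, n_perm = 499, seed = 2)
  expect_equal(wf$slope, 2, tolerance = 1e-9)
  expect_equal(wf$intercept, 6, tolerance = 1e-9)
  expect_equal(diff(wf$ci_slope), 0, tolerance = 1e-9)
  expect_gte(wf$p_perm, 1 / 500)
  # singleton bins contribute no weight: only n >= 2 bins enter the fit
  expect_true(all(wf$bins$n >= 2))
})

test_that("bootstrap median slope converges to the point estimate", {
  set.seed(151)
  pref <- runif(500, 1, 7)
  width <- 6 + 2 * pref + rnorm(500, sd = 0.6)
  wf <- width_vs_preference(pref, width, n_boot = 10000, n_perm = 0, seed = 3)
  expect_equal(wf$slope_med, wf$slope, tolerance = 0.02 * abs(wf$slope))
  # and the noisy truth stays inside the 95% CI
  expect_gt(2, wf$ci_slope[1]); expect_lt(2, wf$ci_slope[2])
})
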