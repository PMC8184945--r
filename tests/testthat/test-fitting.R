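test_that("variance explained matches an lm oracle with free gain and baseline", {
  set.seed(41)
  for (i in 1:6) {
    y <- rnorm(30)
    u <- rnorm(30)
    fit <- lm(y ~ u)
    r2_lm <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    expect_equal(variance_explained(y, u), r2_lm, tolerance = 1e-12)
  }
  # hand case: centered prediction orthogonal to centered data
  y <- c(1, 2, 3, 4); u <- c(0, 1, 1, 0)
  fit <- lm(y ~ u)
  expect_equal(unname(coef(fit)[2]), 0)
  expect_equal(variance_explained(y, u), 0)
  # exact fit up to gain/offset
  expect_equal(variance_explained(3 * u - 7, u), 1)
  expect_error(variance_explained(rep(2, 10), rnorm(10)), "constant")
  expect_error(variance_explained(1:4, 1:5), "length")
})

test_that("noiseless on-grid voxels are recovered exactly by the grid search", {
  p_node <- fx_grid$preferred[fx_grid$preferred == 4][1]
  s_node <- sort(unique(fx_grid$width_sigma))[16]
  f <- fx_fit_sim_voxel(p_node, s_node, sd = 0)
  expect_equal(f$preferred, p_node)
  expect_equal(f$width_sigma, s_node)
  expect_gt(f$r2, 1 - 1e-9)
  expect_true(f$in_range && f$fittable)
})

test_that("tuning above the presented range is estimated but flagged out of range", {
  f <- fx_fit_sim_voxel(16, fx_sigma_for(16), sd = 0, tl = fx_tl_small,
                        U = fx_U_small)
  expect_gt(f$preferred, 7)             # estimate produced, not clipped
  expect_false(f$in_range)
  expect_false(select_sites(as.data.frame(f[1:7])))
})

test_that("pure-noise voxels stay below the selection threshold", {
  set.seed(51)
  r2 <- vapply(1:20, function(i)
    grid_fit(rnorm(176, sd = 0.5), fx_tl_large, fx_grid,
             predictions = fx_U_large)$r2, numeric(1))
  expect_lt(max(r2), 0.30)
})

test_that("grid search equals a brute-force SSE oracle over the same grid", {
  grid_small <- fit_grid(preferred_values = 2^seq(-1, 7, by = 0.5),
                         sigma_values = exp(seq(log(0.1), log(4), length.out = 8)))
  U <- grid_predictions(fx_tl_large, grid_small)
  set.seed(61)
  for (i in 1:10) {
    truth <- tuning_params(2^runif(1, 0, 5.5), runif(1, 0.3, 2.5))
    y <- drop(simulate_voxel(truth, fx_tl_large, noise = noise_model(sd = 0.5)))
    f <- grid_fit(y, fx_tl_large, grid_small, predictions = U)
    # brute force: per-candidate least-squares solve, first-minimum tie-break
    sse <- vapply(seq_len(ncol(U)), function(c)
      sum(residuals(lm(y ~ U[, c]))^2), numeric(1))
    best <- which.min(sse)              # first minimum = same tie-break order
    tol <- 1e-9 * sum((y - mean(y))^2)
    expect_lt(sse[f$grid_index] - sse[best], tol)
    if (sort(sse)[2] - sse[best] > tol) {
      expect_equal(f$preferred, grid_small$preferred[best])
      expect_equal(f$width_sigma, grid_small$width_sigma[best])
    }
    expect_equal(f$r2, 1 - sse[f$grid_index] / sum((y - mean(y))^2),
                 tolerance = 1e-9)
  }
})

test_that("continuous refinement recovers off-grid truth and never hurts", {
  truth <- tuning_params(2^2.06, 0.9)   # between grid nodes
  y <- drop(simulate_voxel(truth, fx_tl_large, noise = noise_model(sd = 0)))
  init <- grid_fit(y, fx_tl_large, fx_grid, predictions = fx_U_large)
  ref <- refine_fit(y, fx_tl_large, init)
  expect_lt(abs(log2(ref$preferred) - log2(truth$preferred)), 1e-3)
  expect_gte(ref$r2, init$r2 - 1e-12)
  set.seed(71)
  for (i in 1:4) {
    y <- drop(simulate_voxel(tuning_params(2^runif(1, 0.5, 5), runif(1, 0.5, 2)),
                             fx_tl_large, noise = noise_model(sd = 0.5)))
    init <- grid_fit(y, fx_tl_large, fx_grid, predictions = fx_U_large)
    expect_gte(refine_fit(y, fx_tl_large, init)$r2, init$r2 - 1e-12)
  }
})

test_that("site selection applies both the threshold and the range criterion", {
  fits <- data.frame(preferred = c(3, 3, 70, 3, 3),
                     width_sigma = 1, gain = c(1, 1, 1, 1, -0.5),
                     baseline = 0,
                     r2 = c(0.29, 0.31, 0.80, 0.80, 0.80),
                     in_range = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                     fittable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(select_sites(fits), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # explicit range overrides the stored flags: 70 is outside 1..64
  expect_equal(select_sites(fits, presented_range = c(1, 64))[3], FALSE)
  expect_error(select_sites(fits, threshold = 1.2), "threshold")
})

test_that("odd/even split averages runs by 1-based acquisition order", {
  A <- matrix(1, 2, 4); B <- matrix(3, 2, 4)
  sp <- split_half(list(A, B))
  expect_equal(sp$odd, A)
  expect_equal(sp$even, B)
  sp8 <- split_half(rep(list(A), 8))
  expect_equal(sp8$odd, sp8$even)
  expect_error(split_half(list(A)), "2 runs")
  # independent-noise halves are uncorrelated
  set.seed(81)
  runs <- lapply(1:8, function(i) rnorm(500))
  sp <- split_half(runs)
  expect_lt(abs(cor(sp$odd, sp$even)), 0.15)
})

test_that("cross-validated R2 freezes tuning and generalises across designs", {
  truth <- tuning_params(4, sort(unique(fx_grid$width_sigma))[18])  # on-grid
  y_small <- drop(simulate_voxel(truth, fx_tl_small, noise = noise_model(sd = 0)))
  y_large <- drop(simulate_voxel(truth, fx_tl_large, noise = noise_model(sd = 0)))
  f <- grid_fit(y_small, fx_tl_small, fx_grid, predictions = fx_U_small)
  expect_equal(crossval_r2(f, y_small, fx_tl_small), 1, tolerance = 1e-9)
  expect_equal(crossval_r2(f, y_large, fx_tl_large), 1, tolerance = 1e-9)
  # badly mismatched tuning predicts almost nothing
  f2 <- list(preferred = 2, width_sigma = 0.4)
  y40 <- drop(simulate_voxel(tuning_params(40, 0.5), fx_tl_large,
                             noise = noise_model(sd = 0)))
  expect_lt(crossval_r2(f2, y40, fx_tl_large), 0.1)
})

test_that("cross-validation does not beat the within-sample fit on average", {
  set.seed(91)
  gap <- vapply(1:15, function(i) {
    truth <- tuning_params(2^runif(1, 0.5, 2.5), runif(1, 0.8, 1.5))
    runs <- lapply(1:4, function(r)
      drop(simulate_voxel(truth, fx_tl_small, noise = noise_model(sd = 0.5))))
    sp <- split_half(runs)
    f <- grid_fit(sp$odd, fx_tl_small, fx_grid, predictions = fx_U_small)
    f$r2 - crossval_r2(f, sp$even, fx_tl_small)
  }, numeric(1))
  expect_gte(mean(gap), 0)
})

test_that("cross-validation matrix runs all 12 iterations with common-range selection", {
  truth <- data.frame(preferred = c(2, 4, 6), width_sigma = 1)
  mk <- function(tl, sd, seed) {
    set.seed(seed)
    t(vapply(seq_len(nrow(truth)), function(i)
      drop(simulate_voxel(tuning_params(truth$preferred[i], truth$width_sigma[i]),
                          tl, noise = noise_model(sd = sd))),
      numeric(176)))
  }
  halves <- list(small_odd = mk(fx_tl_small, 0.15, 1), small_even = mk(fx_tl_small, 0.15, 2),
                 large_odd = mk(fx_tl_large, 0.15, 3), large_even = mk(fx_tl_large, 0.15, 4))
  cv <- crossval_matrix(halves, fx_timelines, fx_grid)
  expect_equal(nrow(cv$iterations), 12)
  expect_equal(sum(cv$iterations$kind == "within"), 4)
  expect_equal(sum(cv$iterations$kind == "cross"), 8)
  expect_true(all(cv$iterations$cv_r2 > 0.5))
  expect_error(crossval_matrix(halves[1:3], fx_timelines, fx_grid), "missing")
})
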