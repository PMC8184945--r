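# weighted least-squares slope/intercept; w = NULL for ordinary LS
.wls <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) return(c(slope = NA_real_, intercept = NA_real_))
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  c(slope = slope, intercept = yb - slope * xb)
}

# one-sided permutation p for a fitted slope: randomise the x (bin-order)
# labels, refit, count permuted slopes >= observed; (count+1)/(n+1) floor.
.perm_p <- function(x, y, w, observed, n_perm) {
  if (n_perm < 1) return(NA_real_)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    s <- .wls(x[sample.int(length(x))], y, w)[["slope"]]
    if (!is.na(s) && s >= observed) cnt <- cnt + 1L
  }
  (cnt + 1) / (n_perm + 1)
}

# bootstrap bins with replacement; returns matrix of (slope, intercept)
.boot_fits <- function(x, y, w, n_boot) {
  n <- length(x)
  out <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("slope", "intercept")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    out[b, ] <- .wls(x[idx], y[idx], if (is.null(w)) NULL else w[idx])
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}

#' Numerosity progression along the cortical surface
#'
#' Fits the logarithmic progression of preferred numerosity with cortical
#' distance: `log2(preferred) = slope * distance + intercept`, on binned map
#' data (see [bin_by_distance()]). A positive slope with shrinking linear
#' steps at larger counts is the signature of cortical magnification of
#' small numerosities. The reported slope and intercept are the medians over
#' bootstrap resamples of the bins (with replacement); the 95% CI is the
#' 2.5--97.5 percentile envelope of the bootstrapped fits; significance is a
#' one-sided permutation test that randomises the order of the distance bins
#' and counts permuted slopes greater than or equal to the observed one.
#'
#' @param bins A `bin_series` of preferred numerosity by cortical distance
#'   (>= 3 non-empty bins).
#' @param n_boot Bootstrap resamples (default 1000; 0 skips the CI).
#' @param n_perm Permutations (default 10000; 0 skips the test).
#' @param seed Optional integer seed.
#' @return A `progression_fit` list: `slope`, `intercept` (point fit),
#'   `slope_med`, `intercept_med` (bootstrap medians), `ci_slope`,
#'   `ci_intercept`, `p_perm`, `n_boot`, `n_perm`.
#' @export
progression_fit <- function(bins, n_boot = 1000, n_perm = 10000, seed = NULL) {
  if (nrow(bins) < 3) stopf("need at least 3 non-empty bins")
  x <- bins$mid
  y <- log2(bins$mean)
  fit <- .wls(x, y)
  with_seed(seed, {
    boot <- if (n_boot > 0) .boot_fits(x, y, NULL, n_boot) else NULL
    p <- if (n_perm > 0) .perm_p(x, y, NULL, fit[["slope"]], n_perm) else NA_real_
    structure(list(
      slope = fit[["slope"]], intercept = fit[["intercept"]],
      slope_med = if (is.null(boot)) fit[["slope"]] else stats::median(boot[, 1]),
      intercept_med = if (is.null(boot)) fit[["intercept"]] else stats::median(boot[, 2]),
      ci_slope = if (is.null(boot)) c(NA, NA) else unname(stats::quantile(boot[, 1], c(.025, .975))),
      ci_intercept = if (is.null(boot)) c(NA, NA) else unname(stats::quantile(boot[, 2], c(.025, .975))),
      p_perm = p, n_boot = n_boot, n_perm = n_perm),
      class = "progression_fit")
  })
}

#' Where large numerosity preferences sit along the map
#'
#' Splits preferred numerosities above the small range into subranges
#' ((7,16], (16,32], (32,64] by default) and reports, per 10% bin of
#' normalized cortical distance, the proportion of selected sites falling in
#' each subrange. On a magnified topographic map these proportions
#' concentrate in the final bins (the high-preference end).
#'
#' @param u Normalized cortical positions of the selected sites.
#' @param preferred Their preferred numerosities.
#' @param width Bin width on u (default 0.10).
#' @param subranges List of `c(lo, hi]` subrange bounds.
#' @return Data.frame: `bin_lo`, `bin_hi`, `n` (selected sites in bin) and
#'   one `prop_lo_hi` column per subrange.
#' @export
proportion_large <- function(u, preferred, width = 0.10,
                             subranges = list(c(7, 16), c(16, 32), c(32, 64))) {
  if (length(u) != length(preferred)) stopf("u and preferred differ in length")
  idx <- pmin(floor(u / width + 1e-9), ceiling(1 / width) - 1)
  ids <- sort(unique(idx))
  out <- do.call(rbind, lapply(ids, function(b) {
    p <- preferred[idx == b]
    row <- data.frame(bin_lo = b * width, bin_hi = (b + 1) * width, n = length(p))
    for (sr in subranges)
      row[[sprintf("prop_%g_%g", sr[1], sr[2])]] <- mean(p > sr[1] & p <= sr[2])
    row
  }))
  out
}

#' Map size versus largest preferred numerosity
#'
#' Pearson correlation between the cortical length of each map and the
#' largest selected preferred numerosity it contains (larger maps can
#' resolve populations tuned to larger counts).
#'
#' @param length_mm Cortical length of each map (>= 3 maps).
#' @param max_preferred Largest selected preferred numerosity per map.
#' @return List with `r`, `p`, `df`.
#' @export
size_vs_max <- function(length_mm, max_preferred) {
  if (length(length_mm) < 3) stopf("need at least 3 maps")
  if (stats::sd(length_mm) == 0 || stats::sd(max_preferred) == 0)
    stopf("constant input; correlation undefined")
  ct <- stats::cor.test(length_mm, max_preferred, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}

#' Percentage deviation of a preference-relation slope from identity
#'
#' Maps the slope of the large-vs-small preference regression onto a 0--1
#' deviation scale: the unity line (slope 1, identical preferences) scores
#' 0; the steepest calibration line `y = 10.5x - 9.5`, which sends the
#' small-range extremes (1, 7) onto the large-range extremes (1, 64),
#' scores 1. `pct_deviation(p) = (p - 1) / 9.5`.
#'
#' @param slope Fitted slope of large-range on small-range preferences.
#' @return The percentage deviation (fraction of the maximal stretch).
#' @export
pct_deviation <- function(slope) (slope - 1) / 9.5

#' Compare preferred numerosities across stimulus ranges
#'
#' For sites selected in both conditions, correlates the small- and
#' large-range preferred numerosities (Pearson), computes the correlation
#' probability at an effective sample size corrected for the factor by which
#' functional voxels were up-sampled onto the surface, fits the ordinary
#' least-squares line of large on small preferences, and converts its slope
#' to the percentage deviation from the unity line.
#'
#' @param p_small,p_large Paired preferred numerosities (>= 3 pairs).
#' @param upsample_factor Up-sampling factor; the effective n is
#'   `length(p_small) / upsample_factor` (default 1).
#' @return A `deviation_result` list: `r`, `n`, `n_eff`, `p_corr`, `slope`,
#'   `intercept`, `pct_dev`.
#' @export
preference_comparison <- function(p_small, p_large, upsample_factor = 1) {
  if (length(p_small) != length(p_large)) stopf("paired vectors differ in length")
  n <- length(p_small)
  if (n < 3) stopf("need at least 3 pairs")
  r <- stats::cor(p_small, p_large)
  n_eff <- n / upsample_factor
  df <- n_eff - 2
  p_corr <- if (df > 0 && abs(r) < 1) {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  } else if (abs(r) >= 1) 0 else NA_real_
  fit <- .wls(p_small, p_large)
  structure(list(r = r, n = n, n_eff = n_eff, p_corr = p_corr,
                 slope = fit[["slope"]], intercept = fit[["intercept"]],
                 pct_dev = pct_deviation(fit[["slope"]])),
            class = "deviation_result")
}

#' Group tests on percentage deviations
#'
#' Pools the per-map, per-participant percentage deviations and tests
#' whether they differ from zero (two-sided Wilcoxon signed-rank, normal
#' approximation with the z statistic reported), whether they differ between
#' maps and participants (two-way ANOVA), and which participants differ from
#' the rest (pairwise t tests, Bonferroni corrected).
#'
#' @param dev Data.frame with columns `map`, `participant`, `pct_dev`.
#' @return List with `wilcoxon` (`z`, `p`, `V`, `df`), `anova`
#'   (data.frame of F and p per factor), `posthoc` (Bonferroni-adjusted
#'   pairwise p matrix across participants).
#' @export
deviation_group_tests <- function(dev) {
  stopifnot(all(c("map", "participant", "pct_dev") %in% names(dev)))
  dev <- dev[stats::complete.cases(dev[, c("map", "participant", "pct_dev")]), ]
  x <- dev$pct_dev
  nz <- x[x != 0]
  wil <- if (length(nz) == 0) {
    list(z = NA_real_, p = NA_real_, V = NA_real_, df = length(x) - 1,
         degenerate = TRUE)
  } else {
    wt <- stats::wilcox.test(x, mu = 0, exact = FALSE, correct = FALSE)
    n <- length(nz)
    mu <- n * (n + 1) / 4
    sdv <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    list(z = (unname(wt$statistic) - mu) / sdv, p = wt$p.value,
         V = unname(wt$statistic), df = length(x) - 1, degenerate = FALSE)
  }
  dev$map <- factor(dev$map)
  dev$participant <- factor(dev$participant)
  av <- stats::aov(pct_dev ~ map + participant, data = dev)
  tab <- summary(av)[[1]]
  fac <- trimws(rownames(tab))
  anova_df <- data.frame(factor = fac, df = tab[, "Df"],
                         F = tab[, "F value"], p = tab[, "Pr(>F)"],
                         row.names = NULL)
  ph <- stats::pairwise.t.test(dev$pct_dev, dev$participant,
                               p.adjust.method = "bonferroni")
  list(wilcoxon = wil, anova = anova_df, posthoc = ph$p.value)
}

#' Tuning width scaling with preferred numerosity
#'
#' Bins tuning widths by preferred numerosity (0.25-wide bins), then fits a
#' straight line to the bin means weighted by the inverse of each bin's
#' standard error (bins with a single site carry no weight and are dropped
#' from the fit). Bootstrap CI and one-sided permutation significance as in
#' [progression_fit()].
#'
#' @param preferred Preferred numerosities of the selected sites.
#' @param width Their tuning widths (linear FWHM by default convention; any
#'   consistent width measure works).
#' @param bin Bin width on preferred numerosity (default 0.25).
#' @param n_boot,n_perm,seed As in [progression_fit()].
#' @return A `width_fit` list: `slope`, `intercept`, bootstrap medians,
#'   `ci_slope`, `ci_intercept`, `p_perm`, and the `bins` used.
#' @export
width_vs_preference <- function(preferred, width, bin = 0.25,
                                n_boot = 1000, n_perm = 10000, seed = NULL) {
  bins <- bin_by_distance(width, preferred, width = bin)
  usable <- bins[bins$n >= 2 & bins$se > 0, , drop = FALSE]
  if (nrow(usable) < 3) stopf("need at least 3 bins with >= 2 sites")
  x <- usable$x_mean                    # bin mean of preferred numerosity
  y <- usable$mean
  w <- 1 / usable$se
  fit <- .wls(x, y, w)
  with_seed(seed, {
    boot <- if (n_boot > 0) .boot_fits(x, y, w, n_boot) else NULL
    p <- if (n_perm > 0) .perm_p(x, y, w, fit[["slope"]], n_perm) else NA_real_
    structure(list(
      slope = fit[["slope"]], intercept = fit[["intercept"]],
      slope_med = if (is.null(boot)) fit[["slope"]] else stats::median(boot[, 1]),
      intercept_med = if (is.null(boot)) fit[["intercept"]] else stats::median(boot[, 2]),
      ci_slope = if (is.null(boot)) c(NA, NA) else unname(stats::quantile(boot[, 1], c(.025, .975))),
      ci_intercept = if (is.null(boot)) c(NA, NA) else unname(stats::quantile(boot[, 2], c(.025, .975))),
      p_perm = p, n_boot = n_boot, n_perm = n_perm, bins = usable),
      class = "width_fit")
  })
}
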