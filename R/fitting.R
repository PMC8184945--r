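#' Candidate grid for tuning-parameter search
#'
#' Log-spaced candidate preferred numerosities and tuning widths evaluated
#' exhaustively during fitting. The default preferred grid extends well
#' beyond the presented stimulus ranges (2^-2 to 2^8 at 1/8-octave steps) so
#' that out-of-range tuning can be estimated and then excluded, rather than
#' clipped to the best of a limited set.
#'
#' @param preferred_values Candidate preferred numerosities (> 0).
#' @param sigma_values Candidate tuning SDs in log2 units (> 0).
#' @return An object of class `fit_grid`: a data.frame of candidates ordered
#'   by preferred then sigma (the tie-break order).
#' @export
fit_grid <- function(preferred_values = 2^seq(-2, 8, by = 1 / 8),
                     sigma_values = exp(seq(log(0.05), log(8), length.out = 30))) {
  if (!length(preferred_values) || !length(sigma_values))
    stopf("grids must be non-empty")
  if (any(preferred_values <= 0) || any(sigma_values <= 0))
    stopf("all grid candidates must be positive")
  g <- expand.grid(width_sigma = sigma_values, preferred = preferred_values,
                   KEEP.OUT.ATTRS = FALSE)[, c("preferred", "width_sigma")]
  structure(g, class = c("fit_grid", "data.frame"))
}

#' Unit predictions for every grid candidate
#'
#' Builds the `n_retained x n_candidates` matrix of unit BOLD predictions,
#' one column per grid candidate, via the per-numerosity regressor shortcut.
#' Precompute this once per timeline when fitting many voxels.
#'
#' @param timeline A `stimulus_timeline`.
#' @param grid A [fit_grid()].
#' @param hrf An [hrf_params()].
#' @param dt_s Fine sampling step in seconds.
#' @return Matrix of candidate predictions (columns in grid order).
#' @export
grid_predictions <- function(timeline, grid = fit_grid(), hrf = hrf_params(),
                             dt_s = 0.05) {
  R <- timeline_regressors(timeline, hrf, dt_s)
  vals <- as.numeric(colnames(R))
  lv <- log2(vals)
  W <- vapply(seq_len(nrow(grid)), function(i) {
    z <- (lv - log2(grid$preferred[i])) / grid$width_sigma[i]
    exp(-z^2 / 2)
  }, numeric(length(vals)))
  R %*% W
}

#' Variance explained by a unit prediction
#'
#' Solves the response gain and baseline by ordinary least squares for the
#' given unit prediction and returns `1 - SSE / SS_total`, the fraction of
#' the data variance captured by the scaled and shifted prediction.
#'
#' @param data Observed time series (length >= 3, not constant).
#' @param prediction Unit model prediction, same length.
#' @return Variance explained in [0, 1] (gain is free, so never negative).
#' @export
variance_explained <- function(data, prediction) {
  if (length(data) != length(prediction)) stopf("lengths differ")
  if (length(data) < 3) stopf("need at least 3 time points")
  yc <- data - mean(data)
  syy <- sum(yc^2)
  if (syy <= 0) stopf("data are constant; variance explained is undefined")
  uc <- prediction - mean(prediction)
  pk <- max(abs(uc))
  if (pk == 0) return(0)
  uc <- uc / pk                     # scale-invariant; exact even for tiny predictions
  suu <- sum(uc^2)
  sum(uc * yc)^2 / (suu * syy)
}

#' Fit tuning parameters to voxel time series by exhaustive grid search
#'
#' For every grid candidate the gain and baseline are solved by least
#' squares and the candidate minimising the residual sum of squared errors is
#' selected (equivalently, maximising variance explained). Ties break toward
#' smaller preferred numerosity, then smaller sigma. Estimates outside the
#' presented range are produced and flagged (`in_range`), not clipped;
#' negative-gain optima and voxels for which every candidate prediction is
#' flat are flagged unfittable.
#'
#' `fit_voxels` fits a whole `voxels x TR` matrix at once; `grid_fit` fits a
#' single time series and returns a `fit_result` list.
#'
#' @param data Numeric vector (one voxel) for `grid_fit`; a `voxels x TR`
#'   matrix for `fit_voxels`.
#' @param timeline A `stimulus_timeline`.
#' @param grid A [fit_grid()].
#' @param hrf An [hrf_params()].
#' @param dt_s Fine sampling step.
#' @param predictions Optional precomputed [grid_predictions()] matrix.
#' @return `fit_voxels`: a data.frame with one row per voxel, columns
#'   `preferred`, `width_sigma`, `gain`, `baseline`, `r2`, `in_range`,
#'   `fittable`. `grid_fit`: a `fit_result` list with the same fields plus
#'   `grid_index`.
#' @export
fit_voxels <- function(data, timeline, grid = fit_grid(), hrf = hrf_params(),
                       dt_s = 0.05, predictions = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (ncol(data) != n_retained(timeline$protocol))
    stopf("data has %d columns but the timeline has %d retained TRs",
          ncol(data), n_retained(timeline$protocol))
  U <- if (is.null(predictions)) grid_predictions(timeline, grid, hrf, dt_s) else predictions
  if (ncol(U) != nrow(grid)) stopf("predictions do not match the grid")

  Y <- t(data)                               # TR x voxels
  Yc <- sweep(Y, 2, colMeans(Y))
  Uc <- sweep(U, 2, colMeans(U))
  # rescale every candidate column to unit peak: the score below is a squared
  # correlation, so this changes nothing at ordinary scales but keeps the
  # arithmetic exact for candidates whose response has underflowed toward the
  # denormal range (very narrow tuning far outside the presented values)
  cscale <- apply(abs(Uc), 2, max)
  degen <- cscale == 0                       # exactly flat prediction
  Uc <- sweep(Uc, 2, pmax(cscale, .Machine$double.xmin), "/")
  suu <- colSums(Uc^2)
  syy <- colSums(Yc^2)
  if (any(syy <= 0)) stopf("constant voxel time series; variance explained is undefined")
  S <- crossprod(Uc, Yc)                     # candidates x voxels
  score <- -S^2 / suu                        # SSE minus syy; lower is better
  score[degen, ] <- 0
  best <- apply(score, 2, which.min)         # first minimum = grid tie-break order
  iv <- seq_len(ncol(Y))
  pick <- cbind(best, iv)
  gain <- S[pick] / suu[best] / cscale[best]
  gain[degen[best]] <- 0
  r2 <- (S[pick]^2) / (suu[best] * syy)
  r2[degen[best]] <- 0
  baseline <- colMeans(Y) - gain * colMeans(U)[best]
  rng <- range(timeline$range_spec$main_values)
  pref <- grid$preferred[best]
  res <- data.frame(
    preferred = pref,
    width_sigma = grid$width_sigma[best],
    gain = gain,
    baseline = baseline,
    r2 = r2,
    in_range = pref >= rng[1] & pref <= rng[2],
    fittable = gain > 0 & !degen[best])
  attr(res, "grid_index") <- best
  res
}

#' @rdname fit_voxels
#' @export
grid_fit <- function(data, timeline, grid = fit_grid(), hrf = hrf_params(),
                     dt_s = 0.05, predictions = NULL) {
  res <- fit_voxels(matrix(data, nrow = 1), timeline, grid, hrf, dt_s, predictions)
  out <- as.list(res[1, ])
  out$grid_index <- attr(res, "grid_index")[1]
  structure(out, class = "fit_result")
}

#' Continuous refinement of a grid fit
#'
#' Polishes the grid optimum by derivative-free (Nelder-Mead) minimisation of
#' the SSE over `(log2 preferred, log sigma)`, with gain and baseline solved
#' by least squares at every evaluation. The refined fit is only accepted if
#' it does not decrease variance explained.
#'
#' @param data Voxel time series.
#' @param timeline A `stimulus_timeline`.
#' @param init A `fit_result` from [grid_fit()].
#' @param hrf An [hrf_params()].
#' @param dt_s Fine sampling step.
#' @return A `fit_result` with an added `refined` flag.
#' @export
refine_fit <- function(data, timeline, init, hrf = hrf_params(), dt_s = 0.05) {
  R <- timeline_regressors(timeline, hrf, dt_s)
  lv <- log2(as.numeric(colnames(R)))
  obj <- function(par) {
    z <- (lv - par[1]) / exp(par[2])
    u <- drop(R %*% exp(-z^2 / 2))
    1 - variance_explained(data, u)
  }
  opt <- tryCatch(
    stats::optim(c(log2(init$preferred), log(init$width_sigma)), obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500)),
    error = function(e) NULL)
  out <- init
  out$refined <- FALSE
  if (!is.null(opt) && (1 - opt$value) >= init$r2 - 1e-12) {
    pars <- tuning_params(2^opt$par[1], exp(opt$par[2]))
    u <- predict_timecourse(timeline, pars, hrf, dt_s, regressors = R)
    fit <- stats::lm.fit(cbind(1, u), data)
    rng <- range(timeline$range_spec$main_values)
    out$preferred <- pars$preferred
    out$width_sigma <- pars$width_sigma
    out$gain <- unname(fit$coefficients[2])
    out$baseline <- unname(fit$coefficients[1])
    out$r2 <- max(init$r2, 1 - opt$value)
    out$in_range <- pars$preferred >= rng[1] & pars$preferred <= rng[2]
    out$fittable <- out$gain > 0
    out$refined <- TRUE
  }
  structure(out, class = "fit_result")
}

#' Select recording sites with clear tuned responses
#'
#' A site is retained when its variance explained exceeds the threshold
#' (default 30%) *and* its preferred numerosity lies within the presented
#' stimulus range *and* the fit is a positive-gain tuned response.
#'
#' @param fits A data.frame from [fit_voxels()].
#' @param threshold Variance-explained threshold in (0, 1); default 0.30.
#' @param presented_range Length-2 numeric `c(min, max)` of presented main
#'   numerosities; defaults to the `in_range` flags already in `fits`.
#' @return Logical selection mask.
#' @export
select_sites <- function(fits, threshold = 0.30, presented_range = NULL) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must lie in (0, 1)")
  in_range <- if (is.null(presented_range)) fits$in_range else
    fits$preferred >= presented_range[1] & fits$preferred <= presented_range[2]
  fits$r2 > threshold & in_range & fits$fittable
}

#' Split runs into odd and even halves
#'
#' Averages the odd-numbered and even-numbered runs (1-based acquisition
#' order) element-wise, producing the two half datasets used for
#' cross-validation.
#'
#' @param runs List of per-run datasets (vectors or matrices of equal shape),
#'   length >= 2.
#' @return List with elements `odd` and `even`.
#' @export
split_half <- function(runs) {
  if (length(runs) < 2) stopf("need at least 2 runs to split")
  avg <- function(idx) Reduce(`+`, runs[idx]) / length(idx)
  list(odd = avg(seq(1, length(runs), by = 2)),
       even = avg(seq(2, length(runs), by = 2)))
}

#' Cross-validated variance explained
#'
#' Freezes the tuning parameters (preferred numerosity and width) estimated
#' on the predictor dataset, generates their unit prediction for the test
#' condition's timeline, re-solves only gain and baseline on the test data,
#' and returns the variance explained (cvR^2).
#'
#' @param predictor_fit A `fit_result` (or one row of a [fit_voxels()]
#'   data.frame) estimated on the predictor dataset.
#' @param test_data Test time series.
#' @param test_timeline Timeline of the test condition.
#' @param hrf An [hrf_params()].
#' @param dt_s Fine sampling step.
#' @param regressors Optional precomputed [timeline_regressors()] for the
#'   test timeline.
#' @return cvR^2 in [0, 1].
#' @export
crossval_r2 <- function(predictor_fit, test_data, test_timeline,
                        hrf = hrf_params(), dt_s = 0.05, regressors = NULL) {
  pars <- tuning_params(predictor_fit$preferred, predictor_fit$width_sigma)
  u <- predict_timecourse(test_timeline, pars, hrf, dt_s, regressors = regressors)
  variance_explained(test_data, u)
}

#' Within- and cross-condition cross-validation matrix
#'
#' Takes the four half-split datasets (small/large condition x odd/even
#' runs), fits each half independently, and evaluates every cross-validation
#' iteration: within-condition (odd predicts even and vice versa, 2
#' iterations per condition, 4 total) and cross-condition (each half predicts
#' both halves of the other condition, 8 total). Voxels enter the comparison
#' when, in every half-fit, variance explained exceeds the threshold and the
#' preferred numerosity falls in the common range presented in both
#' conditions (default 1--7).
#'
#' @param halves Named list of `voxels x TR` matrices: `small_odd`,
#'   `small_even`, `large_odd`, `large_even`.
#' @param timelines Named list of `stimulus_timeline`s: `small`, `large`.
#' @param grid A [fit_grid()].
#' @param hrf An [hrf_params()].
#' @param threshold Variance-explained selection threshold (default 0.30).
#' @param common_range Length-2 range of preferred numerosities presented in
#'   both conditions (default `c(1, 7)`).
#' @param dt_s Fine sampling step.
#' @return List with `iterations` (data.frame: predictor, test, kind, mean
#'   cv_r2 over selected voxels), `per_voxel` (matrix voxels x iterations),
#'   `selected` (logical mask), `fits` (list of half fits).
#' @export
crossval_matrix <- function(halves, timelines, grid = fit_grid(),
                            hrf = hrf_params(), threshold = 0.30,
                            common_range = c(1, 7), dt_s = 0.05) {
  need <- c("small_odd", "small_even", "large_odd", "large_even")
  miss <- setdiff(need, names(halves))
  if (length(miss)) stopf("missing half dataset(s): %s", paste(miss, collapse = ", "))
  cond_of <- c(small_odd = "small", small_even = "small",
               large_odd = "large", large_even = "large")
  preds <- lapply(timelines, grid_predictions, grid = grid, hrf = hrf, dt_s = dt_s)
  regs <- lapply(timelines, timeline_regressors, hrf = hrf, dt_s = dt_s)
  fits <- lapply(need, function(h)
    fit_voxels(halves[[h]], timelines[[cond_of[h]]], grid, hrf, dt_s,
               predictions = preds[[cond_of[h]]]))
  names(fits) <- need
  sel <- Reduce(`&`, lapply(fits, function(f)
    f$r2 > threshold & f$fittable &
      f$preferred >= common_range[1] & f$preferred <= common_range[2]))
  if (!any(sel)) stopf("no voxels satisfy the common-range selection")

  other <- list(small_odd = c("large_odd", "large_even"),
                small_even = c("large_odd", "large_even"),
                large_odd = c("small_odd", "small_even"),
                large_even = c("small_odd", "small_even"))
  within_pairs <- list(c("small_odd", "small_even"), c("small_even", "small_odd"),
                       c("large_odd", "large_even"), c("large_even", "large_odd"))
  cross_pairs <- unlist(lapply(need, function(p)
    lapply(other[[p]], function(t) c(p, t))), recursive = FALSE)
  pairs <- c(within_pairs, cross_pairs)
  kind <- c(rep("within", length(within_pairs)), rep("cross", length(cross_pairs)))

  vox_sel <- which(sel)
  per_voxel <- matrix(NA_real_, length(vox_sel), length(pairs))
  it_names <- vapply(pairs, function(p) paste(p[1], "->", p[2]), character(1))
  colnames(per_voxel) <- it_names
  for (j in seq_along(pairs)) {
    p <- pairs[[j]][1]; t <- pairs[[j]][2]
    tl <- timelines[[cond_of[t]]]
    rg <- regs[[cond_of[t]]]
    for (i in seq_along(vox_sel)) {
      v <- vox_sel[i]
      per_voxel[i, j] <- crossval_r2(fits[[p]][v, ], halves[[t]][v, ], tl,
                                     hrf, dt_s, regressors = rg)
    }
  }
  iterations <- data.frame(predictor = vapply(pairs, `[`, "", 1),
                           test = vapply(pairs, `[`, "", 2),
                           kind = kind,
                           cv_r2 = colMeans(per_voxel),
                           stringsAsFactors = FALSE)
  list(iterations = iterations, per_voxel = per_voxel, selected = sel, fits = fits)
}

#' Within-subject ANOVA comparing within- vs cross-condition cvR^2
#'
#' Repeated-measures one-within-factor ANOVA on per-subject mean cvR^2,
#' testing whether predictions generalise as well across stimulus ranges as
#' within them (a non-significant result is consistent with stable tuning).
#'
#' @param df Data.frame with columns `subject`, `kind`
#'   (`"within"`/`"cross"`), `cv_r2`.
#' @return List with `F`, `p`, `df` and the `aov` object.
#' @export
crossval_anova <- function(df) {
  df$subject <- factor(df$subject)
  df$kind <- factor(df$kind)
  fit <- stats::aov(cv_r2 ~ kind + Error(subject / kind), data = df)
  tab <- summary(fit)[["Error: subject:kind"]][[1]]
  list(F = tab["kind", "F value"], p = tab["kind", "Pr(>F)"],
       df = unname(tab[, "Df"]), aov = fit)
}
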