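#' Numerosity tuning parameters
#'
#' A voxel's population tuning model: a Gaussian in logarithmic (base-2)
#' numerosity space with mean `log2(preferred)` and standard deviation
#' `width_sigma`, scaled by a BOLD `gain` and shifted by a `baseline`.
#'
#' @param preferred Preferred numerosity (> 0); the count eliciting the
#'   maximal response.
#' @param width_sigma Tuning width: SD of the Gaussian in log2-numerosity
#'   units (> 0).
#' @param gain BOLD response amplitude (arbitrary units).
#' @param baseline BOLD offset.
#' @return An object of class `tuning_params`.
#' @export
tuning_params <- function(preferred, width_sigma, gain = 1, baseline = 0) {
  if (!is.numeric(preferred) || preferred <= 0) stopf("preferred must be > 0")
  if (!is.numeric(width_sigma) || width_sigma <= 0) stopf("width_sigma must be > 0")
  structure(list(preferred = preferred, width_sigma = width_sigma,
                 gain = gain, baseline = baseline),
            class = "tuning_params")
}

#' Tuned neural response to a numerosity
#'
#' Evaluates the normalized log-Gaussian tuning function:
#' `exp(-(log2(n) - log2(preferred))^2 / (2 * width_sigma^2))`.
#' The response is 1 at `n = preferred` and symmetric about it on a log2 axis.
#'
#' @param n Presented numerosity (vectorised, all > 0).
#' @param params A [tuning_params()].
#' @return Responses in (0, 1].
#' @export
tuning_response <- function(n, params) {
  if (any(n <= 0)) stopf("numerosity must be > 0")
  z <- (log2(n) - log2(params$preferred)) / params$width_sigma
  exp(-z^2 / 2)
}

#' Tuning width as full width at half maximum
#'
#' `fwhm_log2` gives the FWHM of the tuning curve on the log2-numerosity
#' axis, `2 * sqrt(2 * log(2)) * width_sigma`. `fwhm_linear` gives the span in
#' linear numerosity units between the two half-maximum points,
#' `preferred * (2^h - 2^-h)` with `h = sqrt(2 * log(2)) * width_sigma`;
#' at fixed sigma it is proportional to the preferred numerosity.
#' `sigma_from_fwhm_linear` inverts the linear form.
#'
#' @param width_sigma Tuning SD in log2 units.
#' @return Width in log2 (`fwhm_log2`) or linear (`fwhm_linear`) numerosity
#'   units.
#' @export
fwhm_log2 <- function(width_sigma) 2 * sqrt(2 * log(2)) * width_sigma

#' @rdname fwhm_log2
#' @param params A [tuning_params()].
#' @export
fwhm_linear <- function(params) {
  h <- sqrt(2 * log(2)) * params$width_sigma
  params$preferred * (2^h - 2^(-h))
}

#' @rdname fwhm_log2
#' @param preferred Preferred numerosity.
#' @param fwhm Linear FWHM (numerosity units).
#' @export
sigma_from_fwhm_linear <- function(preferred, fwhm) {
  # solve preferred * (z - 1/z) = fwhm for z = 2^h, h = sqrt(2 log 2) * sigma
  s <- fwhm / preferred
  z <- (s + sqrt(s^2 + 4)) / 2
  log2(z) / sqrt(2 * log(2))
}

#' Hemodynamic response function parameters
#'
#' Canonical two-gamma HRF. The kernel is the difference of two gamma
#' densities parameterised so that `peak_s` and `undershoot_s` are the exact
#' modes of the positive lobe and undershoot; the kernel is normalised to
#' unit sum, so a sustained unit neural drive produces a BOLD plateau of 1
#' and the fitted gain reads as a BOLD amplitude.
#'
#' @param peak_s Peak delay in seconds (default 6).
#' @param undershoot_s Undershoot delay in seconds (default 16).
#' @param disp_peak_s,disp_under_s Dispersions in seconds (default 1).
#' @param ratio Undershoot amplitude relative to the peak lobe (default 1/6).
#' @param duration_s Kernel support in seconds (default 32).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_s = 6, undershoot_s = 16, disp_peak_s = 1,
                       disp_under_s = 1, ratio = 1 / 6, duration_s = 32) {
  if (peak_s <= 0 || undershoot_s <= 0) stopf("delays must be > 0")
  if (disp_peak_s <= 0 || disp_under_s <= 0) stopf("dispersions must be > 0")
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 disp_peak_s = disp_peak_s, disp_under_s = disp_under_s,
                 ratio = ratio, duration_s = duration_s),
            class = "hrf_params")
}

#' @rdname hrf_params
#' @param hrf An `hrf_params` object.
#' @param dt_s Sampling step in seconds.
#' @return `hrf_kernel` returns the sampled kernel (unit sum).
#' @export
hrf_kernel <- function(hrf = hrf_params(), dt_s = 0.05) {
  t <- seq(0, hrf$duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = hrf$peak_s / hrf$disp_peak_s + 1,
                     rate = 1 / hrf$disp_peak_s) -
       hrf$ratio * stats::dgamma(t, shape = hrf$undershoot_s / hrf$disp_under_s + 1,
                                 rate = 1 / hrf$disp_under_s)
  if (sum(h) * dt_s <= 0) stopf("HRF kernel must integrate to a positive value")
  h / sum(h)
}

#' Fine-resolution neural response train
#'
#' Samples the predicted neural response of a tuned population on a regular
#' `dt_s` grid spanning the retained run: during each dot presentation the
#' response equals [tuning_response()] of the presented numerosity; it is zero
#' during the 350 ms blank gaps and between events. Catch-trial colour never
#' affects the response.
#'
#' @param timeline A `stimulus_timeline` (see [events_to_timeline()]).
#' @param params A [tuning_params()].
#' @param dt_s Sampling step in seconds (default 0.05; must divide the TR).
#' @return Numeric vector of length `retained_duration_s / dt_s`.
#' @export
neural_timecourse <- function(timeline, params, dt_s = 0.05) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  n_fine <- round(retained_duration_s(timeline$protocol) / dt_s)
  x <- numeric(n_fine)
  ev <- timeline$events
  if (nrow(ev)) {
    resp <- tuning_response(ev$numerosity, params)
    i0 <- round(ev$onset / dt_s) + 1L
    i1 <- pmin(round((ev$onset + ev$duration) / dt_s), n_fine)
    for (j in seq_len(nrow(ev))) if (i0[j] <= i1[j]) x[i0[j]:i1[j]] <- resp[j]
  }
  x
}

#' Predict the BOLD time course
#'
#' Convolves a fine-resolution neural train with the HRF kernel and samples
#' the result at the retained volume onset times (0-based), giving the unit
#' prediction (gain 1, baseline 0) at the TR grid.
#'
#' @param neural Fine-resolution neural train (see [neural_timecourse()]).
#' @param hrf An [hrf_params()].
#' @param protocol A [scan_protocol()].
#' @param dt_s Sampling step used for `neural` (must divide the TR evenly).
#' @return Numeric vector of length `n_retained(protocol)`.
#' @export
predict_bold <- function(neural, hrf = hrf_params(), protocol = scan_protocol(),
                         dt_s = 0.05) {
  steps_per_tr <- tr_s(protocol) / dt_s
  if (abs(steps_per_tr - round(steps_per_tr)) > 1e-9)
    stopf("dt_s must divide the TR evenly")
  h <- hrf_kernel(hrf, dt_s)
  full <- stats::convolve(neural, rev(h), type = "open")[seq_along(neural)]
  idx <- round((seq_len(n_retained(protocol)) - 1) * round(steps_per_tr)) + 1L
  full[idx]
}

#' Per-numerosity convolved regressors for a timeline
#'
#' Because the neural train is a linear combination of indicator trains (one
#' per distinct presented numerosity) weighted by the tuning response, the
#' BOLD prediction for *any* tuning parameters is `R %*% tuning_response(v)`,
#' where `R` holds the convolved, TR-sampled indicator train of each distinct
#' numerosity `v`. Precomputing `R` makes grid fitting cheap.
#'
#' @inheritParams neural_timecourse
#' @param hrf An [hrf_params()].
#' @return Matrix of size `n_retained x n_distinct_numerosities`, columns
#'   named by numerosity.
#' @export
timeline_regressors <- function(timeline, hrf = hrf_params(), dt_s = 0.05) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  vals <- sort(unique(timeline$events$numerosity))
  n_fine <- round(retained_duration_s(timeline$protocol) / dt_s)
  R <- matrix(0, n_retained(timeline$protocol), length(vals),
              dimnames = list(NULL, vals))
  for (j in seq_along(vals)) {
    ev <- timeline$events[timeline$events$numerosity == vals[j], , drop = FALSE]
    ind <- numeric(n_fine)
    i0 <- round(ev$onset / dt_s) + 1L
    i1 <- pmin(round((ev$onset + ev$duration) / dt_s), n_fine)
    for (k in seq_len(nrow(ev))) if (i0[k] <= i1[k]) ind[i0[k]:i1[k]] <- 1
    R[, j] <- predict_bold(ind, hrf, timeline$protocol, dt_s)
  }
  R
}

#' Unit BOLD prediction for given tuning parameters
#'
#' Convenience wrapper: evaluates the tuned neural train for `params` and
#' returns its convolved, TR-sampled unit prediction. If a precomputed
#' regressor matrix is supplied the linear shortcut is used.
#'
#' @inheritParams neural_timecourse
#' @param hrf An [hrf_params()].
#' @param regressors Optional precomputed [timeline_regressors()] matrix.
#' @return Numeric vector of length `n_retained`.
#' @export
predict_timecourse <- function(timeline, params, hrf = hrf_params(), dt_s = 0.05,
                               regressors = NULL) {
  if (!is.null(regressors)) {
    w <- tuning_response(as.numeric(colnames(regressors)), params)
    return(drop(regressors %*% w))
  }
  predict_bold(neural_timecourse(timeline, params, dt_s), hrf,
               timeline$protocol, dt_s)
}
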