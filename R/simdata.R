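#' Noise model for simulated BOLD time series
#'
#' Additive noise drawn per run: white Gaussian or AR(1) (scaled so the
#' marginal SD equals `sd` in both cases).
#'
#' @param type `"white"` or `"ar1"`.
#' @param sd Marginal noise SD in BOLD units (default 0.5, i.e.
#'   contrast-to-noise gain/sd = 2 for unit gain).
#' @param rho AR(1) coefficient (|rho| < 1; default 0.3, used only for
#'   `"ar1"`).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(type = c("white", "ar1"), sd = 0.5, rho = 0.3) {
  type <- match.arg(type)
  if (sd < 0) stopf("noise sd must be >= 0")
  if (abs(rho) >= 1) stopf("|rho| must be < 1")
  structure(list(type = type, sd = sd, rho = rho), class = "noise_model")
}

draw_noise <- function(noise, n) {
  if (noise$sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = noise$sd)
  if (noise$type == "white") return(e)
  x <- numeric(n)
  x[1] <- e[1]
  for (t in 2:n) x[t] <- noise$rho * x[t - 1] + sqrt(1 - noise$rho^2) * e[t]
  x
}

#' Heterogeneous sub-population mixture within a voxel
#'
#' Models a recording site as `k` neural sub-populations whose preferred
#' numerosities are drawn log-normally around the voxel centre (SD
#' `spread_log2` in log2 units, equal gains). With `k = 1` or `spread_log2 =
#' 0` the voxel reduces exactly to a homogeneous population.
#'
#' @param k Sub-populations per voxel (>= 1).
#' @param spread_log2 SD of sub-population preferred numerosities about the
#'   voxel centre, in log2 units (>= 0).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(k = 1, spread_log2 = 0) {
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (spread_log2 < 0) stopf("spread_log2 must be >= 0")
  structure(list(k = as.integer(k), spread_log2 = spread_log2),
            class = "mixture_spec")
}

#' Generate a ground-truth topographic numerosity map
#'
#' Builds a rectangular surface patch with the low- and high-preference
#' borders at its two ends and recording sites whose preferred numerosity is
#' exponential in axial position (log2 preference linear in cortical
#' distance), so equal log steps occupy equal cortex and linear numerosity
#' steps occupy shrinking cortex -- the cortical magnification of small
#' numerosities. Tuning widths follow a linear width law in linear FWHM
#' units, `FWHM = c0 + c1 * preferred`.
#'
#' @param n_sites Number of recording sites (>= 10; default 120).
#' @param p_min,p_max Preferred numerosity at the two map ends (default
#'   1 and 64).
#' @param length_mm Map length along the progression axis (default 16).
#' @param width_mm Map width across the axis (default 4).
#' @param width_law Length-2 numeric `c(c0, c1)`: FWHM intercept and slope
#'   in linear numerosity units (default `c(6, 2)`, giving an FWHM of 10 at
#'   a preferred numerosity of 2).
#' @param gain,baseline BOLD gain and offset given to every site.
#' @param seed Optional integer seed (controls the across-axis jitter of
#'   site positions).
#' @return A `ground_truth_map` list: `truth` (data.frame of per-site
#'   position and tuning), `patch` (a [surface_patch()]), `roi` (an
#'   [roi_map()]), `length_mm`, `width_law`, and the generator's
#'   `progression_slope` (log2 units per mm).
#' @export
make_ground_truth_map <- function(n_sites = 120, p_min = 1, p_max = 64,
                                  length_mm = 16, width_mm = 4,
                                  width_law = c(6, 2), gain = 1, baseline = 0,
                                  seed = NULL) {
  if (!is_count(n_sites) || n_sites < 10) stopf("need at least 10 sites")
  if (p_min < 1 || p_min >= p_max) stopf("need 1 <= p_min < p_max")
  if (length_mm <= 0 || width_mm <= 0) stopf("map dimensions must be > 0")
  x <- seq(0, length_mm, length.out = n_sites)
  y <- with_seed(seed, stats::runif(n_sites, 0, width_mm))
  log2p <- log2(p_min) + (x / length_mm) * (log2(p_max) - log2(p_min))
  preferred <- 2^log2p
  fwhm <- width_law[1] + width_law[2] * preferred
  if (any(fwhm <= 0)) stopf("width law produces non-positive widths")
  sigma <- sigma_from_fwhm_linear(preferred, fwhm)
  truth <- data.frame(id = seq_len(n_sites), x_mm = x, y_mm = y,
                      preferred = preferred, width_sigma = sigma,
                      fwhm_linear = fwhm, gain = gain, baseline = baseline)
  corners <- data.frame(x_mm = c(0, length_mm, length_mm, 0),
                        y_mm = c(0, 0, width_mm, width_mm))
  patch <- surface_patch(rbind(corners, truth[, c("x_mm", "y_mm")]))
  roi <- roi_map(truth[, c("id", "x_mm", "y_mm")],
                 low_border = cbind(c(0, 0), c(0, width_mm)),
                 high_border = cbind(c(length_mm, length_mm), c(0, width_mm)))
  structure(list(truth = truth, patch = patch, roi = roi,
                 length_mm = length_mm, width_mm = width_mm,
                 width_law = width_law,
                 progression_slope = (log2(p_max) - log2(p_min)) / length_mm),
            class = "ground_truth_map")
}

#' Simulate a voxel's BOLD responses
#'
#' Forward-simulates one recording site under one or more stimulus
#' timelines: the (possibly heterogeneous) tuned neural response is
#' convolved with the HRF, scaled by the gain, shifted by the baseline, and
#' independent noise is added per run. For a mixture voxel the signal is the
#' mean of the `k` sub-population unit predictions (equal gains). Output is
#' deterministic under a given seed; a mixture with `spread_log2 = 0` is
#' bit-identical to the homogeneous voxel (no random draws are consumed).
#'
#' @param params A [tuning_params()] giving the voxel-centre tuning.
#' @param timelines A single `stimulus_timeline` or a named list of them
#'   (one per condition).
#' @param hrf An [hrf_params()].
#' @param noise A [noise_model()].
#' @param n_runs Independent runs per condition (default 1).
#' @param mixture Optional [mixture_spec()].
#' @param seed Optional integer seed.
#' @param dt_s Fine sampling step.
#' @param regressors Optional named list of precomputed
#'   [timeline_regressors()] matrices (one per timeline), to avoid repeated
#'   convolution when simulating many voxels.
#' @return For a single timeline, an `n_runs x n_retained` matrix; for a
#'   list, a named list of such matrices.
#' @export
simulate_voxel <- function(params, timelines, hrf = hrf_params(),
                           noise = noise_model(), n_runs = 1, mixture = NULL,
                           seed = NULL, dt_s = 0.05, regressors = NULL) {
  single <- inherits(timelines, "stimulus_timeline")
  if (single) {
    timelines <- list(run = timelines)
    if (!is.null(regressors) && is.matrix(regressors)) regressors <- list(run = regressors)
  }
  with_seed(seed, {
    sub_pref <- if (!is.null(mixture) && mixture$spread_log2 > 0) {
      2^stats::rnorm(mixture$k, mean = log2(params$preferred),
                     sd = mixture$spread_log2)
    } else rep(params$preferred, if (is.null(mixture)) 1L else mixture$k)
    out <- lapply(names(timelines), function(cond) {
      tl <- timelines[[cond]]
      R <- if (!is.null(regressors)) regressors[[cond]] else
        timeline_regressors(tl, hrf, dt_s)
      U <- vapply(sub_pref, function(p)
        predict_timecourse(tl, tuning_params(p, params$width_sigma), hrf, dt_s,
                           regressors = R),
        numeric(n_retained(tl$protocol)))
      signal <- params$baseline + params$gain * rowMeans(U)
      t(vapply(seq_len(n_runs), function(r) signal + draw_noise(noise, length(signal)),
               numeric(length(signal))))
    })
    names(out) <- names(timelines)
    if (single) out[[1]] else out
  })
}

#' Simulate a full numerosity-mapping experiment
#'
#' Generates, for every site of a ground-truth map and every stimulus
#' condition, `n_runs` noisy BOLD runs -- a complete synthetic dataset with
#' known per-voxel tuning, ready for the fitting, geometry and statistics
#' stages (and for the split-half cross-validation, which needs the
#' individual runs).
#'
#' @param map A [make_ground_truth_map()] result.
#' @param designs Named list of `stimulus_timeline`s (e.g. `small`, `large`).
#' @param hrf An [hrf_params()].
#' @param noise A [noise_model()].
#' @param n_runs Runs per condition (default 8).
#' @param mixture Optional [mixture_spec()] applied to every voxel
#'   (sub-population draws are independent across voxels).
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param dt_s Fine sampling step.
#' @return A `sim_experiment` list: `bold` (per condition, a list of
#'   `n_runs` matrices of size `voxels x TR`), `mean_bold` (per condition,
#'   the run average), `map`, `designs`, `noise`, `n_runs`.
#' @export
simulate_experiment <- function(map, designs, hrf = hrf_params(),
                                noise = noise_model(), n_runs = 8,
                                mixture = NULL, seed = NULL, dt_s = 0.05) {
  stopifnot(inherits(map, "ground_truth_map"))
  nv <- nrow(map$truth)
  regs <- lapply(designs, timeline_regressors, hrf = hrf, dt_s = dt_s)
  with_seed(seed, {
    bold <- lapply(designs, function(tl) {
      n_tr <- n_retained(tl$protocol)
      lapply(seq_len(n_runs), function(r) matrix(NA_real_, nv, n_tr))
    })
    for (v in seq_len(nv)) {
      pars <- tuning_params(map$truth$preferred[v], map$truth$width_sigma[v],
                            map$truth$gain[v], map$truth$baseline[v])
      sims <- simulate_voxel(pars, designs, hrf, noise, n_runs, mixture,
                             seed = NULL, dt_s = dt_s, regressors = regs)
      for (cond in names(designs))
        for (r in seq_len(n_runs)) bold[[cond]][[r]][v, ] <- sims[[cond]][r, ]
    }
    mean_bold <- lapply(bold, function(runs) Reduce(`+`, runs) / length(runs))
    structure(list(bold = bold, mean_bold = mean_bold, map = map,
                   designs = designs, noise = noise, n_runs = n_runs),
              class = "sim_experiment")
  })
}

#' Write a simulated experiment to plain-text fixture files
#'
#' Emits, under `dir`: one BIDS-style events TSV per condition, one
#' `voxels x TR` BOLD TSV per condition and run, the surface-patch vertex
#' TSV, the ROI border TSV, and the ground-truth tuning TSV.
#'
#' @param sim A [simulate_experiment()] bundle.
#' @param dir Output directory (created if missing).
#' @param events Optional named list of `numerosity_events` matching the
#'   conditions; when supplied they are written alongside the data.
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixture <- function(sim, dir, events = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (cond in names(sim$bold)) {
    if (!is.null(events) && cond %in% names(events)) {
      p <- file.path(dir, sprintf("events_%s.tsv", cond))
      write_events(events[[cond]], p)
      paths <- c(paths, p)
    }
    for (r in seq_along(sim$bold[[cond]]))
      wr(sim$bold[[cond]][[r]], sprintf("bold_%s_run%02d.tsv", cond, r))
  }
  wr(sim$map$patch$vertices, "surface.tsv")
  borders <- rbind(data.frame(border = "low", x_mm = sim$map$roi$low_border[, 1],
                              y_mm = sim$map$roi$low_border[, 2]),
                   data.frame(border = "high", x_mm = sim$map$roi$high_border[, 1],
                              y_mm = sim$map$roi$high_border[, 2]))
  wr(borders, "roi_borders.tsv")
  wr(sim$map$truth, "ground_truth.tsv")
  invisible(paths)
}
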