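#' Scan protocol
#'
#' Describes the fMRI acquisition grid for one functional run: the repetition
#' time (TR), the number of acquired volumes, and how many initial volumes are
#' discarded before analysis (to reach steady-state magnetisation).
#'
#' @param tr_ms Milliseconds per volume (default 1950).
#' @param n_frames Volumes acquired per run (default 182, i.e. 354.9 s).
#' @param n_discard Initial volumes dropped (default 6, i.e. 11.7 s).
#' @return An object of class `scan_protocol`.
#' @examples
#' p <- scan_protocol()
#' n_retained(p)    # 176
#' @export
scan_protocol <- function(tr_ms = 1950, n_frames = 182, n_discard = 6) {
  if (!is.numeric(tr_ms) || tr_ms <= 0) stopf("tr_ms must be > 0")
  if (!is_count(n_frames) || !is_count(n_discard)) stopf("n_frames and n_discard must be integers")
  if (n_discard < 0 || n_frames <= n_discard) stopf("need n_frames > n_discard >= 0")
  structure(list(tr_ms = tr_ms, n_frames = as.integer(n_frames),
                 n_discard = as.integer(n_discard)),
            class = "scan_protocol")
}

#' @rdname scan_protocol
#' @param protocol A `scan_protocol`.
#' @export
n_retained <- function(protocol) protocol$n_frames - protocol$n_discard

#' @rdname scan_protocol
#' @export
tr_s <- function(protocol) protocol$tr_ms / 1000

#' @rdname scan_protocol
#' @export
run_duration_s <- function(protocol) protocol$n_frames * protocol$tr_ms / 1000

#' @rdname scan_protocol
#' @export
retained_duration_s <- function(protocol) n_retained(protocol) * protocol$tr_ms / 1000

#' Numerosity range specification
#'
#' The set of main numerosities swept during a run plus the high-numerosity
#' baseline shown during the long rest blocks. Built-in ranges: `"small"`
#' (1--7 dots, baseline 20), `"large"` (octave steps 1--64, baseline 512) and
#' `"large_control"` (8--64, baseline 512). The baseline numerosity is far
#' above the mains so that populations tuned inside the range respond little
#' during baseline.
#'
#' @param name One of `"small"`, `"large"`, `"large_control"`, `"custom"`.
#' @param main_values Strictly increasing integer numerosities; required for
#'   `"custom"`, otherwise defaults per range.
#' @param baseline_value Baseline numerosity, must exceed `max(main_values)`.
#' @return An object of class `range_spec`.
#' @export
range_spec <- function(name = c("small", "large", "large_control", "custom"),
                       main_values = NULL, baseline_value = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    small         = list(main = 1:7,              base = 20L),
    large         = list(main = c(1L, 2L, 4L, 8L, 16L, 32L, 64L), base = 512L),
    large_control = list(main = c(8L, 16L, 32L, 64L),             base = 512L),
    custom        = list(main = NULL, base = NULL))
  if (is.null(main_values)) main_values <- defaults$main
  if (is.null(baseline_value)) baseline_value <- defaults$base
  if (is.null(main_values) || is.null(baseline_value))
    stopf("custom range needs main_values and baseline_value")
  main_values <- as.integer(main_values)
  if (any(main_values < 1)) stopf("numerosities must be >= 1")
  if (any(diff(main_values) <= 0)) stopf("main_values must be strictly increasing")
  if (baseline_value <= max(main_values)) stopf("baseline_value must exceed max(main_values)")
  structure(list(name = name, main_values = main_values,
                 baseline_value = as.integer(baseline_value)),
            class = "range_spec")
}

# Pad or pass through the main values to fill `n_slots` ascending 2-TR slots.
# Ranges with fewer values than slots (large_control) repeat values evenly.
pad_slots <- function(main_values, n_slots) {
  k <- length(main_values)
  if (k == n_slots) return(main_values)
  if (k > n_slots)
    stopf("range has %d main values but the cycle structure has only %d slots", k, n_slots)
  main_values[round(seq(1, k, length.out = n_slots))]
}

#' Build a run's presentation sequence
#'
#' Constructs the full per-presentation event list for one functional run of
#' the numerosity block design: each main numerosity occupies 2 TRs (3900 ms)
#' as 6 presentations of 300 ms dots followed by 350 ms blank, mains sweep in
#' ascending order, then a 15.6 s baseline block, then the descending sweep,
#' then a second baseline block; the whole cycle repeats `n_cycles` times and
#' exactly fills the retained volumes. A fraction `catch_rate` of
#' presentations shows white instead of black dots (attention catch trials);
#' catch colouring never enters the neural model.
#'
#' Event onsets are in seconds from the first *retained* volume.
#'
#' @param range_spec A [range_spec()].
#' @param protocol A [scan_protocol()].
#' @param n_cycles Cycles per run (default 4).
#' @param catch_rate Fraction of presentations drawn white (default 0.10).
#' @param seed Optional integer seed for the catch-trial draw.
#' @param present_s Seconds between presentation onsets (default 0.65).
#' @param on_s Seconds a dot pattern stays on screen (default 0.30).
#' @param baseline_s Duration of each baseline block in seconds (default 15.6).
#' @return A `numerosity_events` data.frame with columns `onset`, `duration`,
#'   `numerosity`, `trial_type` (`"main"`/`"baseline"`), `colour`
#'   (`"black"`/`"white"`), carrying the range and protocol as attributes.
#' @export
build_sequence <- function(range_spec, protocol = scan_protocol(), n_cycles = 4,
                           catch_rate = 0.10, seed = NULL,
                           present_s = 0.65, on_s = 0.30, baseline_s = 15.6) {
  stopifnot(inherits(range_spec, "range_spec"), inherits(protocol, "scan_protocol"))
  if (!is_count(n_cycles) || n_cycles < 1) stopf("n_cycles must be a positive integer")
  if (catch_rate < 0 || catch_rate >= 1) stopf("catch_rate must lie in [0, 1)")

  tr <- tr_s(protocol)
  n_ret <- n_retained(protocol)
  step_tr <- 2L                                 # one numerosity value per 2 TRs
  base_tr <- baseline_s / tr
  if (abs(base_tr - round(base_tr)) > 1e-9)
    stopf("baseline block (%.3f s) is not a whole number of TRs", baseline_s)
  base_tr <- as.integer(round(base_tr))

  # cycle = ascending sweep + baseline + descending sweep + baseline
  tr_per_cycle <- n_ret / n_cycles
  slots <- (tr_per_cycle - 2 * base_tr) / (2 * step_tr)
  if (abs(slots - round(slots)) > 1e-9 || slots < 1)
    stopf(paste0("cycle structure does not fit the retained frames: ",
                 "%d retained TRs / %d cycles = %.2f TRs per cycle, of which ",
                 "%d are baseline, leaving a non-integral number of 2-TR steps"),
          n_ret, n_cycles, tr_per_cycle, 2L * base_tr)
  slots <- as.integer(round(slots))
  values <- pad_slots(range_spec$main_values, slots)

  reps_per_step <- step_tr * tr / present_s      # presentations per numerosity step
  base_reps <- baseline_s / present_s
  if (abs(reps_per_step - round(reps_per_step)) > 1e-9 ||
      abs(base_reps - round(base_reps)) > 1e-9)
    stopf("presentation period %.3f s does not tile the block structure", present_s)
  reps_per_step <- as.integer(round(reps_per_step))
  base_reps <- as.integer(round(base_reps))

  cyc_num <- c(rep(values, each = reps_per_step),
               rep(range_spec$baseline_value, base_reps),
               rep(rev(values), each = reps_per_step),
               rep(range_spec$baseline_value, base_reps))
  cyc_type <- c(rep("main", slots * reps_per_step),
                rep("baseline", base_reps),
                rep("main", slots * reps_per_step),
                rep("baseline", base_reps))
  num <- rep(cyc_num, n_cycles)
  type <- rep(cyc_type, n_cycles)
  n_ev <- length(num)

  catch <- if (catch_rate > 0) {
    with_seed(seed, stats::runif(n_ev) < catch_rate)
  } else rep(FALSE, n_ev)

  ev <- data.frame(
    onset = (seq_len(n_ev) - 1) * present_s,
    duration = on_s,
    numerosity = num,
    trial_type = type,
    colour = ifelse(catch, "white", "black"),
    stringsAsFactors = FALSE)
  structure(ev, range_spec = range_spec, protocol = protocol,
            class = c("numerosity_events", "data.frame"))
}

#' Convert events to a per-TR stimulus timeline
#'
#' Labels every retained volume with the numerosity occupying the majority of
#' its TR window (ties broken toward the earlier event) and keeps the
#' fine-grained presentation train for neural-model convolution. TRs that no
#' event touches are labelled with the baseline numerosity.
#'
#' @param events A `numerosity_events` data.frame (see [build_sequence()]).
#' @param protocol A [scan_protocol()]; defaults to the one attached to `events`.
#' @param range_spec A [range_spec()]; defaults to the one attached to `events`.
#' @return An object of class `stimulus_timeline`: list with `per_tr`
#'   (integer numerosity per retained volume), `events` (the fine train),
#'   `protocol`, `range_spec`.
#' @export
events_to_timeline <- function(events, protocol = attr(events, "protocol"),
                               range_spec = attr(events, "range_spec")) {
  if (is.null(protocol)) stopf("no protocol supplied or attached to events")
  if (is.null(range_spec)) stopf("no range_spec supplied or attached to events")
  tr <- tr_s(protocol)
  n_ret <- n_retained(protocol)
  dur_s <- n_ret * tr

  if (nrow(events) > 0) {
    ends <- events$onset + events$duration
    if (any(events$onset < 0) || any(ends > dur_s + 1e-9))
      stopf("event outside the retained run window (0 to %.2f s)", dur_s)
  }

  per_tr <- rep(range_spec$baseline_value, n_ret)
  if (nrow(events) > 0) {
    for (k in seq_len(n_ret)) {
      w0 <- (k - 1) * tr; w1 <- k * tr
      ov <- pmin(events$onset + events$duration, w1) - pmax(events$onset, w0)
      hit <- ov > 1e-12
      if (!any(hit)) next
      occ <- tapply(ov[hit], events$numerosity[hit], sum)
      best <- names(occ)[occ == max(occ)]
      if (length(best) > 1L) {
        # tie: numerosity of the earliest contributing event
        first_onset <- tapply(events$onset[hit], events$numerosity[hit], min)[best]
        best <- best[which.min(first_onset)]
      }
      per_tr[k] <- as.integer(best)
    }
  }
  structure(list(per_tr = as.integer(per_tr),
                 events = as.data.frame(events)[, c("onset", "duration", "numerosity"),
                                                drop = FALSE],
                 protocol = protocol, range_spec = range_spec),
            class = "stimulus_timeline")
}

#' Generate a constant-total-area random dot pattern
#'
#' Places `n` non-overlapping dots of equal radius uniformly inside a circular
#' aperture, with the *total* dot surface area held constant across
#' numerosities (so luminance/contrast energy does not covary with count):
#' each dot has radius `sqrt(total_area / (n * pi))`.
#'
#' @param n Number of dots (>= 1).
#' @param total_area_deg2 Summed dot area in squared degrees (default 0.785,
#'   the area of a single 1 degree-diameter dot).
#' @param aperture_deg Diameter of the circular stimulus field in degrees
#'   (default 4).
#' @param min_sep_deg Minimum gap between dot edges (default 0.02).
#' @param seed Optional integer seed.
#' @param max_attempts Rejection-sampling attempts per dot before giving up.
#' @return A `dot_pattern` list: `centers` (n x 2 matrix, degrees),
#'   `radius_deg`, `aperture_deg`, `colour`.
#' @export
generate_dot_pattern <- function(n, total_area_deg2 = 0.785, aperture_deg = 4,
                                 min_sep_deg = 0.02, seed = NULL,
                                 max_attempts = 10000) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  radius <- sqrt(total_area_deg2 / (n * pi))
  rmax <- aperture_deg / 2 - radius
  if (rmax <= 0)
    stopf("a single dot of radius %.3f does not fit the %.1f-degree aperture; reduce total_area_deg2",
          radius, aperture_deg)
  min_d <- 2 * radius + min_sep_deg
  centers <- with_seed(seed, {
    xy <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        rr <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(rr * cos(th), rr * sin(th))
        if (i == 1L || all(sqrt(colSums((t(xy[seq_len(i - 1), , drop = FALSE]) - p)^2)) >= min_d)) {
          xy[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stopf("could not place dot %d of %d after %d attempts; reduce total_area_deg2 or min_sep_deg",
              i, n, max_attempts)
    }
    xy
  })
  structure(list(centers = centers, radius_deg = radius,
                 aperture_deg = aperture_deg, colour = "black"),
            class = "dot_pattern")
}

#' Read and write event tables
#'
#' Events are stored as BIDS-style tab-separated tables with columns
#' `onset`, `duration`, `trial_type`, `numerosity`, `colour`.
#' `read_events` validates the schema (all columns present, onsets
#' non-decreasing, numerosities >= 1) and reconstructs the range
#' specification from the table, so `read_events(write_events(x))` returns
#' the same events.
#'
#' @param events A `numerosity_events` data.frame.
#' @param path File path.
#' @return `read_events` returns a `numerosity_events` data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("onset", "duration", "trial_type",
                                               "numerosity", "colour")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  need <- c("onset", "duration", "trial_type", "numerosity", "colour")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stopf("%s is missing required column(s): %s", path, paste(miss, collapse = ", "))
  if (!is.numeric(ev$onset) || !is.numeric(ev$duration) || !is.numeric(ev$numerosity))
    stopf("%s: onset, duration and numerosity must be numeric", path)
  bad <- which(diff(ev$onset) < 0)
  if (length(bad))
    stopf("%s: onset column is not non-decreasing at line %d", path, bad[1] + 2L)  # +1 header, +1 next row
  if (any(ev$numerosity < 1)) stopf("%s: numerosities must be >= 1", path)
  main <- sort(unique(ev$numerosity[ev$trial_type == "main"]))
  base <- unique(ev$numerosity[ev$trial_type == "baseline"])
  rs <- if (length(main) && length(base) == 1L)
    range_spec("custom", main_values = main, baseline_value = base) else NULL
  structure(ev[, need], range_spec = rs,
            class = c("numerosity_events", "data.frame"))
}
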