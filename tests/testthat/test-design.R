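test_that("small-range sequence reproduces the block-design arithmetic", {
  pr <- fx_protocol
  expect_equal(run_duration_s(pr), 354.9)
  expect_equal(pr$n_discard * tr_s(pr), 11.7)
  expect_equal(n_retained(pr), 176)

  ev <- build_sequence(range_spec("small"), pr, seed = 1)
  # a run is 4 cycles of (7 asc + baseline + 7 desc + baseline), each
  # numerosity step 6 presentations of 650 ms = 3900 ms = 2 TRs
  expect_equal(nrow(ev), 528)
  step1 <- ev[ev$numerosity == 1 & ev$onset < 10, ]
  expect_equal(nrow(step1), 6)
  expect_equal(diff(range(step1$onset)) + 0.65, 3.9)
  # first baseline block starts after the 7-step ascending sweep (14 TRs)
  base1 <- ev[ev$trial_type == "baseline" & ev$onset < 50, ]
  expect_equal(min(base1$onset), 14 * tr_s(pr))
  expect_equal(nrow(base1), 24)
  expect_equal(diff(range(base1$onset)) + 0.65, 15.6)
  # events exactly tile the retained run
  expect_equal(nrow(ev) * 0.65, retained_duration_s(pr))
})

test_that("per-TR timeline follows the ascending/descending cycle", {
  tl <- fx_tl_small
  expect_length(tl$per_tr, 176)
  expect_equal(tl$per_tr[1], 1L)
  expect_equal(tl$per_tr[1:14], rep(1:7, each = 2))
  expect_equal(tl$per_tr[15:22], rep(20L, 8))           # baseline block
  expect_equal(tl$per_tr[23:36], rep(7:1, each = 2))    # descending sweep
  expect_equal(tl$per_tr[45:58], rep(1:7, each = 2))    # cycle 2
  # every TR label is a main or baseline numerosity
  expect_true(all(tl$per_tr %in% c(1:7, 20L)))
})

test_that("retained-frame accounting holds for all built-in ranges", {
  for (nm in c("small", "large", "large_control")) {
    ev <- build_sequence(range_spec(nm), fx_protocol, seed = 4)
    expect_equal(nrow(ev) * 0.65, retained_duration_s(fx_protocol), info = nm)
    tl <- events_to_timeline(ev)
    expect_length(tl$per_tr, 176)
  }
  # large-control pads its 4 values over the 7 ascending slots
  evc <- build_sequence(range_spec("large_control"), fx_protocol, seed = 4)
  mains <- unique(evc$numerosity[evc$trial_type == "main"])
  expect_setequal(mains, c(8, 16, 32, 64))
})

test_that("a cycle structure that does not tile the retained frames errors", {
  expect_error(build_sequence(range_spec("small"), scan_protocol(1950, 180, 6)),
               "TR")
  expect_error(build_sequence(range_spec("small"), fx_protocol, n_cycles = 3),
               "TR")
})

test_that("timeline labelling uses majority occupancy with early tie-break", {
  pr <- scan_protocol(2000, 3, 0)
  ev <- data.frame(onset = c(0, 0.9, 2.5), duration = c(0.9, 0.9, 1),
                   numerosity = c(2L, 5L, 3L), trial_type = "main",
                   colour = "black")
  tl <- events_to_timeline(ev, pr, range_spec("small"))
  # TR 1: numerosities 2 and 5 occupy 0.9 s each; tie goes to the earlier event
  expect_equal(tl$per_tr[1], 2L)
  expect_equal(tl$per_tr[2], 3L)
  expect_equal(tl$per_tr[3], 20L)   # untouched TR -> baseline
  # empty event list -> all-baseline timeline
  tl0 <- events_to_timeline(ev[0, ], pr, range_spec("small"))
  expect_equal(tl0$per_tr, rep(20L, 3))
  # event past the run end is rejected
  ev_bad <- data.frame(onset = 5.9, duration = 0.3, numerosity = 1L,
                       trial_type = "main", colour = "black")
  expect_error(events_to_timeline(ev_bad, pr, range_spec("small")), "outside")
})

test_that("catch-event fraction converges to the catch rate", {
  fr <- vapply(1:20, function(s) {
    ev <- build_sequence(range_spec("small"), fx_protocol, seed = 100 + s)
    mean(ev$colour == "white")
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.10), 0.02)   # >10,000 presentations pooled
  # catch colouring never reaches the timeline used by the neural model
  ev <- build_sequence(range_spec("small"), fx_protocol, seed = 5)
  ev2 <- ev; ev2$colour <- "black"
  expect_identical(events_to_timeline(ev)$per_tr, events_to_timeline(ev2)$per_tr)
})

test_that("dot patterns conserve total area and respect the aperture", {
  for (n in c(1, 2, 7, 64, 512)) {
    dp <- generate_dot_pattern(n, seed = n)
    expect_equal(n * pi * dp$radius_deg^2, 0.785, tolerance = 1e-12, info = n)
    # all dots entirely inside the aperture
    expect_true(all(sqrt(rowSums(dp$centers^2)) <= dp$aperture_deg / 2 - dp$radius_deg + 1e-12))
    if (n > 1) {
      d <- as.matrix(dist(dp$centers))
      expect_gte(min(d[upper.tri(d)]), 2 * dp$radius_deg + 0.02 - 1e-12)
    }
  }
  expect_equal(generate_dot_pattern(1, seed = 1)$radius_deg, sqrt(0.785 / pi))
  # infeasible packing is reported with advice
  expect_error(generate_dot_pattern(40, total_area_deg2 = 9, seed = 1), "total_area")
})

test_that("events survive a TSV round trip and malformed tables are rejected", {
  ev <- build_sequence(range_spec("small"), fx_protocol, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(as.data.frame(ev2)[, names(ev)], as.data.frame(ev),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(ev2, "range_spec")$main_values, 1:7)
  expect_equal(attr(ev2, "range_spec")$baseline_value, 20L)

  # missing numerosity column
  bad <- as.data.frame(ev)[, c("onset", "duration", "trial_type", "colour")]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(path), "numerosity")

  # non-monotone onsets are reported with a line number
  bad2 <- as.data.frame(ev)
  bad2$onset[5] <- 0.1
  write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(path), "line 6")
})
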