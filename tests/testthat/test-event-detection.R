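test_that("a single peak with a quiet tail is detected at its sample", {
  v <- c(1, 1, 3, rep(1, 40))  # quiet tail well beyond 2.5 s at 10 Hz
  av <- avm_series(v, 10, "r1")
  ev <- detect_events(av, detector_config(threshold = 2))
  expect_equal(ev$t0_index, 3L)
  expect_equal(ev$t0_time_s, 0.2)
})

test_that("recurrent peaks suppress all but the final boundary event", {
  # Peaks above threshold every 1 s; each interior peak is followed by
  # another within the 2.5 s quiet window, so only the last above-
  # threshold sample (whose truncated window is quiet) qualifies.
  fs <- 10
  v <- rep(1, 100)
  peaks <- seq(5, 95, by = 10)
  v[peaks] <- 3
  ev <- detect_events(avm_series(v, fs, "r"), detector_config(threshold = 2))
  expect_equal(ev$t0_index, 95L)
  expect_equal(oracle_detect(v, 2, 25L), 95L)
})

test_that("a threshold above the maximum yields no events", {
  v <- abs(rnorm(100, 1, 0.1))
  ev <- detect_events(avm_series(v, 20, "r"),
                      detector_config(threshold = max(v) + 1))
  expect_equal(nrow(ev), 0L)
})

test_that("samples equal to the threshold break the quiet period", {
  # the 2.0 sample after the peak is not quiet (quiet needs < threshold)
  v <- c(1, 3, 2, rep(1, 30))
  ev <- detect_events(avm_series(v, 10, "r"), detector_config(threshold = 2))
  expect_equal(ev$t0_index, integer(0))
})

test_that("detector matches the brute-force scan on random series", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      n <- sample(100:1500, 1)
      av <- random_avm_series(n)
      thr <- runif(1, stats::quantile(av$values, 0.5), max(av$values) * 1.05)
      quiet <- sample(3:60, 1) / av$fs_hz
      cfg <- detector_config(threshold = thr, quiet_period_s = quiet)
      got <- detect_events(av, cfg)$t0_index
      want <- oracle_detect(av$values, thr, as.integer(round(quiet * av$fs_hz)))
      expect_identical(got, want)
    }
  })
})

test_that("raising the threshold shrinks the crossing set; the last crossing is always an event", {
  # Note the raw event count is NOT monotone in the threshold: raising
  # it can silence a peak that previously broke another peak's quiet
  # window, turning the earlier peak into a new event.
  withr::with_seed(7, {
    for (rep in 1:30) {
      av <- random_avm_series(500)
      thrs <- sort(runif(6, 0.5, 5))
      n_above <- vapply(thrs, function(th) sum(av$values > th), integer(1))
      expect_true(all(diff(n_above) <= 0))
      for (th in thrs) {
        ev <- detect_events(av, detector_config(threshold = th))
        above <- which(av$values > th)
        if (length(above)) {
          expect_true(max(above) %in% ev$t0_index)
          expect_true(all(av$values[ev$t0_index] > th))
        } else {
          expect_equal(nrow(ev), 0L)
        }
      }
    }
  })
})

test_that("a threshold increase can legitimately create an event", {
  # 5 g peaks 3 s apart with 3 g peaks between them (1 s spacing): at
  # threshold 2 only the final peak has a quiet window; at threshold 4
  # the 3 g peaks are silent and every 5 g peak qualifies.
  fs <- 10
  v <- rep(1, 140)
  v[c(10, 40, 70, 100)] <- 5
  v[c(20, 30, 50, 60, 80, 90, 110, 120)] <- 3
  lo <- detect_events(avm_series(v, fs, "r"), detector_config(threshold = 2))
  hi <- detect_events(avm_series(v, fs, "r"), detector_config(threshold = 4))
  expect_equal(lo$t0_index, 120L)
  expect_equal(hi$t0_index, c(10L, 40L, 70L, 100L))
})

test_that("labeling marks pre-maximum events as ADL, later ones as falls", {
  v <- rep(1, 1200)
  v[100] <- 2.5   # pre-fall activity peak
  v[800] <- 6     # the fall impact (global maximum)
  rec <- accel_record("f1", ax = v, ay = rep(0, 1200), az = rep(0, 1200),
                      fs_hz = 100, class_label = "fall")
  ev <- label_events(rec, detect_events(compute_avm(rec),
                                        detector_config(threshold = 2)))
  expect_equal(ev$t0_index, c(100L, 800L))
  expect_equal(ev$label, c("adl", "fall"))

  # an event exactly at the maximum is a fall
  single <- ev[ev$t0_index == 800L, ]
  expect_equal(single$label, "fall")

  # in an ADL record everything is ADL
  rec_adl <- rec
  rec_adl$class_label <- "adl"
  ev2 <- label_events(rec_adl, detect_events(compute_avm(rec_adl),
                                             detector_config(threshold = 2)))
  expect_equal(unique(ev2$label), "adl")
})

test_that("calibration returns the largest grid threshold detecting every fall", {
  make_fall <- function(id, peak) {
    v <- rep(1, 300)
    v[150] <- peak
    accel_record(id, v, rep(0, 300), rep(0, 300), fs_hz = 25,
                 class_label = "fall")
  }
  falls <- list(make_fall("a", 2.2), make_fall("b", 3.7), make_fall("c", 5))
  cfg <- detector_config()
  th <- calibrate_threshold(falls, cfg = cfg)
  # brute force over the full grid
  grid <- seq(0, 5, by = 0.005)
  ok <- vapply(grid, function(g) {
    all(vapply(falls, function(r) {
      ev <- label_events(r, detect_events(compute_avm(r),
                                          detector_config(threshold = g)))
      any(ev$label == "fall")
    }, logical(1)))
  }, logical(1))
  expect_equal(th, max(grid[ok]))
  expect_lt(th, 2.2)                   # weakest peak must still be crossed
  expect_gt(th, 2.2 - 0.005 - 1e-9)    # grid point just below it works
})

test_that("a 1.2 g fall caps the calibrated threshold at 1.195", {
  v <- rep(1, 300); v[150] <- 1.2
  weak <- accel_record("w", v, rep(0, 300), rep(0, 300), fs_hz = 25,
                       class_label = "fall")
  th <- calibrate_threshold(list(weak), cfg = detector_config())
  expect_lte(th, 1.195)
})

test_that("calibration signals no solution explicitly", {
  v <- rep(1, 300); v[150] <- 1.4
  rec <- accel_record("r", v, rep(0, 300), rep(0, 300), fs_hz = 25,
                      class_label = "fall")
  expect_warning(
    th <- calibrate_threshold(list(rec), grid_lo = 2, grid_hi = 5,
                              cfg = detector_config()),
    "no grid threshold")
  expect_true(is.na(th))
  expect_error(calibrate_threshold(list(), cfg = detector_config()),
               "no fall records")
})

test_that("event-centered extraction honours the margin rule", {
  fs <- 100
  v <- rep(1, 2000)
  v[200] <- 2.6   # 2 s in: insufficient 4 s head margin
  v[1000] <- 3    # 10 s in: fine (and the global max)
  rec <- accel_record("r", v, rep(0, 2000), rep(0, 2000), fs_hz = fs,
                      class_label = "fall")
  out <- build_event_centered(list(rec), detector_config(threshold = 2))
  expect_equal(sum(out$events$retained), 1L)
  expect_equal(nrow(out$events), 2L)
  ecr <- out$ecrs[[1]]
  expect_equal(length(ecr$ax), 2L * 400L + 1L)  # 4 s each side + center
  expect_equal(ecr$center, 401L)
  expect_equal(ecr$avm[ecr$center], 3)

  # margin 0 retains everything
  out0 <- build_event_centered(list(rec),
                               detector_config(threshold = 2,
                                               margin_s = 1e-9))
  expect_equal(sum(out0$events$retained), 2L)

  # retention never grows with the margin
  margins <- c(0.5, 1, 2, 3, 4, 6)
  kept <- vapply(margins, function(m) {
    sum(build_event_centered(list(rec),
                             detector_config(threshold = 2,
                                             margin_s = m))$events$retained)
  }, integer(1))
  expect_true(all(diff(kept) <= 0))
})
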