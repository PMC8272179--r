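#' Detector configuration
#'
#' @param threshold AVM threshold in g that a sample must exceed to start
#'   a potential fall event.
#' @param quiet_period_s Duration (s) after an above-threshold sample
#'   that must stay below the threshold for the sample to qualify as a
#'   potential fall event.  Default 2.5 s.
#' @param margin_s Seconds of data required -- and extracted -- on each
#'   side of an event when building event-centered records.  Default 4 s.
#' @return A `detector_config` list.
#' @export
detector_config <- function(threshold = NA_real_, quiet_period_s = 2.5,
                            margin_s = 4.0) {
  if (!is.na(threshold) && threshold < 0) stop("threshold must be >= 0")
  stopifnot(quiet_period_s > 0, margin_s > 0)
  structure(list(threshold = as.numeric(threshold),
                 quiet_period_s = as.numeric(quiet_period_s),
                 margin_s = as.numeric(margin_s)),
            class = "detector_config")
}

# Seconds -> samples, shared rounding convention for all time offsets.
samples_of <- function(t_s, fs_hz) as.integer(round(t_s * fs_hz))

#' Detect potential fall events in an AVM series
#'
#' A potential fall event is a sample whose AVM exceeds the threshold
#' and is followed by a quiet period: every sample in the
#' `quiet_period_s` window after it stays strictly below the threshold.
#' A quiet window truncated by the end of the record counts as quiet, so
#' an impact shortly before the record ends is still detected.  Within a
#' run of consecutive above-threshold samples only the last one can
#' qualify (every earlier one is followed by an above-threshold sample).
#'
#' @param avm An [avm_series()].
#' @param cfg A [detector_config()] with `threshold` set.
#' @return Data frame of potential events in increasing index order:
#'   `record_id`, `t0_index` (1-based sample index), `t0_time_s`
#'   (`(t0_index - 1) / fs_hz`).
#' @export
detect_events <- function(avm, cfg) {
  stopifnot(inherits(avm, "avm_series"), inherits(cfg, "detector_config"))
  thr <- cfg$threshold
  if (is.na(thr)) stop("detect_events: cfg$threshold is not set")
  v <- avm$values
  empty <- data.frame(record_id = character(0), t0_index = integer(0),
                      t0_time_s = numeric(0), stringsAsFactors = FALSE)
  if (!length(v)) return(empty)
  W <- samples_of(cfg$quiet_period_s, avm$fs_hz)
  if (W < 1L) {
    stop("detect_events: quiet period shorter than one sample at fs = ",
         avm$fs_hz, " Hz")
  }
  above <- which(v > thr)
  if (!length(above)) return(empty)
  # Quiet is violated by any sample >= threshold (not strictly below it).
  viol <- which(v >= thr)
  nxt_pos <- findInterval(above, viol) + 1L   # first violation after each
  nxt <- c(viol, NA_integer_)[nxt_pos]
  keep <- is.na(nxt) | nxt > above + W
  idx <- above[keep]
  data.frame(record_id = rep(avm$record_id, length(idx)),
             t0_index = idx,
             t0_time_s = (idx - 1L) / avm$fs_hz,
             stringsAsFactors = FALSE)
}

#' Label potential events as true falls or ADL
#'
#' In an ADL record every potential event is an ADL by definition.  Fall
#' records may contain ADL activity before the fall itself, so only
#' events detected at or after the largest AVM peak of the record are
#' labeled as falls; events strictly before the global maximum are
#' labeled ADL (they were triggered by pre-fall activity).  Ties in the
#' maximum resolve to its first occurrence.
#'
#' @param record The [accel_record()] the events were detected on.
#' @param events Data frame from [detect_events()].
#' @param avm Optional precomputed [compute_avm()] result for `record`.
#' @return `events` with an added `label` column (`"fall"`/`"adl"`).
#' @export
label_events <- function(record, events, avm = compute_avm(record)) {
  stopifnot(inherits(record, "accel_record"))
  if (!nrow(events)) {
    events$label <- character(0)
    return(events)
  }
  if (record$class_label == "adl") {
    events$label <- "adl"
  } else {
    peak_idx <- which.max(avm$values)
    events$label <- ifelse(events$t0_index >= peak_idx, "fall", "adl")
  }
  events
}

#' Calibrate the detection threshold on a set of fall records
#'
#' Evaluates the detector on a grid of thresholds (default 0 to 5 g in
#' steps of 0.005 g) and returns the largest grid value for which every
#' fall record still yields at least one fall-labeled potential event.
#' Picking the largest such threshold minimises false alarms on ADL data
#' while keeping every fall detectable.
#'
#' @param fall_records List of QC-passed fall [accel_record()]s (or an
#'   `accel_dataset`; only its fall records are used).
#' @param grid_lo,grid_hi,grid_step Threshold grid in g.
#' @param cfg A [detector_config()]; its `threshold` is ignored.
#' @return The calibrated threshold (g).  `NA` with a warning if even
#'   `grid_lo` fails on some record.
#' @export
calibrate_threshold <- function(fall_records, grid_lo = 0, grid_hi = 5,
                                grid_step = 0.005,
                                cfg = detector_config()) {
  records <- as_record_list(fall_records)
  records <- Filter(function(r) r$class_label == "fall", records)
  if (!length(records)) stop("calibrate_threshold: no fall records supplied")
  stopifnot(grid_lo < grid_hi, grid_step > 0)
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  feas_all <- rep(TRUE, length(grid))
  for (rec in records) {
    avm <- compute_avm(rec)
    W <- samples_of(cfg$quiet_period_s, avm$fs_hz)
    if (W < 1L) stop("calibrate_threshold: quiet period < 1 sample")
    feas_all <- feas_all & record_feasible_thresholds(avm$values, grid, W)
    if (!any(feas_all)) break
  }
  if (!any(feas_all)) {
    warning("calibrate_threshold: no grid threshold detects every fall; ",
            "returning NA")
    return(NA_real_)
  }
  max(grid[feas_all])
}

# Grid thresholds under which a series yields >= 1 fall-labeled event.
# Sample i (at or after the global maximum) is a fall event for threshold
# g iff v[i] > g and max of the quiet window after i is < g, i.e.
# g in (max_window_i, v[i]).  The record's feasible set is the union of
# those open intervals over i; the comparisons below are exactly the ones
# detect_events() makes, so equality cases agree bitwise.
record_feasible_thresholds <- function(v, grid, W) {
  n <- length(v)
  peak_idx <- which.max(v)
  feas <- rep(FALSE, length(grid))
  for (i in peak_idx:n) {
    hi <- v[i]
    j2 <- min(i + W, n)
    lo <- if (j2 > i) max(v[(i + 1L):j2]) else -Inf
    if (hi > lo) feas <- feas | (grid > lo & grid < hi)
  }
  feas
}

#' Build event-centered records around labeled potential events
#'
#' Runs detection and labeling on every record, then extracts, for each
#' event with at least `margin_s` of data on both sides, the tri-axial
#' excerpt spanning `[t0 - margin_s, t0 + margin_s]` into a new
#' event-centered record; the event sample sits at the excerpt midpoint.
#' Events without the required margin are dropped and counted.
#'
#' @param records An `accel_dataset` or list of [accel_record()]s
#'   (normally the QC-kept set).
#' @param cfg A [detector_config()] with `threshold` set (e.g. from
#'   [calibrate_threshold()]).
#' @return List with:
#'   * `ecrs`: list of `event_centered_record` objects;
#'   * `events`: data frame of all labeled events with a `retained` flag;
#'   * `retention`: data frame `margin_s, n_fall, n_adl` giving, for
#'     margin 0 and for the configured margin, how many events have that
#'     much data available on both sides.
#' @export
build_event_centered <- function(records, cfg) {
  records <- as_record_list(records)
  stopifnot(inherits(cfg, "detector_config"))
  if (is.na(cfg$threshold)) stop("build_event_centered: threshold not set")
  ecrs <- list()
  rows <- list()
  for (rec in records) {
    avm <- compute_avm(rec)
    ev <- label_events(rec, detect_events(avm, cfg), avm)
    if (!nrow(ev)) next
    M <- samples_of(cfg$margin_s, rec$fs_hz)
    ev$margin_before_s <- (ev$t0_index - 1L) / rec$fs_hz
    ev$margin_after_s <- (rec$N - ev$t0_index) / rec$fs_hz
    ev$retained <- ev$t0_index - M >= 1L & ev$t0_index + M <= rec$N
    for (k in seq_len(nrow(ev))) {
      if (!ev$retained[k]) next
      i0 <- ev$t0_index[k]
      sel <- (i0 - M):(i0 + M)
      ecrs[[length(ecrs) + 1L]] <- structure(
        list(event_id = sprintf("%s_%06d", rec$record_id, i0),
             record_id = rec$record_id,
             t0_index = i0,
             label = ev$label[k],
             activity_type = rec$activity_type,
             subject_id = rec$subject_id,
             fs_hz = rec$fs_hz,
             center = M + 1L,
             ax = rec$ax[sel], ay = rec$ay[sel], az = rec$az[sel],
             avm = avm$values[sel]),
        class = "event_centered_record"
      )
    }
    rows[[length(rows) + 1L]] <- ev
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0), t0_index = integer(0),
               t0_time_s = numeric(0), label = character(0),
               margin_before_s = numeric(0), margin_after_s = numeric(0),
               retained = logical(0))
  retention <- do.call(rbind, lapply(unique(c(0, cfg$margin_s)), function(m) {
    ok <- events$margin_before_s >= m & events$margin_after_s >= m
    data.frame(margin_s = m,
               n_fall = sum(ok & events$label == "fall"),
               n_adl = sum(ok & events$label == "adl"))
  }))
  list(ecrs = ecrs, events = events, retention = retention)
}

#' @export
print.event_centered_record <- function(x, ...) {
  cat(sprintf("<event_centered_record %s> label %s, %d samples @ %g Hz\n",
              x$event_id, x$label, length(x$ax), x$fs_hz))
  invisible(x)
}
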