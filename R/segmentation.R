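#' Enumerate window configurations over the t1--t4 grid
#'
#' The segmentation model places up to three sequential windows around a
#' potential fall event at time t0: the impact window W1 spans
#' `[t0 - t3, t0 + t4)`, the pre-impact window W2 spans
#' `[t0 - t1, t0 - t3)` and the post-impact window W3 spans
#' `[t0 + t4, t0 + t2)`.  t1 and t2 run from 0 to `t_max` in steps of
#' `outer_step`; for each, t3 runs from 0 to t1 and t4 from 0 to t2 in
#' steps of `inner_step`.  The all-zero tuple (every window empty) is
#' excluded.  With the defaults this yields 81 x 81 - 1 = 6560
#' configurations.
#'
#' @param t_max Maximal value of t1 and t2 in seconds (default 4).
#' @param outer_step Step for t1/t2 in seconds (default 0.5).
#' @param inner_step Step for t3/t4 in seconds (default 0.25).
#' @return Data frame with columns `config_id`, `t1`, `t2`, `t3`, `t4`,
#'   `window_class`.
#' @export
enumerate_configs <- function(t_max = 4, outer_step = 0.5,
                              inner_step = 0.25) {
  stopifnot(t_max > 0, outer_step > 0, inner_step > 0)
  if (abs(t_max / outer_step - round(t_max / outer_step)) > 1e-9 ||
      abs(outer_step / inner_step - round(outer_step / inner_step)) > 1e-9) {
    stop("enumerate_configs: steps must divide t_max / each other")
  }
  outer <- seq(0, t_max, by = outer_step)
  # Left side (t1, t3) and right side (t2, t4) vary independently.
  side <- do.call(rbind, lapply(outer, function(t1) {
    data.frame(t1 = t1, t3 = seq(0, t1, by = inner_step))
  }))
  grid <- merge(
    stats::setNames(side, c("t1", "t3")),
    stats::setNames(side, c("t2", "t4"))
  )
  grid <- grid[, c("t1", "t2", "t3", "t4")]
  grid <- grid[order(grid$t1, grid$t2, grid$t3, grid$t4), , drop = FALSE]
  grid <- grid[!(grid$t1 == 0 & grid$t2 == 0 & grid$t3 == 0 & grid$t4 == 0), ]
  rownames(grid) <- NULL
  grid$window_class <- classify_config(grid$t1, grid$t2, grid$t3, grid$t4)
  data.frame(config_id = sprintf("cfg%05d", seq_len(nrow(grid))), grid,
             stringsAsFactors = FALSE)
}

#' Classify a (t1, t2, t3, t4) tuple into its window configuration
#'
#' Applies the configuration criteria row by row:
#' * `W1`: t1 = t3 and t2 = t4 (single impact window);
#' * `W1+W2`: t2 = t4, t1 > t3, and t3 > 0 or t4 > 0;
#' * `W1+W3`: t1 = t3, t2 > t4, and t3 > 0 or t4 > 0;
#' * `W2+W3`: t3 = 0, t4 = 0, t1 > 0, t2 > 0 (empty impact window);
#' * `W1+W2+W3`: t1 > 0, t2 > 0, t1 > t3, t2 > t4, and t3 > 0 or t4 > 0;
#' * the all-zero tuple is `degenerate`.
#'
#' The t1--t4 grid additionally contains 16 tuples with a single
#' pre-impact-only or post-impact-only window (t3 = t4 = 0 and exactly
#' one of t1, t2 positive), which the five criteria above do not cover;
#' they are classified `W2` and `W3` respectively and swept like any
#' other configuration.
#'
#' @param t1,t2,t3,t4 Numeric vectors (recycled to a common length) of
#'   window parameters in seconds, with `0 <= t3 <= t1`, `0 <= t4 <= t2`.
#' @return Character vector of window classes.
#' @export
classify_config <- function(t1, t2, t3, t4) {
  n <- max(length(t1), length(t2), length(t3), length(t4))
  t1 <- rep_len(t1, n); t2 <- rep_len(t2, n)
  t3 <- rep_len(t3, n); t4 <- rep_len(t4, n)
  if (any(t3 < 0 | t4 < 0 | t3 > t1 | t4 > t2)) {
    stop("classify_config: need 0 <= t3 <= t1 and 0 <= t4 <= t2")
  }
  inner <- t3 > 0 | t4 > 0
  out <- rep(NA_character_, n)
  zero <- t1 == 0 & t2 == 0 & t3 == 0 & t4 == 0
  out[zero] <- "degenerate"
  pick <- function(cond) is.na(out) & cond
  out[pick(t1 == t3 & t2 == t4)] <- "W1"
  out[pick(t2 == t4 & t1 > t3 & inner)] <- "W1+W2"
  out[pick(t1 == t3 & t2 > t4 & inner)] <- "W1+W3"
  out[pick(t3 == 0 & t4 == 0 & t1 > 0 & t2 > 0)] <- "W2+W3"
  out[pick(t1 > 0 & t2 > 0 & t1 > t3 & t2 > t4 & inner)] <- "W1+W2+W3"
  out[pick(t3 == 0 & t4 == 0 & t1 > 0 & t2 == 0)] <- "W2"
  out[pick(t3 == 0 & t4 == 0 & t1 == 0 & t2 > 0)] <- "W3"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("classify_config: tuple (%g, %g, %g, %g) matches no rule",
                 t1[bad], t2[bad], t3[bad], t4[bad]))
  }
  out
}

#' Cut an event-centered record into W1/W2/W3 segments
#'
#' Window boundaries are half-open `[start, end)` so adjacent windows
#' never share a sample; time offsets map to sample offsets with
#' `round(t * fs)`, and the event sample itself belongs to W1 whenever
#' W1 is non-empty.  Only the windows belonging to the configuration's
#' window class are emitted, in temporal order W2, W1, W3.
#'
#' @param ecr An `event_centered_record` from [build_event_centered()].
#' @param config A single-row data frame (or list) with `t1`, `t2`,
#'   `t3`, `t4` and `window_class`, as produced by [enumerate_configs()].
#' @return Named list of segments (subset of `W2`, `W1`, `W3`), each a
#'   list with `window_id`, `ax`, `ay`, `az`, `avm`, `fs_hz`, `event_id`.
#' @export
extract_segments <- function(ecr, config) {
  stopifnot(inherits(ecr, "event_centered_record"))
  cls <- config$window_class
  if (identical(cls, "degenerate")) {
    stop("extract_segments: degenerate configuration has no windows")
  }
  fs <- ecr$fs_hz
  n <- length(ecr$ax)
  c0 <- ecr$center
  o1 <- samples_of(config$t1, fs); o2 <- samples_of(config$t2, fs)
  o3 <- samples_of(config$t3, fs); o4 <- samples_of(config$t4, fs)
  if (c0 - o1 < 1L || c0 + o2 - 1L > n) {
    stop("extract_segments: t1/t2 exceed the available margin of '",
         ecr$event_id, "'")
  }
  bounds <- list(
    W2 = c(c0 - o1, c0 - o3 - 1L),
    W1 = c(c0 - o3, c0 + o4 - 1L),
    W3 = c(c0 + o4, c0 + o2 - 1L)
  )
  wanted <- strsplit(cls, "+", fixed = TRUE)[[1L]]
  segs <- list()
  for (w in c("W2", "W1", "W3")) {
    if (!(w %in% wanted)) next
    b <- bounds[[w]]
    if (b[2L] < b[1L]) {
      stop("extract_segments: window ", w, " is empty for class ", cls)
    }
    sel <- b[1L]:b[2L]
    segs[[w]] <- list(window_id = w, ax = ecr$ax[sel], ay = ecr$ay[sel],
                      az = ecr$az[sel], avm = ecr$avm[sel], fs_hz = fs,
                      event_id = ecr$event_id)
  }
  segs
}
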