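#' Eight per-segment magnitude features
#'
#' Computes, from a tri-axial segment of N samples and its AVM trace,
#' the eight features used to discriminate falls from ADL:
#'
#' 1. `avm_mean` -- mean AVM;
#' 2. `avm_max` -- maximal AVM;
#' 3. `avm_min` -- minimal AVM;
#' 4. `avm_range` -- `avm_max - avm_min`;
#' 5. `avm_std` -- population standard deviation of AVM (divisor N);
#' 6. `sma` -- Summed Magnitude Area, `sum(|ax| + |ay| + |az|)`
#'    (an unnormalised sum, so it grows with segment length);
#' 7. `aamv` -- Average Absolute Acceleration Magnitude Variation, the
#'    mean of `|AVM[i+1] - AVM[i]|` over the N - 1 consecutive pairs;
#' 8. `avm_rms` -- `sqrt(sum(ax^2 + ay^2 + az^2))`, i.e.
#'    `sqrt(sum(AVM^2))` (no 1/N factor).
#'
#' All inputs and outputs are in g-derived units.  Orientation-based
#' features are deliberately absent: they would require a known sensor
#' orientation on the body.
#'
#' @param segment A segment from [extract_segments()], or any list with
#'   numeric `ax`, `ay`, `az` (and optionally a precomputed `avm`).
#' @param aamv_divisor `"n_minus_1"` (default: mean over the N - 1
#'   defined differences) or `"n"` (sum of the differences divided by N).
#' @param rms_sqrt Apply the square root in `avm_rms` (default `TRUE`);
#'   `FALSE` returns the plain sum of squares.
#' @return Named numeric vector of length 8.
#' @export
segment_features <- function(segment, aamv_divisor = c("n_minus_1", "n"),
                             rms_sqrt = TRUE) {
  aamv_divisor <- match.arg(aamv_divisor)
  ax <- segment$ax; ay <- segment$ay; az <- segment$az
  n <- length(ax)
  if (n < 2L) stop("segment_features: need >= 2 samples (AAMV undefined)")
  v <- segment$avm
  if (is.null(v)) v <- sqrt(ax^2 + ay^2 + az^2)
  m <- sum(v) / n
  vmax <- max(v)
  vmin <- min(v)
  abs_diff_sum <- sum(abs(v[-1L] - v[-n]))
  ss <- sum(ax^2 + ay^2 + az^2)
  c(avm_mean = m,
    avm_max = vmax,
    avm_min = vmin,
    avm_range = vmax - vmin,
    avm_std = sqrt(sum((v - m)^2) / n),
    sma = sum(abs(ax) + abs(ay) + abs(az)),
    aamv = abs_diff_sum / if (aamv_divisor == "n") n else n - 1L,
    avm_rms = if (rms_sqrt) sqrt(ss) else ss)
}

#' Feature vector for one event-centered record under one configuration
#'
#' Extracts the configuration's windows from the record and concatenates
#' their eight-feature blocks in temporal order (W2, W1, W3, for the
#' windows present), yielding 8, 16 or 24 values named
#' `<window>.<feature>`.
#'
#' @inheritParams extract_segments
#' @inheritParams segment_features
#' @return Named numeric vector of length 8 x (number of windows).
#' @export
config_features <- function(ecr, config,
                            aamv_divisor = c("n_minus_1", "n"),
                            rms_sqrt = TRUE) {
  segs <- extract_segments(ecr, config)
  blocks <- lapply(segs, segment_features, aamv_divisor = aamv_divisor,
                   rms_sqrt = rms_sqrt)
  out <- unlist(blocks)  # names become e.g. "W2.avm_mean"
  out
}

#' Feature matrix for a set of event-centered records
#'
#' @param ecrs List of `event_centered_record`s.
#' @param config One configuration row from [enumerate_configs()].
#' @inheritParams segment_features
#' @return List with `x` (numeric matrix, one row per record), `label`
#'   (factor with levels `adl`, `fall`), `type` (activity type per
#'   record) and `event_id`.
#' @export
feature_matrix <- function(ecrs, config,
                           aamv_divisor = c("n_minus_1", "n"),
                           rms_sqrt = TRUE) {
  stopifnot(length(ecrs) > 0)
  rows <- lapply(ecrs, config_features, config = config,
                 aamv_divisor = aamv_divisor, rms_sqrt = rms_sqrt)
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(ecrs, `[[`, character(1), "event_id")
  list(x = x,
       label = factor(vapply(ecrs, `[[`, character(1), "label"),
                      levels = c("adl", "fall")),
       type = vapply(ecrs, `[[`, character(1), "activity_type"),
       event_id = rownames(x))
}

#' Write a feature table as CSV
#'
#' Columns: `event_id`, `config_id`, `label`, `type`, then the feature
#' columns of [feature_matrix()].
#'
#' @param fm A [feature_matrix()] result.
#' @param config The configuration the features were computed under.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, config, path) {
  df <- data.frame(event_id = fm$event_id,
                   config_id = config$config_id,
                   label = as.character(fm$label),
                   type = fm$type,
                   fm$x, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
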