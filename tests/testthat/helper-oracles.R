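# Independent reference implementations used as oracles.  These stay
# deliberately naive (literal scans, truth tables, textbook formulas) so
# they share no code path with the package.

# Literal O(N * W) scan for the threshold + quiet-period detector: a
# sample qualifies iff it exceeds the threshold and every sample in the
# next W samples (truncated at the end of the series, which counts as
# quiet) stays strictly below it.
oracle_detect <- function(v, thr, W) {
  n <- length(v)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] <= thr) next
    j2 <- min(i + W, n)
    quiet <- if (j2 > i) all(v[(i + 1):j2] < thr) else TRUE
    if (quiet) out <- c(out, i)
  }
  out
}

# Truth-table window classifier: name the set of non-empty windows.
# W1 = [t0-t3, t0+t4), W2 = [t0-t1, t0-t3), W3 = [t0+t4, t0+t2).
oracle_classify <- function(t1, t2, t3, t4) {
  present <- c(W1 = t3 + t4 > 0, W2 = t1 - t3 > 0, W3 = t2 - t4 > 0)
  if (!any(present)) return("degenerate")
  paste(names(present)[present], collapse = "+")
}

# Textbook single-pass feature formulas via base helpers.
oracle_features <- function(ax, ay, az) {
  v <- sqrt(ax^2 + ay^2 + az^2)
  n <- length(v)
  c(avm_mean = mean(v),
    avm_max = max(v),
    avm_min = min(v),
    avm_range = diff(range(v)),
    avm_std = stats::sd(v) * sqrt((n - 1) / n),
    sma = sum(abs(ax)) + sum(abs(ay)) + sum(abs(az)),
    aamv = mean(abs(diff(v))),
    avm_rms = sqrt(sum(v^2)))
}

random_segment <- function(n) {
  list(ax = stats::rnorm(n, 0, 2), ay = stats::rnorm(n, 0.5, 1),
       az = stats::runif(n, -3, 3))
}

# A jagged AVM-like series with resting baseline and occasional bursts.
random_avm_series <- function(n, fs = 40) {
  v <- abs(1 + stats::rnorm(n, 0, 0.1))
  n_burst <- sample(0:6, 1)
  for (b in seq_len(n_burst)) {
    at <- sample(n, 1)
    w <- sample(2:15, 1)
    sel <- at:min(n, at + w)
    v[sel] <- v[sel] + stats::runif(1, 0.5, 6) * stats::runif(length(sel))
  }
  avm_series(v, fs, sprintf("rnd%04d", sample.int(9999, 1)))
}

# Hand-built event-centered record from a magnitude trace (put on one
# axis so the trace is the AVM).
make_ecr <- function(avm_trace, fs, label = "fall", type = "manual",
                     id = "ecr1") {
  n <- length(avm_trace)
  stopifnot(n %% 2 == 1)
  structure(list(event_id = id, record_id = id,
                 t0_index = (n + 1L) %/% 2L, label = label,
                 activity_type = type, subject_id = "S01", fs_hz = fs,
                 center = (n + 1L) %/% 2L,
                 ax = avm_trace, ay = rep(0, n), az = rep(0, n),
                 avm = abs(avm_trace)),
            class = "event_centered_record")
}

# Small end-to-end study: dataset -> QC -> calibration -> ECRs.
build_study <- function(n_fall, n_adl, difficulty, seed, ...) {
  cfg <- generator_config(n_fall_records = n_fall, n_adl_records = n_adl,
                          difficulty = difficulty, seed = seed, ...)
  ds <- generate_dataset(cfg)
  kept <- qc_kept_records(ds)
  th <- calibrate_threshold(kept, cfg = detector_config())
  det <- detector_config(threshold = th)
  list(cfg = cfg, ds = ds, kept = kept, threshold = th, det = det,
       bec = build_event_centered(kept, det))
}
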