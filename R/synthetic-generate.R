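#' Generator configuration
#'
#' @param n_fall_records,n_adl_records Number of fall / ADL records.
#' @param sampling_rate_hz Sampling frequency in Hz.  Values outside
#'   the 25--238 Hz regime of the emulated waist-worn sensors are
#'   permitted with a warning.
#' @param difficulty Class-overlap knob passed to
#'   [default_templates()].
#' @param noise_sd Per-axis Gaussian noise sd in g.
#' @param templates Named list of [activity_template()]s; defaults to
#'   `default_templates(difficulty, noise_sd)`.
#' @param template_mix Optional list with named weight vectors `fall`
#'   and `adl` over the template names; defaults to uniform weights
#'   within each class.
#' @param error_spike_frac Fraction of all records given a one-sample
#'   spike pushing the maximal AVM above 30 g (sensor-error emulation).
#' @param error_lowpeak_frac Fraction of fall records compressed so
#'   every AVM peak stays below 1.1 g (a fall in which no fall was
#'   actually recorded).
#' @param short_tail_frac Fraction of fall records truncated 2 s after
#'   the impact, so their events fail a 4 s margin but survive a 0 s
#'   one (exercises the retention accounting).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_fall_records = 100, n_adl_records = 100,
                             sampling_rate_hz = 100, difficulty = 0.2,
                             noise_sd = 0.03, templates = NULL,
                             template_mix = NULL,
                             error_spike_frac = 0,
                             error_lowpeak_frac = 0,
                             short_tail_frac = 0, seed = 1) {
  stopifnot(n_fall_records >= 0, n_adl_records >= 0,
            sampling_rate_hz > 0,
            error_spike_frac >= 0, error_spike_frac <= 1,
            error_lowpeak_frac >= 0, error_lowpeak_frac <= 1,
            short_tail_frac >= 0, short_tail_frac <= 1)
  if (sampling_rate_hz < 25 || sampling_rate_hz > 238) {
    warning("sampling_rate_hz ", sampling_rate_hz,
            " is outside the emulated 25-238 Hz regime")
  }
  if (is.null(templates)) {
    templates <- default_templates(difficulty, noise_sd)
  }
  cls <- vapply(templates, `[[`, character(1), "class_label")
  if (is.null(template_mix)) {
    template_mix <- list(
      fall = stats::setNames(rep(1, sum(cls == "fall")),
                             names(templates)[cls == "fall"]),
      adl = stats::setNames(rep(1, sum(cls == "adl")),
                            names(templates)[cls == "adl"])
    )
  }
  structure(list(n_fall_records = as.integer(n_fall_records),
                 n_adl_records = as.integer(n_adl_records),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 difficulty = difficulty, noise_sd = noise_sd,
                 templates = templates, template_mix = template_mix,
                 error_spike_frac = error_spike_frac,
                 error_lowpeak_frac = error_lowpeak_frac,
                 short_tail_frac = short_tail_frac,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Write / read a generator configuration as YAML
#'
#' Serialises the scalar parameters of a [generator_config()] (the
#' template library is reconstructed from `difficulty` and `noise_sd`).
#'
#' @param cfg A [generator_config()].
#' @param path YAML file path.
#' @return `write_generator_config`: `path` invisibly;
#'   `read_generator_config`: a [generator_config()].
#' @export
write_generator_config <- function(cfg, path) {
  keep <- c("n_fall_records", "n_adl_records", "sampling_rate_hz",
            "difficulty", "noise_sd", "error_spike_frac",
            "error_lowpeak_frac", "short_tail_frac", "seed")
  yaml::write_yaml(unclass(cfg)[keep], path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

# Half-cosine ramp from `from` to `to` over n samples (ends exactly at
# `to`; starts one step away from `from` for continuity with the
# previous sample).
ramp_to <- function(from, to, n) {
  if (n <= 0L) return(numeric(0))
  from + (to - from) * (1 - cos(pi * seq_len(n) / n)) / 2
}

draw_amp <- function(par) {
  if (length(par) == 2L) runif(1, par[1L], par[2L]) else par[1L]
}

# Synthesize the AVM magnitude profile of one template (consumes the
# current RNG stream).  Returns list(m, primary_index).
synth_magnitude <- function(template, fs) {
  m <- numeric(0)
  primary <- NA_integer_
  last <- 1
  plans <- template$phase_plan
  if (!is.null(template$pre_activity)) {
    pre <- synth_magnitude(template$pre_activity, fs)
    m <- pre$m
    last <- if (length(m)) m[length(m)] else 1
  }
  jit <- template$duration_jitter
  for (p in plans) {
    dur <- if (jit > 0) p$duration * runif(1, 1 - jit, 1 + jit) else
      p$duration
    n <- as.integer(round(dur * fs))
    if (n < 1L) next
    seg <- switch(
      p$kind,
      rest = rep(1, n),
      pre_impact_descent = ramp_to(last, draw_amp(p$depth), n),
      impact_peak = {
        A <- draw_amp(p$amp)
        n_up <- as.integer(ceiling(n / 2))
        out <- c(ramp_to(last, A, n_up), ramp_to(A, 1, n - n_up))
        primary <- length(m) + n_up
        out
      },
      periodic_motion = {
        a <- draw_amp(p$amp)
        f <- p$freq_hz * runif(1, 0.9, 1.1)
        phi <- runif(1, 0, 2 * pi)
        tt <- seq_len(n) / fs
        1 + a * (sin(2 * pi * f * tt + phi) +
                   0.3 * sin(4 * pi * f * tt + 2 * phi))
      },
      posture_change = {
        a <- draw_amp(p$amp)
        1 + a * sin(pi * seq_len(n) / n)^2
      },
      stop("unknown phase kind: ", p$kind)
    )
    m <- c(m, seg)
    last <- m[length(m)]
  }
  if (!is.null(template$secondary_peak) && !is.na(primary)) {
    sp <- template$secondary_peak
    A2 <- draw_amp(sp$amp)
    at <- primary + as.integer(round(sp$delay_s * fs))
    half <- as.integer(round(0.125 * fs))
    sel <- max(1L, at - half):min(length(m), at + half)
    pulse <- 1 + (A2 - 1) * sin(pi * seq_along(sel) / length(sel))^2
    m[sel] <- pmax(m[sel], pulse)
  }
  list(m = pmax(m, 0.02), primary_index = primary)
}

# Project a magnitude profile onto a random static sensor orientation
# and add per-axis Gaussian noise (consumes the RNG stream).
project_axes <- function(m, noise_sd) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  n <- length(m)
  eps <- if (noise_sd > 0) matrix(rnorm(3L * n, 0, noise_sd), ncol = 3L)
  else matrix(0, n, 3L)
  list(ax = u[1L] * m + eps[, 1L],
       ay = u[2L] * m + eps[, 2L],
       az = u[3L] * m + eps[, 3L])
}

generate_record_impl <- function(template, cfg, seed, record_id,
                                 subject_id) {
  fs <- cfg$sampling_rate_hz
  out <- withr::with_seed(as.integer(seed), {
    syn <- synth_magnitude(template, fs)
    axes <- project_axes(syn$m, template$noise_sd)
    list(syn = syn, axes = axes)
  })
  rec <- accel_record(record_id, out$axes$ax, out$axes$ay, out$axes$az,
                      fs, class_label = template$class_label,
                      subject_id = subject_id,
                      activity_type = template$name)
  attr(rec, "primary_index") <- out$syn$primary_index
  rec
}

#' Generate one fall record
#'
#' Synthesizes the template's AVM magnitude profile (descent below 1 g,
#' impact pulse, rest near 1 g, plus any secondary peak or prepended
#' ADL), projects it onto a random static sensor orientation and adds
#' per-axis Gaussian noise.  Deterministic given `seed`.
#'
#' @param template A fall [activity_template()].
#' @param cfg A [generator_config()] (supplies sampling rate).
#' @param seed Integer seed for this record.
#' @param record_id,subject_id Identifiers stored in the record.
#' @return An [accel_record()] with attribute `primary_index` marking
#'   the primary impact sample.
#' @export
generate_fall_record <- function(template, cfg, seed, record_id = "F0001",
                                 subject_id = "S01") {
  stopifnot(inherits(template, "activity_template"),
            template$class_label == "fall")
  rec <- generate_record_impl(template, cfg, seed, record_id, subject_id)
  pk <- attr(rec, "primary_index")
  need <- as.integer(round(4 * rec$fs_hz))
  if (pk - need < 1L || pk + need > rec$N) {
    stop("generate_fall_record: template '", template$name,
         "' leaves less than 4 s around the primary impact")
  }
  rec
}

#' Generate one ADL record
#'
#' @param template An ADL [activity_template()].
#' @inheritParams generate_fall_record
#' @return An [accel_record()].
#' @export
generate_adl_record <- function(template, cfg, seed, record_id = "A0001",
                                subject_id = "S01") {
  stopifnot(inherits(template, "activity_template"),
            template$class_label == "adl")
  generate_record_impl(template, cfg, seed, record_id, subject_id)
}

# --- deterministic sensor-error injections (no RNG) -------------------

inject_spike <- function(rec) {
  i <- max(2L, as.integer(round(0.15 * rec$N)))
  v <- sqrt(rec$ax[i]^2 + rec$ay[i]^2 + rec$az[i]^2)
  if (v > 0) {
    s <- 35 / v
    rec$ax[i] <- rec$ax[i] * s
    rec$ay[i] <- rec$ay[i] * s
    rec$az[i] <- rec$az[i] * s
  } else {
    rec$ax[i] <- 35
  }
  rec
}

# Compress the AVM trace around the 1 g rest level so the maximal peak
# lands at 1.05 g (< 1.1 g strictly), keeping rest samples near 1 g.
inject_lowpeak <- function(rec) {
  v <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
  vmax <- max(v)
  if (vmax <= 1.05) return(rec)
  f <- (1 + (v - 1) * (0.05 / (vmax - 1))) / v
  rec$ax <- rec$ax * f
  rec$ay <- rec$ay * f
  rec$az <- rec$az * f
  rec
}

trim_short_tail <- function(rec) {
  pk <- attr(rec, "primary_index")
  keep <- min(rec$N, pk + as.integer(round(2 * rec$fs_hz)))
  rec$ax <- rec$ax[1:keep]; rec$ay <- rec$ay[1:keep]
  rec$az <- rec$az[1:keep]; rec$N <- keep
  rec
}

#' Generate a labeled synthetic dataset
#'
#' Draws templates per record according to the configured mix,
#' generates every record from a per-record seed derived from
#' `cfg$seed`, applies the configured sensor-error injections to a
#' deterministically chosen set of records, and assembles a manifest.
#' Identical configurations (including the seed) produce identical
#' datasets.
#'
#' @param cfg A [generator_config()].
#' @return An `accel_dataset`: list with `records` (named list of
#'   [accel_record()]s), `manifest` (data frame `record_id, subject_id,
#'   activity_type, class, fs_hz, path, error_type, short_tail`;
#'   `error_type` is the ground-truth flag of the QC-violating
#'   injections) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n_f <- cfg$n_fall_records
  n_a <- cfg$n_adl_records
  n <- n_f + n_a
  if (n == 0L) stop("generate_dataset: no records requested")
  tpl <- cfg$templates
  cls <- vapply(tpl, `[[`, character(1), "class_label")
  fall_names <- names(tpl)[cls == "fall"]
  adl_names <- names(tpl)[cls == "adl"]
  mixw <- cfg$template_mix
  plan <- withr::with_seed(cfg$seed, {
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
    tpl_assign <- c(
      if (n_f) sample(fall_names, n_f, replace = TRUE,
                      prob = mixw$fall[fall_names]),
      if (n_a) sample(adl_names, n_a, replace = TRUE,
                      prob = mixw$adl[adl_names])
    )
    spike <- sort(sample.int(n, round(cfg$error_spike_frac * n)))
    fall_pool <- setdiff(seq_len(n_f), spike)
    lowpeak <- sort(sample(fall_pool,
                           min(round(cfg$error_lowpeak_frac * n_f),
                               length(fall_pool))))
    tail_pool <- setdiff(fall_pool, lowpeak)
    short_tail <- sort(sample(tail_pool,
                              min(round(cfg$short_tail_frac * n_f),
                                  length(tail_pool))))
    list(rec_seeds = rec_seeds, tpl_assign = tpl_assign, spike = spike,
         lowpeak = lowpeak, short_tail = short_tail)
  })
  classes <- rep(c("fall", "adl"), c(n_f, n_a))
  ids <- sprintf("R%04d", seq_len(n))
  subjects <- sprintf("S%02d", (seq_len(n) - 1L) %% 10L + 1L)
  records <- vector("list", n)
  error_type <- rep("none", n)
  error_type[plan$spike] <- "avm_over_30g"
  error_type[plan$lowpeak] <- "fall_peak_under_1p1g"
  for (i in seq_len(n)) {
    t_i <- tpl[[plan$tpl_assign[i]]]
    rec <- if (classes[i] == "fall") {
      generate_fall_record(t_i, cfg, plan$rec_seeds[i], ids[i], subjects[i])
    } else {
      generate_adl_record(t_i, cfg, plan$rec_seeds[i], ids[i], subjects[i])
    }
    if (i %in% plan$short_tail) rec <- trim_short_tail(rec)
    if (error_type[i] == "avm_over_30g") rec <- inject_spike(rec)
    if (error_type[i] == "fall_peak_under_1p1g") rec <- inject_lowpeak(rec)
    records[[i]] <- rec
  }
  names(records) <- ids
  manifest <- data.frame(
    record_id = ids, subject_id = subjects,
    activity_type = plan$tpl_assign, class = classes,
    fs_hz = cfg$sampling_rate_hz,
    path = file.path("records", paste0(ids, ".csv")),
    error_type = error_type,
    short_tail = seq_len(n) %in% plan$short_tail,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, manifest = manifest, config = cfg),
            class = "accel_dataset")
}
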