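#' Phase descriptors for activity templates
#'
#' Activity templates are ordered plans of signal phases on the AVM
#' magnitude scale (g units; 1 g is the rest level).  Amplitude
#' parameters given as a length-2 vector are uniform draw ranges,
#' sampled once per generated record.
#'
#' * `phase_rest(duration)` -- static posture, magnitude 1 g.
#' * `phase_descent(duration, depth)` -- pre-impact descent: the
#'   magnitude ramps from 1 g down to `depth` (partial free fall; a
#'   complete free fall would read 0 g).
#' * `phase_impact(duration, amp)` -- impact peak: a half-cosine pulse
#'   rising to `amp` and returning to 1 g.  The peak sample is the
#'   phase's primary impact.
#' * `phase_periodic(duration, amp, freq_hz)` -- sustained periodic
#'   motion (walking-like): a two-harmonic oscillation around 1 g with
#'   fundamental near `freq_hz` (10% frequency jitter and random phase
#'   per record).
#' * `phase_posture(duration, amp)` -- a slow posture-change bump of
#'   height `amp` above 1 g.
#'
#' @param duration Phase duration in seconds (> 0).
#' @param depth,amp Amplitude parameter (g): a fixed value or a
#'   `c(lo, hi)` uniform draw range.
#' @param freq_hz Fundamental frequency of periodic motion (Hz).
#' @return A phase descriptor list.
#' @name phases
NULL

phase_descriptor <- function(kind, duration, ...) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  extra <- list(...)
  for (nm in names(extra)) {
    if (is.numeric(extra[[nm]]) && any(extra[[nm]] < 0)) {
      stop("phase ", kind, ": parameter '", nm, "' must be >= 0")
    }
  }
  c(list(kind = kind, duration = duration), extra)
}

#' @rdname phases
#' @export
phase_rest <- function(duration) phase_descriptor("rest", duration)

#' @rdname phases
#' @export
phase_descent <- function(duration = 0.4, depth = c(0.10, 0.40)) {
  phase_descriptor("pre_impact_descent", duration, depth = depth)
}

#' @rdname phases
#' @export
phase_impact <- function(duration = 0.3, amp = c(2, 8)) {
  phase_descriptor("impact_peak", duration, amp = amp)
}

#' @rdname phases
#' @export
phase_periodic <- function(duration, amp = c(0.25, 0.45), freq_hz = 1.8) {
  phase_descriptor("periodic_motion", duration, amp = amp,
                   freq_hz = freq_hz)
}

#' @rdname phases
#' @export
phase_posture <- function(duration, amp = c(0.05, 0.15)) {
  phase_descriptor("posture_change", duration, amp = amp)
}

#' Define an activity template
#'
#' @param name Template identifier (used as the record's activity type).
#' @param class_label `"fall"` or `"adl"`.
#' @param phase_plan Ordered list of phase descriptors (see [phases]).
#'   A fall template must contain exactly one `phase_impact()` (its
#'   primary impact); an ADL template at most one.
#' @param noise_sd Per-axis additive Gaussian noise, in g (default
#'   0.03: small relative to the 1 g rest level).
#' @param secondary_peak Optional `list(delay_s =, amp =)` describing a
#'   second impact `delay_s` seconds after the primary one (a broken
#'   fall, e.g. to the knees first and then to the ground).
#' @param pre_activity Optional `activity_template` whose phases are
#'   prepended before this template's own plan (a fall preceded by an
#'   ADL, e.g. a fall while sitting down).
#' @param duration_jitter Fractional jitter applied to every phase
#'   duration per generated record (0 = exact durations, the default;
#'   the built-in library uses 0.1 so that no class carries a fixed
#'   timing fingerprint).
#' @return An `activity_template` list.
#' @export
activity_template <- function(name, class_label = c("fall", "adl"),
                              phase_plan, noise_sd = 0.03,
                              secondary_peak = NULL, pre_activity = NULL,
                              duration_jitter = 0) {
  class_label <- match.arg(class_label)
  stopifnot(is.list(phase_plan), length(phase_plan) > 0,
            is.numeric(noise_sd), noise_sd >= 0,
            duration_jitter >= 0, duration_jitter < 1)
  kinds <- vapply(phase_plan, `[[`, character(1), "kind")
  n_impact <- sum(kinds == "impact_peak")
  if (class_label == "fall" && n_impact != 1L) {
    stop("fall template '", name, "' must have exactly one impact_peak ",
         "phase, found ", n_impact)
  }
  if (class_label == "adl" && n_impact > 1L) {
    stop("adl template '", name, "' has more than one impact_peak phase")
  }
  if (!is.null(secondary_peak)) {
    stopifnot(is.list(secondary_peak), secondary_peak$delay_s > 0,
              all(secondary_peak$amp >= 0))
  }
  if (!is.null(pre_activity)) {
    stopifnot(inherits(pre_activity, "activity_template"))
  }
  structure(list(name = name, class_label = class_label,
                 phase_plan = phase_plan, noise_sd = noise_sd,
                 secondary_peak = secondary_peak,
                 pre_activity = pre_activity,
                 duration_jitter = duration_jitter),
            class = "activity_template")
}

#' @export
print.activity_template <- function(x, ...) {
  cat(sprintf("<activity_template %s> %s, %d phases, %.1f s\n",
              x$name, x$class_label, length(x$phase_plan),
              sum(vapply(x$phase_plan, `[[`, numeric(1), "duration"))))
  invisible(x)
}

#' Built-in fall and ADL templates
#'
#' The default library of activity morphologies.  Falls follow the
#' three-phase model (pre-impact descent below 1 g, impact spike, rest
#' near 1 g) and always place the primary impact at least 4.5 s from
#' both record ends; ADL templates cover low-peak slow movements,
#' impact-like activities (sitting down hard, jumping) and sustained
#' walking.
#'
#' The `difficulty` knob (0..1) controls how much class signal the
#' impact itself carries.  At 0, fall pre-impact dips (down to
#' 0.10--0.40 g) are disjoint from the shallow unloading dips of
#' impact-like ADL and fall impact amplitudes (2--8 g) extend far above
#' the ADL range (1.5--3 g), so fall and ADL feature distributions are
#' linearly separable.  As difficulty grows the dip depths converge and
#' the fall amplitude range shrinks toward the ADL one, while the pre-
#' and post-impact structure (walking before some falls; rest after a
#' fall versus settling motion after an impact-like ADL) is unchanged:
#' at difficulty 1 most of the class signal lives in the pre- and
#' post-impact intervals rather than in the impact window.  Falls
#' preceded by an ADL always place the fall impact above the prepended
#' ADL's peak, as the largest-peak labeling rule presumes.
#'
#' @param difficulty Class-overlap knob in \[0, 1\] (default 0.2).
#' @param noise_sd Per-axis Gaussian noise sd in g (default 0.03).
#' @return Named list of [activity_template()]s.
#' @export
default_templates <- function(difficulty = 0.2, noise_sd = 0.03) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  d <- difficulty
  fall_depth <- c(0.10, 0.40) + 0.45 * d
  sit_depth <- c(0.75, 0.95) - 0.20 * d
  jump_depth <- c(0.60, 0.85) - 0.25 * d
  fall_amp <- c(2, 8 - 4.5 * d)
  settle_amp <- c(0.10, 0.25)
  sit_tpl <- activity_template(
    "adl_sit_down", "adl",
    list(phase_rest(4.4),
         phase_descent(0.35, sit_depth),
         phase_impact(0.3, c(1.5, 3)),
         phase_periodic(1.5, settle_amp, freq_hz = 1.2),
         phase_rest(4.1)),
    noise_sd = noise_sd, duration_jitter = 0.1
  )
  pre_sit <- activity_template(
    "adl_sit_down", "adl",
    list(phase_rest(4.2),
         phase_descent(0.35, sit_depth),
         phase_impact(0.3, c(1.5, 3)),
         phase_periodic(1.2, settle_amp, freq_hz = 1.2),
         phase_rest(2.9)),
    noise_sd = noise_sd, duration_jitter = 0.1
  )
  list(
    fall_flat = activity_template(
      "fall_flat", "fall",
      list(phase_rest(4.4),
           phase_descent(0.35, fall_depth),
           phase_impact(0.3, fall_amp),
           phase_rest(5.4)),
      noise_sd = noise_sd, duration_jitter = 0.1
    ),
    fall_from_walk = activity_template(
      "fall_from_walk", "fall",
      list(phase_periodic(4.4, c(0.25, 0.45), freq_hz = 1.8),
           phase_descent(0.35, fall_depth),
           phase_impact(0.3, fall_amp),
           phase_rest(5.4)),
      noise_sd = noise_sd, duration_jitter = 0.1
    ),
    fall_broken = activity_template(
      "fall_broken", "fall",
      list(phase_rest(4.4),
           phase_descent(0.35, fall_depth),
           phase_impact(0.3, c(3, max(3.5, fall_amp[2]))),
           phase_rest(5.4)),
      noise_sd = noise_sd, duration_jitter = 0.1,
      secondary_peak = list(delay_s = 0.8, amp = c(2.2, max(3.2, 6 - 2.5 * d)))
    ),
    fall_after_adl = activity_template(
      "fall_after_adl", "fall",
      list(phase_rest(1.3),
           phase_descent(0.35, fall_depth),
           phase_impact(0.3, c(3.2, max(3.6, fall_amp[2]))),
           phase_rest(5.4)),
      noise_sd = noise_sd, duration_jitter = 0.1,
      pre_activity = pre_sit
    ),
    adl_slow = activity_template(
      "adl_slow", "adl",
      list(phase_rest(2),
           phase_posture(2.5, c(0.05, 0.15)),
           phase_rest(2.5),
           phase_posture(1.5, c(0.05, 0.12)),
           phase_rest(2)),
      noise_sd = noise_sd, duration_jitter = 0.1
    ),
    adl_sit_down = sit_tpl,
    adl_jump = activity_template(
      "adl_jump", "adl",
      list(phase_periodic(4.4, c(0.20, 0.35), freq_hz = 1.8),
           phase_descent(0.35, jump_depth),
           phase_impact(0.3, c(1.8, 3)),
           phase_periodic(1.5, c(0.20, 0.35), freq_hz = 1.8),
           phase_rest(4.1)),
      noise_sd = noise_sd, duration_jitter = 0.1
    ),
    adl_walk = activity_template(
      "adl_walk", "adl",
      list(phase_periodic(10.5, c(0.45, 0.60), freq_hz = 1.8)),
      noise_sd = noise_sd, duration_jitter = 0.1
    )
  )
}
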