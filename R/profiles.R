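#' Subject breathing profile
#'
#' A `subject_profile` describes how one simulated subject breathes at rest and
#' how they adapt to exercise. Subjects differ in their adaptation strategy:
#' some meet an increased respiratory load mostly by breathing faster
#' (`"rate_dominant"`), others mostly by breathing deeper
#' (`"amplitude_dominant"`), and many do a bit of both (`"mixed"`). Strategy
#' defaults encode that heterogeneity: a rate-dominant subject multiplies rate
#' by 1.7 and amplitude by 1.35 during exercise, an amplitude-dominant subject
#' leaves rate unchanged and doubles amplitude, and a mixed subject does 1.4 /
#' 1.6.
#'
#' @param subject_id Character label for the subject.
#' @param strategy One of `"rate_dominant"`, `"amplitude_dominant"`, `"mixed"`:
#'   how the subject increases ventilation under load.
#' @param rest_rate Resting breathing rate, breaths per minute (6-40).
#' @param rest_amplitude Resting inspiratory depth, arbitrary pressure units.
#' @param exercise_rate_multiplier,exercise_amplitude_multiplier Factors (>= 1)
#'   applied to rate and amplitude during exercise. Defaults depend on
#'   `strategy`.
#' @param breath_length_cv Coefficient of variation of breath-cycle lengths,
#'   in `[0, 1)`.
#' @param amplitude_cv Coefficient of variation of inspiratory depths,
#'   in `[0, 1)`.
#' @param noise_sd Standard deviation of additive sensor noise, pressure units.
#' @param baseline_drift_amplitude Amplitude of a slow sinusoidal baseline
#'   drift, pressure units.
#' @param seed Integer seed; all randomness in recordings generated from this
#'   profile derives from it.
#'
#' @return A `subject_profile` object (a named list).
#' @examples
#' p <- subject_profile("s1", strategy = "rate_dominant", seed = 1)
#' p$exercise_rate_multiplier
#' @export
subject_profile <- function(subject_id,
                            strategy = c("mixed", "rate_dominant", "amplitude_dominant"),
                            rest_rate = 15,
                            rest_amplitude = 1,
                            exercise_rate_multiplier = NULL,
                            exercise_amplitude_multiplier = NULL,
                            breath_length_cv = 0.12,
                            amplitude_cv = 0.15,
                            noise_sd = 0.12,
                            baseline_drift_amplitude = 0.1,
                            seed = 1L) {
  strategy <- match.arg(strategy)
  defaults <- switch(strategy,
    rate_dominant      = c(rate = 1.7, amp = 1.35),
    amplitude_dominant = c(rate = 1.0, amp = 2.0),
    mixed              = c(rate = 1.4, amp = 1.6)
  )
  if (is.null(exercise_rate_multiplier)) exercise_rate_multiplier <- defaults[["rate"]]
  if (is.null(exercise_amplitude_multiplier)) exercise_amplitude_multiplier <- defaults[["amp"]]

  p <- structure(
    list(
      subject_id = as.character(subject_id),
      strategy = strategy,
      rest_rate = rest_rate,
      rest_amplitude = rest_amplitude,
      exercise_rate_multiplier = exercise_rate_multiplier,
      exercise_amplitude_multiplier = exercise_amplitude_multiplier,
      breath_length_cv = breath_length_cv,
      amplitude_cv = amplitude_cv,
      noise_sd = noise_sd,
      baseline_drift_amplitude = baseline_drift_amplitude,
      seed = as.integer(seed)
    ),
    class = "subject_profile"
  )
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "subject_profile"))
  chk <- function(ok, msg) if (!ok) stop("invalid subject_profile: ", msg, call. = FALSE)
  chk(is.character(p$subject_id) && nzchar(p$subject_id), "subject_id must be non-empty")
  chk(p$rest_rate >= 6 && p$rest_rate <= 40,
      "rest_rate must lie in the physiological band 6-40 breaths/min")
  chk(p$rest_amplitude > 0, "rest_amplitude must be positive")
  chk(p$exercise_rate_multiplier >= 1, "exercise_rate_multiplier must be >= 1")
  chk(p$exercise_amplitude_multiplier >= 1, "exercise_amplitude_multiplier must be >= 1")
  # exercised rate must stay under the 2 Hz (120 breaths/min) physiological ceiling
  chk(p$rest_rate * p$exercise_rate_multiplier < 120,
      "exercise rate would exceed the 2 Hz physiological ceiling")
  if (p$strategy == "rate_dominant") {
    chk(p$exercise_rate_multiplier > p$exercise_amplitude_multiplier,
        "rate_dominant requires rate multiplier > amplitude multiplier")
  }
  if (p$strategy == "amplitude_dominant") {
    chk(p$exercise_amplitude_multiplier > p$exercise_rate_multiplier,
        "amplitude_dominant requires amplitude multiplier > rate multiplier")
  }
  chk(p$breath_length_cv >= 0 && p$breath_length_cv < 1, "breath_length_cv must be in [0, 1)")
  chk(p$amplitude_cv >= 0 && p$amplitude_cv < 1, "amplitude_cv must be in [0, 1)")
  chk(p$noise_sd >= 0, "noise_sd must be >= 0")
  chk(p$baseline_drift_amplitude >= 0, "baseline_drift_amplitude must be >= 0")
  chk(is.finite(p$seed), "seed must be a finite integer")
  invisible(p)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> %s  [%s]\n  rest: %.1f breaths/min, amplitude %.2f\n  exercise: rate x%.2f, amplitude x%.2f\n  cv: length %.2f, depth %.2f; noise sd %.2f; seed %d\n",
    x$subject_id, x$strategy, x$rest_rate, x$rest_amplitude,
    x$exercise_rate_multiplier, x$exercise_amplitude_multiplier,
    x$breath_length_cv, x$amplitude_cv, x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Build a cohort of subject profiles with mixed adaptation strategies
#'
#' @param n Number of subjects.
#' @param seed Integer seed; per-subject seeds and between-subject variation in
#'   resting rate/amplitude are derived from it.
#' @param strategies Strategies to cycle through across subjects.
#' @param prefix Prefix for subject ids.
#' @param ... Further arguments passed to [subject_profile()].
#' @return A list of `subject_profile` objects.
#' @export
cohort_profiles <- function(n, seed = 1L,
                            strategies = c("rate_dominant", "amplitude_dominant"),
                            prefix = "S", ...) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    rates <- stats::runif(n, 12, 18)
    amps <- stats::runif(n, 0.8, 1.2)
    seeds <- sample.int(.Machine$integer.max, n)
  })
  purrr::map(seq_len(n), function(i) {
    subject_profile(
      subject_id = sprintf("%s%02d", prefix, i),
      strategy = strategies[[(i - 1L) %% length(strategies) + 1L]],
      rest_rate = rates[i],
      rest_amplitude = amps[i],
      seed = seeds[i],
      ...
    )
  })
}
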