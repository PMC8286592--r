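#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Breath-cycle shape fractions. A cycle runs baseline -> inspiratory trough ->
# shallow expiratory hump -> end-expiratory pause at baseline. Inspiration
# produces minima because the signal is nasal pressure in the oxygen circuit.
.shape <- list(insp = 0.35, exp = 0.25, hump = 0.15)

# Minimum cycle length (s): 2 Hz is the physiological ceiling on breathing rate.
.min_cycle_s <- 0.5

draw_pos <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean * cv^2 / 1)
}

# Draw breath cycles filling `duration` seconds for one schedule segment.
# `rate_mult`/`amp_mult` may be functions of time-within-segment (transition).
draw_cycles_segment <- function(profile, duration, t0, regime, rate_mult, amp_mult) {
  onsets <- numeric(0); lengths <- numeric(0); depths <- numeric(0)
  t <- 0
  mean_rest_len <- 60 / profile$rest_rate
  while (TRUE) {
    rm <- if (is.function(rate_mult)) rate_mult(t) else rate_mult
    am <- if (is.function(amp_mult)) amp_mult(t) else amp_mult
    len <- max(.min_cycle_s, draw_pos(1, mean_rest_len / rm, profile$breath_length_cv))
    if (t + len > duration) break
    dep <- draw_pos(1, profile$rest_amplitude * am, profile$amplitude_cv)
    onsets <- c(onsets, t0 + t); lengths <- c(lengths, len); depths <- c(depths, dep)
    t <- t + len
  }
  tibble(
    t_onset = onsets, length_s = lengths, depth = depths,
    t_min = onsets + .shape$insp / 2 * lengths, regime = rep(regime, length(onsets))
  )
}

regime_multipliers <- function(profile, regime, transition_tau = 120) {
  switch(regime,
    reference = ,
    artifact  = list(rate = 1, amp = 1),
    exercise  = list(rate = profile$exercise_rate_multiplier,
                     amp = profile$exercise_amplitude_multiplier),
    transition = list(
      rate = function(t) 1 + (profile$exercise_rate_multiplier - 1) * exp(-t / transition_tau),
      amp  = function(t) 1 + (profile$exercise_amplitude_multiplier - 1) * exp(-t / transition_tau)
    ),
    absent = NULL,
    stop("unknown regime: ", regime)
  )
}

draw_cycles <- function(profile, schedule, transition_tau = 120) {
  t0 <- c(0, cumsum(schedule$duration_s))[seq_len(nrow(schedule))]
  purrr::map2_dfr(seq_len(nrow(schedule)), t0, function(i, start) {
    regime <- schedule$regime[[i]]
    m <- regime_multipliers(profile, regime, transition_tau)
    if (is.null(m)) return(tibble())
    draw_cycles_segment(profile, schedule$duration_s[[i]], start, regime, m$rate, m$amp)
  })
}

# Evaluate the breathing waveform (no noise/drift) at sample times `tt`.
render_cycles <- function(cycles, tt) {
  p <- numeric(length(tt))
  if (nrow(cycles) == 0) return(p)
  idx <- findInterval(tt, cycles$t_onset)
  inside <- idx >= 1
  s <- (tt[inside] - cycles$t_onset[idx[inside]]) / cycles$length_s[idx[inside]]
  d <- cycles$depth[idx[inside]]
  v <- numeric(length(s))
  ii <- s < .shape$insp
  v[ii] <- -d[ii] * sin(pi * s[ii] / .shape$insp)
  ee <- !ii & s < .shape$insp + .shape$exp
  v[ee] <- .shape$hump * d[ee] * sin(pi * (s[ee] - .shape$insp) / .shape$exp)
  v[s >= 1] <- 0  # time past a truncated final cycle: end-expiratory pause
  p[inside] <- v
  p
}

# Artifact events: short perturbations superimposed on reference breathing.
# mult scales the breathing component (mouth breathing / drinking attenuate the
# nasal signal); add injects high-frequency, high-variance pressure (cough,
# speech). Windows containing them remain labelled reference.
apply_events <- function(breath, tt, events, profile) {
  mult <- rep(1, length(tt)); add <- numeric(length(tt))
  if (is.null(events) || nrow(events) == 0) return(list(mult = mult, add = add))
  a <- profile$rest_amplitude
  for (i in seq_len(nrow(events))) {
    span <- tt >= events$t_start[i] & tt < events$t_start[i] + events$duration_s[i]
    n <- sum(span)
    if (n == 0) next
    tloc <- tt[span] - events$t_start[i]
    switch(events$type[i],
      cough = {
        add[span] <- add[span] +
          2.5 * a * sin(2 * pi * 3.5 * tloc) * (sin(2 * pi * tloc / events$duration_s[i])^2) +
          stats::rnorm(n, 0, 0.8 * a)
      },
      speech = {
        add[span] <- add[span] +
          0.8 * a * sin(2 * pi * 4 * tloc) * abs(sin(2 * pi * 0.6 * tloc)) +
          stats::rnorm(n, 0, 0.3 * a)
        mult[span] <- 0.6
      },
      drink = {
        mult[span] <- 0.3
        add[span] <- add[span] + stats::rnorm(n, 0, 0.2 * a)
      },
      mouth_breathing = {
        mult[span] <- 0.25
      },
      stop("unknown artifact type: ", events$type[i])
    )
  }
  list(mult = mult, add = add)
}

render_recording <- function(profile, schedule, events = NULL, sampling_rate = 10,
                             transition_tau = 120) {
  total <- sum(schedule$duration_s)
  n <- round(total * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate
  cycles <- draw_cycles(profile, schedule, transition_tau)
  breath <- render_cycles(cycles, tt)
  ev <- apply_events(breath, tt, events, profile)
  # drift follows the subject; absent spans are sensor noise only
  present <- breath_presence_mask(schedule, tt)
  drift <- profile$baseline_drift_amplitude * sin(2 * pi * tt / 60) * present
  noise <- stats::rnorm(n, 0, profile$noise_sd)
  pressure <- breath * ev$mult + ev$add + drift + noise
  list(signal = tibble(time_s = tt, pressure = pressure), cycles = cycles)
}

breath_presence_mask <- function(schedule, tt) {
  edges <- c(0, cumsum(schedule$duration_s))
  idx <- findInterval(tt, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > nrow(schedule)] <- nrow(schedule)
  as.numeric(schedule$regime[idx] != "absent")
}

new_recording <- function(profile, schedule, rendered, sampling_rate, kind,
                          events = NULL, schedule_true = NULL) {
  structure(
    list(
      signal = rendered$signal,
      sampling_rate = sampling_rate,
      schedule = schedule,
      schedule_true = if (is.null(schedule_true)) schedule else schedule_true,
      cycles = rendered$cycles,
      events = if (is.null(events)) tibble(type = character(), t_start = numeric(),
                                           duration_s = numeric()) else events,
      profile = profile,
      kind = kind
    ),
    class = "resp_recording"
  )
}

#' @export
print.resp_recording <- function(x, ...) {
  cat(sprintf(
    "<resp_recording> %s (%s): %.1f min at %g Hz, %d samples, %d breath cycles\n",
    x$profile$subject_id, x$kind, nrow(x$signal) / x$sampling_rate / 60,
    x$sampling_rate, nrow(x$signal), nrow(x$cycles)
  ))
  print(dplyr::count(x$schedule, .data$regime, wt = .data$duration_s, name = "seconds"))
  invisible(x)
}

#' Simulate the 30-minute healthy-subject protocol recording
#'
#' Generates a 30-minute nasal-pressure recording at 10 Hz following the
#' scripted healthy protocol: 23 windows (17.25 min) of resting reference
#' breathing during which the subject drinks, coughs, speaks and
#' mouth-breathes at set times, 4 windows (3 min) of exercise, and 13 windows
#' (9.75 min) of gradual recovery back to rest. Cutting the recording into
#' non-overlapping 45-s windows therefore yields exactly 40 windows labelled
#' 23 reference / 4 exercise / 13 transition. Artifact periods stay inside the
#' reference class: they are part of everyday "normality".
#'
#' The recording carries a ground-truth side channel (`$cycles`): the true
#' onset, trough time, length and inspiratory depth of every simulated breath,
#' so breath detection can be scored against truth.
#'
#' @param profile A [subject_profile()].
#' @param sampling_rate Samples per second (default 10).
#' @param transition_tau Time constant (s) of the exponential recovery of rate
#'   and amplitude during the transition phase.
#' @return A `resp_recording` object.
#' @examples
#' rec <- make_healthy_protocol(subject_profile("s1", seed = 42))
#' nrow(rec$signal)  # 18000 samples = 30 min x 10 Hz
#' @export
make_healthy_protocol <- function(profile, sampling_rate = 10, transition_tau = 120) {
  validate_profile(profile)
  schedule <- tibble(
    regime = c("reference", "exercise", "transition"),
    duration_s = c(23 * 45, 4 * 45, 13 * 45)
  )
  # artifact script: one event per designated reference window, fixed offsets
  events <- tibble(
    type = c("drink", "cough", "speech", "mouth_breathing"),
    t_start = c(6, 10, 14, 18) * 45 + 10,
    duration_s = c(12, 8, 15, 15)
  )
  rendered <- withr::with_seed(profile$seed,
    render_recording(profile, schedule, events, sampling_rate, transition_tau))
  new_recording(profile, schedule, rendered, sampling_rate, "healthy_protocol",
                events = events)
}

#' Simulate a long observational COPD-like recording
#'
#' Emulates an 8-hour observational recording from an oxygen-therapy patient:
#' long stretches of resting reference breathing, gaps where the subject is
#' absent (cannula off, sensor noise only), and a configurable number of
#' exercise periods (e.g. a morning bike session and afternoon gymnastics) at
#' randomized positions. Because such exercise times are only approximately
#' scheduled, an optional label-noise mechanism blurs the exercise-block edges
#' by up to `label_noise_windows` 45-s windows in the *reported* schedule
#' (`$schedule`), while the true schedule is kept in `$schedule_true`.
#'
#' @param profile A [subject_profile()].
#' @param duration_hours Recording length in hours.
#' @param n_exercise_blocks Number of exercise periods.
#' @param exercise_block_minutes Length of each exercise period, minutes.
#' @param absent_fraction Approximate fraction of the recording with the
#'   subject absent.
#' @param label_noise_windows Maximum edge shift (in 45-s windows) applied to
#'   exercise-block boundaries in the reported schedule; 0 disables label
#'   noise.
#' @param sampling_rate Samples per second.
#' @return A `resp_recording`.
#' @export
make_copd_like <- function(profile, duration_hours = 8, n_exercise_blocks = 2,
                           exercise_block_minutes = 12, absent_fraction = 0.12,
                           label_noise_windows = 2, sampling_rate = 10) {
  validate_profile(profile)
  stopifnot(duration_hours > 0, n_exercise_blocks >= 0)
  n_win <- floor(duration_hours * 3600 / 45)
  block_len <- max(1L, round(exercise_block_minutes * 60 / 45))
  if (n_exercise_blocks * block_len > n_win) {
    stop("exercise blocks (", n_exercise_blocks, " x ", block_len,
         " windows) do not fit in ", n_win, " windows", call. = FALSE)
  }

  out <- withr::with_seed(profile$seed, {
    regime <- rep("reference", n_win)
    ex_edges <- integer(0)
    if (n_exercise_blocks > 0) {
      # one block per equal span of the day (morning bike, afternoon gym, ...)
      span <- floor(n_win / n_exercise_blocks)
      for (b in seq_len(n_exercise_blocks)) {
        lo <- (b - 1L) * span + 1L
        hi <- min(b * span, n_win) - block_len
        start <- if (hi <= lo) lo else sample(lo:hi, 1)
        regime[start:(start + block_len - 1L)] <- "exercise"
        ex_edges <- c(ex_edges, start, start + block_len)
      }
    }
    # absent gaps (3-10 min), avoiding exercise blocks
    target_absent <- round(absent_fraction * n_win)
    got <- 0L; tries <- 0L
    while (got < target_absent && tries < 200L) {
      tries <- tries + 1L
      len <- sample(4:13, 1)
      start <- sample.int(n_win - len, 1)
      span_idx <- start:(start + len - 1L)
      if (all(regime[span_idx] == "reference")) {
        regime[span_idx] <- "absent"
        got <- got + len
      }
    }
    reported <- regime
    if (label_noise_windows > 0 && n_exercise_blocks > 0) {
      reported <- blur_exercise_edges(regime, label_noise_windows)
    }
    list(regime = regime, reported = reported)
  })

  schedule_true <- rle_schedule(out$regime)
  schedule_rep <- rle_schedule(out$reported)
  rendered <- withr::with_seed(profile$seed + 1L,
    render_recording(profile, schedule_true, NULL, sampling_rate))
  new_recording(profile, schedule_rep, rendered, sampling_rate, "copd_like",
                schedule_true = schedule_true)
}

rle_schedule <- function(regime_per_window, window_s = 45) {
  r <- rle(regime_per_window)
  tibble(regime = r$values, duration_s = r$lengths * window_s)
}

blur_exercise_edges <- function(regime, max_shift) {
  n <- length(regime)
  is_ex <- regime == "exercise"
  r <- rle(is_ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- regime
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    ds <- sample(-max_shift:max_shift, 1); de <- sample(-max_shift:max_shift, 1)
    ns <- min(max(1L, s + ds), n); ne <- min(max(ns, e + de), n)
    out[s:e] <- ifelse(regime[s:e] == "exercise", "reference", regime[s:e])
    span <- ns:ne
    out[span] <- ifelse(out[span] == "absent", "absent", "exercise")
  }
  out
}

#' Generate a single-regime pressure waveform
#'
#' Low-level generator: a stretch of breathing under one regime, built as a
#' concatenation of breath cycles. Cycle lengths and inspiratory depths are
#' drawn from gamma distributions around the regime's means (the exercise
#' regime applies the profile's strategy multipliers); each cycle is a
#' half-sine inspiratory trough below baseline, a shallower expiratory
#' recovery, and an end-expiratory pause. White sensor noise and a slow
#' sinusoidal baseline drift are added.
#'
#' @param profile A [subject_profile()].
#' @param regime One of `"reference"`, `"exercise"`, `"transition"`,
#'   `"absent"`.
#' @param duration Seconds of signal to generate.
#' @param sampling_rate Samples per second.
#' @param seed Seed; defaults to the profile's.
#' @return Numeric pressure vector of `duration * sampling_rate` samples, with
#'   the true breath-cycle log attached as attribute `"cycles"`.
#' @examples
#' x <- synth_waveform(subject_profile("s1", noise_sd = 0, breath_length_cv = 0,
#'                                     baseline_drift_amplitude = 0, rest_rate = 20),
#'                     "reference", 45)
#' length(x)  # 450
#' @export
synth_waveform <- function(profile, regime = "reference", duration = 45,
                           sampling_rate = 10, seed = profile$seed) {
  validate_profile(profile)
  stopifnot(duration > 0)
  schedule <- tibble(regime = regime, duration_s = duration)
  rendered <- withr::with_seed(seed,
    render_recording(profile, schedule, NULL, sampling_rate))
  structure(rendered$signal$pressure, cycles = rendered$cycles)
}

#' Simulate a full study cohort
#'
#' Builds the default study cohort: healthy subjects each recorded under the
#' scripted 30-minute protocol, plus patients recorded observationally over
#' several hours with approximate exercise labels. Strategies alternate
#' between rate-dominant and amplitude-dominant across subjects.
#'
#' @param n_healthy,n_copd Cohort sizes (study defaults: 20 and 8).
#' @param seed Integer master seed.
#' @param copd_hours Duration of each observational recording, hours.
#' @param ... Passed to [cohort_profiles()] (e.g. `noise_sd`).
#' @return A tibble with one row per subject: `subject`, `cohort`
#'   (`"healthy"`/`"copd"`), `strategy`, and the `recording` in a list-column.
#' @export
simulate_cohort <- function(n_healthy = 20, n_copd = 8, seed = 1L,
                            copd_hours = 8, ...) {
  hp <- if (n_healthy > 0) cohort_profiles(n_healthy, seed = seed, prefix = "H", ...) else list()
  cp <- if (n_copd > 0) cohort_profiles(n_copd, seed = seed + 1L, prefix = "P", ...) else list()
  rows_h <- purrr::map(hp, function(p) {
    tibble(subject = p$subject_id, cohort = "healthy", strategy = p$strategy,
           recording = list(make_healthy_protocol(p)))
  })
  rows_c <- purrr::map(cp, function(p) {
    tibble(subject = p$subject_id, cohort = "copd", strategy = p$strategy,
           recording = list(make_copd_like(p, duration_hours = copd_hours)))
  })
  dplyr::bind_rows(!!!rows_h, !!!rows_c)
}
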