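test_that("healthy protocol has the fixed recording and label structure", {
  p <- subject_profile("h1", strategy = "rate_dominant", seed = 101)
  rec <- make_healthy_protocol(p)
  expect_equal(nrow(rec$signal), 18000)  # 30 min x 60 s x 10 Hz
  w <- window_recording(rec)
  expect_equal(nrow(w), 40)
  counts <- table(w$label)
  expect_equal(unname(counts[c("reference", "exercise", "transition")]),
               c(23L, 4L, 13L), ignore_attr = TRUE)
})

test_that("label structure holds for every strategy and seed", {
  for (seed in c(2, 33, 444)) {
    for (strat in c("rate_dominant", "amplitude_dominant", "mixed")) {
      p <- subject_profile("x", strategy = strat, seed = seed)
      w <- window_recording(make_healthy_protocol(p))
      expect_equal(unname(table(w$label)[c("reference", "exercise", "transition")]),
                   c(23L, 4L, 13L), ignore_attr = TRUE)
    }
  }
})

test_that("generation is deterministic given the seed", {
  p <- subject_profile("d", seed = 77)
  r1 <- make_healthy_protocol(p)
  r2 <- make_healthy_protocol(p)
  expect_identical(r1$signal$pressure, r2$signal$pressure)
  expect_identical(r1$cycles, r2$cycles)
  r3 <- make_healthy_protocol(subject_profile("d", seed = 78))
  expect_false(identical(r1$signal$pressure, r3$signal$pressure))
})

test_that("noiseless jitter-free waveform is periodic at the breathing frequency", {
  x <- synth_waveform(clean_profile(rest_rate = 20), "reference", 45)
  expect_length(x, 450)
  # period 3 s = 30 samples: the signal repeats exactly
  expect_equal(x[1:(450 - 30)], x[31:450], tolerance = 1e-12)
  ff <- fourier_features(x)
  peak <- ff$freq_hz[which.max(ff$magnitude[ff$bin > 0]) + 1]
  expect_equal(peak, 1 / 3, tolerance = 1e-9)
})

test_that("true instantaneous breathing frequency never exceeds 2 Hz", {
  p <- subject_profile("fast", rest_rate = 39, exercise_rate_multiplier = 2.8,
                       exercise_amplitude_multiplier = 1.2,
                       strategy = "rate_dominant", breath_length_cv = 0.4, seed = 5)
  rec <- make_healthy_protocol(p)
  expect_true(all(rec$cycles$length_s >= 0.5))
  # profiles whose exercise rate would cross 2 Hz are rejected outright
  expect_error(subject_profile("bad", rest_rate = 39, exercise_rate_multiplier = 4,
                               strategy = "rate_dominant"),
               "ceiling")
})

test_that("strategy multipliers reach the generated cycles (cycle-log oracle)", {
  p_rate <- subject_profile("r", strategy = "rate_dominant", seed = 8,
                            breath_length_cv = 0.05, amplitude_cv = 0.05)
  rec <- make_healthy_protocol(p_rate)
  ref <- dplyr::filter(rec$cycles, regime == "reference")
  exe <- dplyr::filter(rec$cycles, regime == "exercise")
  rate_factor <- median(ref$length_s) / median(exe$length_s)
  expect_equal(rate_factor, p_rate$exercise_rate_multiplier, tolerance = 0.08)

  p_amp <- subject_profile("a", strategy = "amplitude_dominant", seed = 9,
                           breath_length_cv = 0.05, amplitude_cv = 0.05)
  rec2 <- make_healthy_protocol(p_amp)
  depth_factor <- median(dplyr::filter(rec2$cycles, regime == "exercise")$depth) /
    median(dplyr::filter(rec2$cycles, regime == "reference")$depth)
  expect_equal(depth_factor, p_amp$exercise_amplitude_multiplier, tolerance = 0.08)
})

test_that("transition cycles decay from exercise back toward rest", {
  p <- subject_profile("t", strategy = "rate_dominant", seed = 12,
                       breath_length_cv = 0, amplitude_cv = 0, noise_sd = 0)
  rec <- make_healthy_protocol(p)
  tr <- dplyr::filter(rec$cycles, regime == "transition")
  early <- dplyr::filter(tr, t_onset < min(t_onset) + 90)
  late <- dplyr::filter(tr, t_onset > max(t_onset) - 90)
  rest_len <- 60 / p$rest_rate
  exe_len <- rest_len / p$exercise_rate_multiplier
  expect_true(mean(early$length_s) > exe_len + 0.1)   # genuinely intermediate
  expect_true(mean(early$length_s) < rest_len - 0.1)
  expect_equal(mean(late$length_s), rest_len, tolerance = 0.05)
})

test_that("copd-like recordings honour blocks, gaps and label noise settings", {
  p <- subject_profile("c", strategy = "mixed", seed = 21)
  rec <- make_copd_like(p, duration_hours = 2, n_exercise_blocks = 2,
                        label_noise_windows = 0)
  expect_equal(sum(rec$schedule_true$regime == "exercise"), 2)
  expect_identical(rec$schedule, rec$schedule_true)  # label-noise 0 => identity
  expect_true(any(rec$schedule_true$regime == "absent"))

  rec0 <- make_copd_like(p, duration_hours = 1, n_exercise_blocks = 0)
  expect_false(any(rec0$schedule_true$regime == "exercise"))

  expect_error(make_copd_like(p, duration_hours = 0.5, n_exercise_blocks = 10),
               "do not fit")
})

test_that("absent spans carry sensor noise but no breathing oscillation", {
  p <- subject_profile("gap", seed = 31)
  rec <- make_copd_like(p, duration_hours = 1, n_exercise_blocks = 0,
                        absent_fraction = 0.3)
  w <- window_recording(rec)
  sw <- segment_windows(w)
  absent_lbl <- sw$label == "excluded"
  expect_true(any(absent_lbl))
  expect_true(all(sw$quality[absent_lbl] == "absent"))
  sd_abs <- mean(purrr::map_dbl(sw$samples[absent_lbl], sd))
  expect_equal(sd_abs, p$noise_sd, tolerance = 0.15)
})

test_that("recordings round-trip through CSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  rec <- make_healthy_protocol(subject_profile("io1", seed = 3))
  write_recording(rec, dir)
  back <- read_recording(file.path(dir, "io1.csv"))
  expect_equal(back$signal$pressure, rec$signal$pressure)
  expect_equal(back$schedule, rec$schedule)
  expect_equal(back$cycles$t_min, rec$cycles$t_min)
  expect_equal(back$profile$seed, rec$profile$seed)

  cohort <- simulate_cohort(n_healthy = 2, n_copd = 0, seed = 4)
  write_cohort(cohort, file.path(dir, "cohort"))
  back2 <- read_cohort(file.path(dir, "cohort"))
  expect_equal(nrow(back2), 2)
  expect_equal(back2$recording[[1]]$signal$pressure,
               cohort$recording[[1]]$signal$pressure)
})
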