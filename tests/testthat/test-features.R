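test_that("breathing rate is the inverse median cycle length", {
  seg <- function(lengths) structure(list(cycle_lengths = lengths,
                                          depths = rep(1, length(lengths))),
                                     class = "breath_segmentation")
  expect_equal(breathing_rate(seg(rep(3, 15))), 1 / 3)
  expect_equal(breathing_rate(seg(c(2.5, 3.0, 3.5, 3.0, 2.8))), 1 / 3)
  expect_true(is.na(breathing_rate(seg(c(3, 3, 3)))))  # quality-filtered upstream
})

test_that("amplitude is the median inspiratory depth", {
  seg <- function(depths) structure(list(cycle_lengths = rep(3, length(depths) + 1),
                                         depths = depths),
                                    class = "breath_segmentation")
  expect_equal(signal_amplitude(seg(rep(0.7, 9))), 0.7)
  expect_equal(signal_amplitude(seg(c(1, 2, 100, 2, 2))), 2)  # robust to outlier
})

test_that("Fourier magnitudes follow the closed form for bin-aligned signals", {
  tt <- (0:449) / 10
  # constant signal: all mass in the DC bin
  ff <- fourier_features(rep(2.5, 450))
  expect_equal(ff$magnitude[ff$bin == 0], 2.5)
  expect_true(all(abs(ff$magnitude[ff$bin > 0]) < 1e-12))
  # pure sinusoid amplitude A at bin k: one-sided magnitude A / 2
  x <- 1.8 * sin(2 * pi * (12 / 45) * tt)
  ff2 <- fourier_features(x)
  expect_equal(ff2$magnitude[ff2$bin == 12], 1.8 / 2, tolerance = 1e-10)
  expect_lt(max(ff2$magnitude[ff2$bin != 12]), 1e-10)
  # retained bins: frequencies n/45 up to 2 Hz -> n = 0..90, 91 bins
  expect_equal(nrow(ff2), 91)
  expect_equal(max(ff2$freq_hz), 2)
  expect_error(fourier_features(c(rep(0, 449), NA)), "non-finite")
})

test_that("FFT path matches direct numerical integration of the coefficient integral", {
  tt <- (0:449) / 10
  f <- 1.2 * cos(2 * pi * 9 / 45 * tt) + 0.7 * sin(2 * pi * 30 / 45 * tt) +
    0.4 * sin(2 * pi * 81 / 45 * tt) + 0.9
  ours <- fourier_features(f)
  oracle <- fourier_integral_oracle(f, 10, ours$bin)
  expect_equal(ours$magnitude, oracle, tolerance = 1e-8)
})

test_that("spectral energy of a bin-aligned sinusoid concentrates in its bin", {
  tt <- (0:449) / 10
  x <- sin(2 * pi * (15 / 45) * tt)
  ff <- fourier_features(x)
  expect_gt(ff$magnitude[ff$bin == 15]^2 / sum(ff$magnitude^2), 0.99)
})

test_that("constant shifts move only the DC bin; rate and amplitude are unaffected", {
  x <- synth_waveform(clean_profile(), "reference", 45)
  f1 <- fourier_features(x); f2 <- fourier_features(x + 3)
  # DC magnitude is |window mean|, so it tracks the shift exactly
  expect_equal(f1$magnitude[f1$bin == 0], abs(mean(x)), tolerance = 1e-12)
  expect_equal(f2$magnitude[f2$bin == 0], abs(mean(x) + 3), tolerance = 1e-12)
  expect_equal(f1$magnitude[-1], f2$magnitude[-1], tolerance = 1e-9)
  s1 <- segment_breaths(x, 10); s2 <- segment_breaths(x + 3, 10)
  expect_equal(breathing_rate(s1), breathing_rate(s2))
  expect_equal(signal_amplitude(s1), signal_amplitude(s2), tolerance = 1e-9)
})

test_that("ARIMA sign convention maps the estimator onto the prediction equation", {
  # strong positive moving-average loading under the subtracted convention
  y <- withr::with_seed(42, simulate_arima111(450, mu = 0, phi = 0, theta = 0.7, sd = 1))
  est <- arima_features(y)
  expect_lt(abs(est$theta - 0.7), 0.15)
  expect_lt(abs(est$phi), 0.2)
})

test_that("ARIMA estimates behave at the null and degenerate limits", {
  # pure random walk: differenced series is white noise. At that null the
  # AR and MA roots cancel and are individually weakly identified, so the
  # identifiable quantities are the drift and the contrast phi - theta
  # ((1 - phi B) w = (1 - theta B) e is white noise iff phi = theta).
  y <- withr::with_seed(9, cumsum(rnorm(450)))
  est <- arima_features(y)
  expect_lt(abs(est$mu), 0.15)
  expect_lt(abs(est$phi - est$theta), 0.15)
  cst <- arima_features(rep(4, 450))
  expect_true(all(is.na(unlist(cst))))
  expect_equal(attr(cst, "reason"), "constant_series")
})

test_that("ARIMA estimator is consistent as the window grows", {
  rmse_at <- function(n, reps = 40) {
    errs <- withr::with_seed(n, vapply(seq_len(reps), function(i) {
      y <- simulate_arima111(n, 0.01, 0.5, 0.3)
      est <- arima_features(y)
      sqrt(mean((c(est$phi, est$theta) - c(0.5, 0.3))^2))
    }, numeric(1)))
    mean(errs, na.rm = TRUE)
  }
  r200 <- rmse_at(200); r450 <- rmse_at(450); r1000 <- rmse_at(1000)
  expect_gt(r200, r450)
  expect_gt(r450, r1000)
})

test_that("PCA projection is orthonormal, variance-ordered and leak-free", {
  x <- withr::with_seed(5, matrix(rnorm(40 * 8), 40, 8))
  p <- fit_pca(x, 5)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  proj <- project_pca(p, x)
  expect_equal(apply(proj, 2, var), p$explained_variance,
               tolerance = 1e-10, ignore_attr = TRUE)
  # rank-2 training matrix: components 3+ explain ~nothing
  basis <- withr::with_seed(6, matrix(rnorm(2 * 8), 2, 8))
  wts <- withr::with_seed(7, matrix(rnorm(30 * 2), 30, 2))
  p2 <- fit_pca(wts %*% basis, 5)
  expect_lt(sum(p2$explained_variance[3:5]), 1e-20 + 1e-10 * p2$explained_variance[1])
  # loadings depend only on training rows
  held <- withr::with_seed(8, matrix(rnorm(10 * 8), 10, 8))
  expect_identical(fit_pca(x, 5)$loadings, p$loadings)
  expect_identical(project_pca(fit_pca(x, 5), held), project_pca(p, held))
  expect_error(fit_pca(x[1:4, ], 5), "at least")
})

test_that("feature extraction is deterministic and flags poor windows as missing", {
  feats <- test_cohort_features(n = 2, seed = 11)
  cohort2 <- simulate_cohort(n_healthy = 2, n_copd = 0, seed = 11)
  feats2 <- extract_cohort_features(cohort2)
  expect_equal(feats, feats2)
  bad <- feats$quality != "ok"
  expect_true(all(is.na(feats$breathing_rate[bad])))
  expect_true(all(is.na(feats$arima_phi[bad])))
  ok <- feats$quality == "ok"
  expect_true(all(is.finite(feats$breathing_rate[ok])))
  expect_true(all(feats$breathing_rate[ok] > 0 & feats$breathing_rate[ok] <= 2))
  expect_true(all(feats$amplitude[ok] >= 0))
  expect_equal(sum(grepl("^f_\\d{4}$", names(feats))), 91)
})
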