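#' Breathing rate of a window
#'
#' The breathing rate is the inverse of the median breath-cycle length within
#' the window, in Hz. It is only defined for windows that pass the quality
#' filter; otherwise `NA`.
#'
#' @param seg A `breath_segmentation`.
#' @param config A [resp_config()].
#' @return Rate in Hz, or `NA_real_` for poor-quality windows.
#' @examples
#' # 15 cycles of 3 s -> 1/3 Hz = 20 breaths/min
#' @export
breathing_rate <- function(seg, config = resp_config()) {
  if (quality_filter(seg, config) != "ok") return(NA_real_)
  1 / stats::median(seg$cycle_lengths)
}

#' Signal amplitude of a window
#'
#' The median inspiratory depth: the distance between the pressure minima and
#' the estimated baseline, summarized by the median over the window's breaths.
#'
#' @inheritParams breathing_rate
#' @return Amplitude in pressure units, or `NA_real_` for poor-quality
#'   windows.
#' @export
signal_amplitude <- function(seg, config = resp_config()) {
  if (quality_filter(seg, config) != "ok") return(NA_real_)
  stats::median(seg$depths)
}

#' Fourier magnitude features of a window
#'
#' Computes the Fourier coefficients c_n = (1/T) * integral of f(t)
#' exp(-i n w t) dt over the window (w = 2 pi / T, T the window length),
#' via the FFT of the sampled window scaled by 1/N, and returns the
#' magnitudes |c_n| for all bins with frequency n/T at or below
#' `fourier_fmax` (default 2 Hz — above that a breathing rate has no
#' physiological sense, so higher bins carry only noise). At 45 s and 10 Hz
#' this keeps bins n = 0..90 with a resolution of 1/45 Hz. A pure sinusoid of
#' amplitude A at a bin frequency yields magnitude A/2 under this one-sided
#' normalization; the DC bin (n = 0) carries the window mean.
#'
#' @param samples Numeric pressure vector (full window).
#' @param sampling_rate Samples per second.
#' @param config A [resp_config()].
#' @return A tibble with columns `bin` (n), `freq_hz` (n/T) and `magnitude`.
#' @export
fourier_features <- function(samples, sampling_rate = 10, config = resp_config()) {
  if (any(!is.finite(samples))) stop("non-finite samples in window", call. = FALSE)
  n <- length(samples)
  T_s <- n / sampling_rate
  mags <- Mod(stats::fft(samples)) / n
  bins <- 0:(n - 1)
  freq <- bins / T_s
  keep <- freq <= config$fourier_fmax + 1e-12
  if (!config$include_dc) keep[1] <- FALSE
  tibble(bin = bins[keep], freq_hz = freq[keep], magnitude = mags[keep])
}

#' ARIMA(1,1,1) coefficients of a window
#'
#' Fits, by exact maximum likelihood, the ARIMA(1,1,1) model with drift
#'
#'   y_t = mu + y_(t-1) + Phi (y_(t-1) - y_(t-2)) - theta e_(t-1) + e_t
#'
#' to the window, i.e. an ARMA(1,1) with constant on the differenced series.
#' The fitted triple (mu, Phi, theta) summarizes the window's temporal
#' dynamics: mu the drift, Phi the autoregression of successive pressure
#' changes, theta the moving-average loading on the previous innovation.
#' Note the sign convention above subtracts the moving-average term, whereas
#' [stats::arima()] adds it; the returned `theta` is mapped accordingly
#' (`theta = -ma1`), and the drift is `intercept * (1 - Phi)` since
#' [stats::arima()] parameterizes the mean, not the constant. Stationarity
#' (|Phi| < 1) and invertibility (|theta| < 1) are enforced by the
#' estimator's parameter transformation.
#'
#' @param samples Numeric pressure vector (full window).
#' @return A named list `(mu, phi, theta)`; all `NA` (with attribute
#'   `"reason"`) for constant series or non-converging fits.
#' @export
arima_features <- function(samples) {
  miss <- function(reason) structure(list(mu = NA_real_, phi = NA_real_, theta = NA_real_),
                                     reason = reason)
  if (length(samples) < 10) return(miss("too_short"))
  d <- diff(samples)
  if (all(d == 0)) return(miss("constant_series"))
  fit <- tryCatch(
    suppressWarnings(stats::arima(d, order = c(1L, 0L, 1L), include.mean = TRUE,
                                  method = "ML", transform.pars = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # CSS-ML fallback for awkward likelihood surfaces
    fit <- tryCatch(
      suppressWarnings(stats::arima(d, order = c(1L, 0L, 1L), include.mean = TRUE)),
      error = function(e) NULL
    )
  }
  if (is.null(fit) || any(!is.finite(coef(fit)))) return(miss("non_convergence"))
  co <- coef(fit)
  list(mu = unname(co["intercept"] * (1 - co["ar1"])),
       phi = unname(co["ar1"]),
       theta = unname(-co["ma1"]))
}

#' Principal-component reduction of Fourier magnitudes
#'
#' The ~91 Fourier magnitudes cannot enter the classifiers directly without
#' running into the curse of dimensionality, so they are reduced to their
#' first `n_components` (default 5) principal components. The projection is
#' always learned on training rows only — in cross-validation it is refit
#' inside each training fold — and then applied unchanged to held-out rows.
#'
#' @param x Numeric matrix of training rows (windows) by Fourier bins.
#' @param n_components Number of components to keep.
#' @return An object of class `resp_pca`: `center`, `loadings` (bins by
#'   components, orthonormal), `explained_variance`.
#' @export
fit_pca <- function(x, n_components = 5) {
  x <- as.matrix(x)
  if (nrow(x) < max(n_components + 1L, 6L)) {
    stop("PCA needs at least ", max(n_components + 1L, 6L), " training rows, got ",
         nrow(x), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  structure(list(
    center = pc$center,
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = pc$sdev[seq_len(k)]^2,
    n_components = k
  ), class = "resp_pca")
}

#' @rdname fit_pca
#' @param pca A fitted `resp_pca`.
#' @param newdata Matrix of rows to project (same columns as training).
#' @return `project_pca()`: a rows-by-components score matrix.
#' @export
project_pca <- function(pca, newdata) {
  stopifnot(inherits(pca, "resp_pca"))
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, pca$center, "-") %*% pca$loadings
}

fourier_colnames <- function(freq_hz) sprintf("f_%04d", round(freq_hz * 1000))

#' Extract the full feature vector for every window
#'
#' Computes, for each quality-passing window, the four feature families:
#' breathing rate (Hz), signal amplitude, the ARIMA(1,1,1) triple
#' (`arima_mu`, `arima_phi`, `arima_theta`) and the Fourier magnitudes at or
#' below 2 Hz (columns `f_0000` ... `f_2000`, labelled by bin frequency in
#' mHz). Windows failing the quality filter keep their row with `NA`
#' features, so downstream code can drop them listwise per feature set.
#'
#' @param windows A segmented window tibble from [segment_windows()].
#' @param sampling_rate Samples per second.
#' @param config A [resp_config()].
#' @return A tibble: `subject`, `window`, `t0`, `label`, `quality`,
#'   `n_breaths`, the named features, and the Fourier magnitude columns.
#' @export
extract_features <- function(windows, sampling_rate = 10, config = resp_config()) {
  rows <- purrr::pmap(
    list(windows$samples, windows$segmentation, windows$quality),
    function(x, seg, quality) {
      ff <- fourier_features(x, sampling_rate, config)
      fmag <- stats::setNames(ff$magnitude, fourier_colnames(ff$freq_hz))
      if (quality != "ok" || is.null(seg)) {
        core <- c(breathing_rate = NA_real_, amplitude = NA_real_,
                  arima_mu = NA_real_, arima_phi = NA_real_, arima_theta = NA_real_)
        fmag[] <- NA_real_
      } else {
        ar <- arima_features(x)
        core <- c(breathing_rate = breathing_rate(seg, config),
                  amplitude = signal_amplitude(seg, config),
                  arima_mu = ar$mu, arima_phi = ar$phi, arima_theta = ar$theta)
      }
      as_tibble(as.list(c(core, fmag)))
    }
  )
  dplyr::bind_cols(
    dplyr::select(window_summary(windows),
                  dplyr::any_of(c("subject", "window", "t0", "label", "quality", "n_breaths"))),
    dplyr::bind_rows(rows)
  )
}

#' Extract features for every recording in a cohort
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (columns `subject`,
#'   `cohort`, `recording`).
#' @param config A [resp_config()].
#' @return A feature tibble (one row per window) with a `cohort` column.
#' @export
extract_cohort_features <- function(cohort, config = resp_config()) {
  purrr::map2_dfr(cohort$recording, cohort$cohort, function(rec, coh) {
    window_recording(rec, config) |>
      segment_windows(rec$sampling_rate, config) |>
      extract_features(rec$sampling_rate, config) |>
      dplyr::mutate(cohort = coh, .after = "subject")
  })
}
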