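#' Cut a recording into non-overlapping 45-second windows
#'
#' Splits the pressure trace into `floor(duration / window_s)` consecutive
#' windows; a trailing partial segment is discarded, never zero-padded. Each
#' window is labelled by the majority regime of its samples (ties broken
#' toward the earlier regime). Artifact spans count as reference — drinking,
#' coughing, speaking and mouth breathing belong to everyday "normality" —
#' and windows whose majority regime is `absent` are labelled `excluded`.
#'
#' @param rec A `resp_recording`.
#' @param config A [resp_config()].
#' @return A tibble with one row per window: `subject`, `window` (1-based
#'   index), `t0` (start time, s), `label` (`reference` / `exercise` /
#'   `transition` / `excluded`), and the window's `samples` as a list-column.
#' @examples
#' rec <- make_healthy_protocol(subject_profile("s1", seed = 7))
#' w <- window_recording(rec)
#' table(w$label)
#' @export
window_recording <- function(rec, config = resp_config()) {
  stopifnot(inherits(rec, "resp_recording"))
  fs <- rec$sampling_rate
  stopifnot(fs > 0)
  wlen <- round(config$window_s * fs)
  n_win <- floor(nrow(rec$signal) / wlen)
  if (n_win == 0) {
    return(tibble(subject = character(), window = integer(), t0 = numeric(),
                  label = character(), samples = list()))
  }
  x <- rec$signal$pressure
  edges <- c(0, cumsum(rec$schedule$duration_s))
  regimes <- rec$schedule$regime
  purrr::map_dfr(seq_len(n_win), function(i) {
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    tt <- (idx - 1L) / fs
    seg <- findInterval(tt, edges, rightmost.closed = TRUE)
    seg[seg < 1] <- 1L; seg[seg > length(regimes)] <- length(regimes)
    reg <- regimes[seg]
    reg[reg == "artifact"] <- "reference"
    counts <- table(factor(reg, levels = unique(reg)))  # unique() keeps temporal order
    maj <- names(counts)[which.max(counts)]             # which.max: earliest of tied
    tibble(
      subject = rec$profile$subject_id,
      window = i,
      t0 = (i - 1L) * config$window_s,
      label = if (maj == "absent") "excluded" else maj,
      samples = list(x[idx])
    )
  })
}

#' Detect subject presence in a window
#'
#' A subject is present when the window contains genuine respiratory
#' oscillation: the mean spectral power in the respiratory band (0.1-2 Hz)
#' must be at least `presence_threshold` times the broadband noise floor,
#' estimated from the spectrum above 2.5 Hz. A cannula-off window contains
#' white sensor noise only, whose spectrum is flat, so the ratio sits near 1.
#'
#' @param samples Numeric pressure vector for one window.
#' @param sampling_rate Samples per second.
#' @param config A [resp_config()].
#' @return `TRUE` if presence is detected. A ratio exactly at the threshold
#'   counts as present.
#' @export
detect_presence <- function(samples, sampling_rate = 10, config = resp_config()) {
  n <- length(samples)
  if (n < 8 || all(samples == samples[1])) return(FALSE)
  spec <- Mod(stats::fft(samples))^2 / n
  freq <- (seq_len(n) - 1) / n * sampling_rate
  half <- freq <= sampling_rate / 2
  spec <- spec[half]; freq <- freq[half]
  band <- freq >= 0.1 & freq <= 2
  floor_band <- freq > 2.5
  if (!any(floor_band)) floor_band <- freq > 2
  band_power <- mean(spec[band])
  noise_floor <- mean(spec[floor_band])
  if (noise_floor <= 0) return(band_power > 0)
  band_power / noise_floor >= config$presence_threshold
}

# Local-minima search with prominence filtering and minimum separation.
# Works on the inverted signal: a trough's prominence is how far the signal
# must rise (on its lower side) before reaching a deeper trough or the edge.
find_minima <- function(x, min_prominence, min_sep_samples) {
  y <- -x
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L  # strict rise then fall
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    lo <- i; while (lo > 1 && y[lo - 1] <= y[i]) lo <- lo - 1L
    left_base <- if (lo == 1) min(y[1:i]) else {
      j <- max(which(y[1:(i - 1)] > y[i]), 1L); min(y[j:i])
    }
    hi <- i; while (hi < n && y[hi + 1] <= y[i]) hi <- hi + 1L
    right_base <- if (hi == n) min(y[i:n]) else {
      j <- i + min(which(y[(i + 1):n] > y[i])); min(y[i:j])
    }
    y[i] - max(left_base, right_base)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (length(keep) == 0) return(integer(0))
  ord <- order(prom, decreasing = TRUE)
  selected <- integer(0)
  for (i in keep[ord]) {
    if (all(abs(i - selected) >= min_sep_samples)) selected <- c(selected, i)
  }
  sort(selected)
}

#' Segment the breath cycles of a window
#'
#' Detects inspiratory troughs as prominence-filtered local minima of the
#' (lightly smoothed) pressure signal with a minimum separation of
#' `min_breath_s` seconds, refines each trough to the deepest raw sample in
#' its neighbourhood, estimates the baseline as a rolling median, and derives
#' breath-cycle lengths (between consecutive troughs) and inspiratory depths
#' (baseline minus trough pressure).
#'
#' @inheritParams detect_presence
#' Trough *times* are refined to sub-sample precision by a noise-averaging
#' centroid of the smoothed dip, so cycle lengths do not inherit the sampling
#' grid's quantization.
#'
#' @return A list of class `breath_segmentation`: `minima_idx` (sample
#'   positions), `minima_t` (seconds, centroid-refined), `cycle_lengths` (s), `depths`
#'   (pressure units, >= 0), `baseline` (per-sample rolling-median curve).
#'   An empty segmentation (no minima) is returned when nothing is found.
#' @export
segment_breaths <- function(samples, sampling_rate = 10, config = resp_config()) {
  n <- length(samples)
  empty <- structure(list(minima_idx = integer(0), minima_t = numeric(0),
                          cycle_lengths = numeric(0), depths = numeric(0),
                          baseline = rep(NA_real_, n)),
                     class = "breath_segmentation")
  if (n < 4) return(empty)

  ks <- max(1L, round(config$smooth_s * sampling_rate))
  xs <- if (ks > 1) stats::filter(samples, rep(1 / ks, ks), sides = 2) else samples
  xs <- as.numeric(xs)
  xs[is.na(xs)] <- samples[is.na(xs)]

  prom <- config$min_prominence
  if (is.null(prom)) {
    rng <- stats::quantile(xs, c(0.05, 0.95), names = FALSE)
    prom <- 0.25 * (rng[2] - rng[1])
  }
  if (prom <= 0) return(empty)
  sep <- max(1L, round(config$min_breath_s * sampling_rate))
  idx <- find_minima(xs, prom, sep)
  if (length(idx) == 0) return(empty)

  # refine each trough to the deepest raw sample within +/- 0.2 s (for depth)
  r <- max(1L, as.integer(round(0.2 * sampling_rate)))
  idx <- vapply(idx, function(i) {
    lo <- max(1L, as.integer(i) - r); hi <- min(n, as.integer(i) + r)
    lo + which.min(samples[lo:hi]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))

  # sub-sample trough timing: centroid of the smoothed dip within +/- 0.5 s,
  # which averages out sensor noise that displaces the bare argmin
  rc <- max(1L, as.integer(round(0.5 * sampling_rate)))
  minima_t <- vapply(idx, function(i) {
    lo <- max(1L, i - rc); hi <- min(n, i + rc)
    w <- pmax(0, max(xs[lo:hi]) - xs[lo:hi])
    if (sum(w) == 0) w <- rep(1, hi - lo + 1)
    (sum((lo:hi) * w) / sum(w) - 1) / sampling_rate
  }, numeric(1))

  kb <- round(config$baseline_s * sampling_rate)
  if (kb %% 2 == 0) kb <- kb + 1L
  kb <- min(kb, if (n %% 2 == 1) n else n - 1L)
  baseline <- as.numeric(stats::runmed(samples, kb, endrule = "median"))

  depths <- pmax(0, baseline[idx] - samples[idx])
  structure(list(
    minima_idx = idx,
    minima_t = minima_t,
    cycle_lengths = diff(minima_t),
    depths = depths,
    baseline = baseline
  ), class = "breath_segmentation")
}

#' @export
print.breath_segmentation <- function(x, ...) {
  cat(sprintf("<breath_segmentation> %d troughs, %d cycles (median %.2f s, median depth %.2f)\n",
              length(x$minima_idx), length(x$cycle_lengths),
              stats::median(x$cycle_lengths), stats::median(x$depths)))
  invisible(x)
}

#' Window quality filter
#'
#' Windows with fewer than `min_breaths` (default 4) identified breaths, or
#' with breathing lengths too variable (coefficient of variation above
#' `max_cycle_cv`), are flagged poor quality and excluded from all
#' classification data. The too-few-breaths rule takes precedence and is
#' independent of every other setting.
#'
#' @param seg A `breath_segmentation`.
#' @param config A [resp_config()].
#' @return One of `"ok"`, `"too_few_breaths"`, `"too_variable"`.
#' @export
quality_filter <- function(seg, config = resp_config()) {
  ncyc <- length(seg$cycle_lengths)
  if (ncyc < config$min_breaths) return("too_few_breaths")
  m <- mean(seg$cycle_lengths)
  cv <- if (m > 0) stats::sd(seg$cycle_lengths) / m else Inf
  if (cv > config$max_cycle_cv) return("too_variable")
  "ok"
}

#' Assess presence, breaths and quality for every window
#'
#' Runs [detect_presence()], [segment_breaths()] and [quality_filter()] over a
#' window table, adding per-window quality status and breath summaries.
#'
#' @param windows Window tibble from [window_recording()].
#' @param sampling_rate Samples per second.
#' @param config A [resp_config()].
#' @return The input tibble with added columns `quality` (`ok` /
#'   `too_few_breaths` / `too_variable` / `absent`), `n_breaths`,
#'   `median_cycle_s`, `median_depth`, and the `segmentation` list-column.
#' @export
segment_windows <- function(windows, sampling_rate = 10, config = resp_config()) {
  res <- purrr::map(windows$samples, function(x) {
    if (!detect_presence(x, sampling_rate, config)) {
      return(list(quality = "absent", seg = NULL))
    }
    seg <- segment_breaths(x, sampling_rate, config)
    list(quality = quality_filter(seg, config), seg = seg)
  })
  windows |>
    dplyr::mutate(
      quality = purrr::map_chr(res, "quality"),
      segmentation = purrr::map(res, "seg"),
      n_breaths = purrr::map_int(res, ~ if (is.null(.x$seg)) 0L else length(.x$seg$cycle_lengths)),
      median_cycle_s = purrr::map_dbl(res, ~ if (is.null(.x$seg) || length(.x$seg$cycle_lengths) == 0)
        NA_real_ else stats::median(.x$seg$cycle_lengths)),
      median_depth = purrr::map_dbl(res, ~ if (is.null(.x$seg) || length(.x$seg$depths) == 0)
        NA_real_ else stats::median(.x$seg$depths))
    )
}

#' Drop list-columns for a tidy per-window export
#'
#' @param windows A segmented window tibble.
#' @return A plain tibble (one row per window) suitable for CSV export.
#' @export
window_summary <- function(windows) {
  dplyr::select(windows, -dplyr::any_of(c("samples", "segmentation")))
}
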