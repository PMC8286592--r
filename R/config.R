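#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one place so that a run
#' is fully described by (data, config, seed).
#'
#' @param window_s Window length in seconds. The analysis is defined on 45-s
#'   non-overlapping windows; trailing partial segments are discarded.
#' @param presence_threshold Subject presence requires the mean spectral power
#'   in the respiratory band (0.1-2 Hz) to be at least this multiple of the
#'   broadband noise floor (estimated above 2.5 Hz). The boundary case (ratio
#'   exactly equal to the threshold) counts as present.
#' @param min_prominence Minimum prominence (pressure units) for a local
#'   minimum to count as an inspiratory trough. `NULL` (default) selects an
#'   adaptive value of 25% of the window's robust range (5th-95th percentile).
#' @param min_breath_s Minimum separation between detected troughs, seconds.
#'   The default 0.5 s is the 2 Hz physiological ceiling on breathing rate.
#' @param smooth_s Length (s) of the moving-average smoother applied before
#'   trough *detection*; depths are always measured on the raw signal at the
#'   locally refined minimum.
#' @param baseline_s Length (s) of the rolling-median window used to estimate
#'   the pressure baseline.
#' @param max_cycle_cv Windows whose breath-length coefficient of variation
#'   exceeds this are flagged `too_variable`.
#' @param min_breaths Windows with fewer identified breaths than this are
#'   flagged `too_few_breaths` (hard rule: fewer than 4 breaths).
#' @param fourier_fmax Upper frequency bound (Hz) for retained Fourier bins;
#'   the bin at exactly `fourier_fmax` is included.
#' @param include_dc Keep the 0 Hz Fourier bin (encodes baseline level).
#' @param pca_components Number of principal components kept when reducing the
#'   Fourier magnitudes.
#' @param shrinkage Covariance shrinkage intensity toward the diagonal in
#'   `[0, 1]`, or `NULL` for a data-driven (Ledoit-Wolf-style) intensity.
#' @param ci_method `"delong"` or `"bootstrap"` for the AUC confidence
#'   interval.
#' @param cutoff_formula `"corrected"` minimizes sqrt(FPR^2 + (1-TPR)^2), the
#'   distance to the upper-left ROC corner; `"as-printed"` uses
#'   sqrt(FPR^2 + (1+TPR)^2) for audit purposes.
#' @param fold_assignment `"contiguous"` (default; honest under temporal
#'   autocorrelation) or `"random"` assignment of reference windows to folds
#'   in the one-class scheme.
#' @return A named list of class `resp_config`.
#' @export
resp_config <- function(window_s = 45,
                        presence_threshold = 3,
                        min_prominence = NULL,
                        min_breath_s = 0.5,
                        smooth_s = 0.3,
                        baseline_s = 5,
                        max_cycle_cv = 0.5,
                        min_breaths = 4,
                        fourier_fmax = 2,
                        include_dc = TRUE,
                        pca_components = 5,
                        shrinkage = NULL,
                        ci_method = c("delong", "bootstrap"),
                        cutoff_formula = c("corrected", "as-printed"),
                        fold_assignment = c("contiguous", "random")) {
  structure(list(
    window_s = window_s,
    presence_threshold = presence_threshold,
    min_prominence = min_prominence,
    min_breath_s = min_breath_s,
    smooth_s = smooth_s,
    baseline_s = baseline_s,
    max_cycle_cv = max_cycle_cv,
    min_breaths = min_breaths,
    fourier_fmax = fourier_fmax,
    include_dc = include_dc,
    pca_components = pca_components,
    shrinkage = shrinkage,
    ci_method = match.arg(ci_method),
    cutoff_formula = match.arg(cutoff_formula),
    fold_assignment = match.arg(fold_assignment)
  ), class = "resp_config")
}
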