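as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "exercise"
}

#' Empirical ROC curve
#'
#' Computes the empirical ROC over all distinct score thresholds with the
#' convention that a window is called exercise when `score >= threshold`
#' (both Mahalanobis distances and predicted probabilities increase with
#' exercise-likeness). Tied scores are grouped into a single step, so a
#' constant score vector yields the chance diagonal. Rows with missing
#' scores are dropped.
#'
#' @param scores Numeric scores, higher = more exercise-like.
#' @param labels Class labels: `"exercise"`/`"reference"`, logical, or 0/1.
#' @return A tibble of ROC points: `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) (threshold `Inf`) and ending at (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  keep <- is.finite(scores)
  scores <- scores[keep]; pos <- pos[keep]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_last <- cumsum(rle(s)$lengths)           # last index of each tie group
  tp <- cumsum(p)[grp_last]
  fp <- cumsum(!p)[grp_last]
  tibble(
    threshold = c(Inf, s[grp_last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A ROC tibble from [roc_curve()].
#' @return The AUC in `[0, 1]`; with tie-grouped steps this equals the
#'   tie-corrected Mann-Whitney statistic exactly.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' AUC with a 95% confidence interval
#'
#' The point estimate is the trapezoidal AUC (equivalently the tie-corrected
#' Mann-Whitney statistic). The confidence interval uses DeLong's method by
#' default, or a stratified bootstrap, both via the pROC package, truncated
#' to `[0, 1]`. With fewer than 2 observations in either class the AUC is
#' still returned but the interval is flagged unavailable (`NA`).
#'
#' @inheritParams roc_curve
#' @param config A [resp_config()] (`ci_method` is used).
#' @param conf_level Confidence level.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return A list: `auc`, `ci` (length-2 numeric, possibly `NA`), `method`.
#' @export
auc_with_ci <- function(scores, labels, config = resp_config(), conf_level = 0.95,
                        boot_n = 2000) {
  pos <- as_positive(labels)
  keep <- is.finite(scores)
  scores <- scores[keep]; pos <- pos[keep]
  auc <- auc_trapezoid(roc_curve(scores, pos))
  if (sum(pos) < 2 || sum(!pos) < 2) {
    return(list(auc = auc, ci = c(NA_real_, NA_real_), method = "unavailable"))
  }
  r <- pROC::roc(response = pos, predictor = scores, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  ci <- if (config$ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  } else {
    suppressWarnings(pROC::ci.auc(r, conf.level = conf_level, method = "bootstrap",
                                  boot.n = boot_n, boot.stratified = TRUE,
                                  progress = "none"))
  }
  list(auc = auc, ci = pmin(1, pmax(0, as.numeric(ci[c(1, 3)]))),
       method = config$ci_method)
}

#' Select the upper-left-corner operating point
#'
#' Picks the score threshold whose ROC point minimizes the distance to the
#' upper-left corner (FPR = 0, TPR = 1): sqrt(FPR^2 + (1 - TPR)^2). Ties are
#' broken toward higher sensitivity. For audit, `formula = "as-printed"`
#' minimizes sqrt(FPR^2 + (1 + TPR)^2) instead; that variant is minimized at
#' TPR = 0 and is kept only to reproduce the literal formula.
#'
#' @param roc A ROC tibble from [roc_curve()].
#' @param formula `"corrected"` (default) or `"as-printed"`.
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `distance`.
#' @export
select_cutoff <- function(roc, formula = c("corrected", "as-printed")) {
  formula <- match.arg(formula)
  stopifnot(nrow(roc) > 0)
  d <- if (formula == "corrected") {
    sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  } else {
    sqrt(roc$fpr^2 + (1 + roc$tpr)^2)
  }
  best <- which(d <= min(d) + 1e-12)
  best <- best[which.max(roc$tpr[best])]
  list(cutoff = roc$threshold[best],
       sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best],
       distance = d[best])
}

#' Full metric panel for a set of scored windows
#'
#' Computes the ROC curve, AUC with confidence interval, the
#' upper-left-corner cut-off, and the accuracy / sensitivity / specificity
#' at that cut-off (recomputed from the raw scores, calling exercise when
#' `score >= cutoff`).
#'
#' @param scored A tibble with `score` and `label` columns (e.g. from
#'   [one_class_cv()] or [supervised_cv()]), or a numeric score vector.
#' @param labels Labels, when `scored` is a bare numeric vector.
#' @param config A [resp_config()].
#' @return An object of class `resp_roc` with fields `roc` (points tibble),
#'   `auc`, `auc_ci`, `cutoff`, `accuracy`, `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scored, labels = NULL, config = resp_config()) {
  if (is.data.frame(scored)) {
    scores <- scored$score; labels <- scored$label
  } else {
    scores <- scored
  }
  pos <- as_positive(labels)
  keep <- is.finite(scores)
  scores <- scores[keep]; pos <- pos[keep]
  roc <- roc_curve(scores, pos)
  a <- auc_with_ci(scores, pos, config)
  cut <- select_cutoff(roc, config$cutoff_formula)
  called <- scores >= cut$cutoff
  structure(list(
    roc = roc,
    auc = a$auc, auc_ci = a$ci, ci_method = a$method,
    cutoff = cut$cutoff,
    accuracy = mean(called == pos),
    sensitivity = mean(called[pos]),
    specificity = mean(!called[!pos]),
    n_pos = sum(pos), n_neg = sum(!pos),
    cutoff_formula = config$cutoff_formula
  ), class = "resp_roc")
}

#' @export
print.resp_roc <- function(x, ...) {
  cat(sprintf(
    "<resp_roc> AUC %.3f (%.3f-%.3f, %s), cutoff %.3g\n  accuracy %.3f, sensitivity %.3f, specificity %.3f  [%d exercise / %d reference]\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method, x$cutoff,
    x$accuracy, x$sensitivity, x$specificity, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Feature-set comparison table
#'
#' Pools scored windows across subjects and computes, for every
#' (cohort, mode, feature set) combination present, the four headline
#' metrics: accuracy, sensitivity and specificity at the upper-left-corner
#' cut-off, and AUC with its confidence interval.
#'
#' @param scored Scored-window tibble(s): output of [one_class_cv()] /
#'   [supervised_cv()], possibly row-bound across runs, with an optional
#'   `cohort` column.
#' @param config A [resp_config()].
#' @return A tibble with one row per (cohort, mode, feature_set), feature
#'   sets in canonical order.
#' @export
build_comparison <- function(scored, config = resp_config()) {
  stopifnot(nrow(scored) > 0)
  if (!"cohort" %in% names(scored)) scored$cohort <- "cohort"
  scored |>
    dplyr::mutate(feature_set = factor(.data$feature_set, levels = names(feature_sets()))) |>
    dplyr::group_by(.data$cohort, .data$mode, .data$feature_set) |>
    dplyr::group_modify(function(g, key) {
      r <- evaluate_scores(g, config = config)
      tibble(accuracy = r$accuracy, sensitivity = r$sensitivity,
             specificity = r$specificity, auc = r$auc,
             auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
             n_windows = r$n_pos + r$n_neg)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cohort, .data$mode, .data$feature_set) |>
    dplyr::mutate(feature_set = as.character(.data$feature_set))
}

#' Render a comparison table as markdown
#'
#' @param comparison Output of [build_comparison()].
#' @param digits Digits for the proportions.
#' @return A character vector of markdown lines (one table per cohort/mode).
#' @export
comparison_markdown <- function(comparison, digits = 3) {
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  out <- character(0)
  for (key in split(comparison, interaction(comparison$cohort, comparison$mode, drop = TRUE))) {
    out <- c(out,
      sprintf("**%s cohort, %s classification**", key$cohort[1],
              gsub("_", "-", key$mode[1])),
      "",
      "| Predictive variables | Accuracy | Sensitivity | Specificity | AUC |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s (%s-%s) |",
              key$feature_set, fmt(key$accuracy), fmt(key$sensitivity),
              fmt(key$specificity), fmt(key$auc), fmt(key$auc_lo), fmt(key$auc_hi)),
      "")
  }
  out
}
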