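#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ROC result into its curve points
#'
#' @param x A `resp_roc` from [evaluate_scores()].
#' @param ... Unused.
#' @return A tibble of ROC points (`threshold`, `fpr`, `tpr`).
#' @method tidy resp_roc
#' @export
tidy.resp_roc <- function(x, ...) x$roc

#' One-row summary of a ROC result
#'
#' @param x A `resp_roc`.
#' @param ... Unused.
#' @return A one-row tibble: accuracy, sensitivity, specificity, AUC and its
#'   confidence interval, cut-off and class sizes.
#' @method glance resp_roc
#' @export
glance.resp_roc <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, auc = x$auc,
         auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
         cutoff = x$cutoff, n_exercise = x$n_pos, n_reference = x$n_neg)
}

#' Tidy a reference model
#'
#' @param x A `resp_reference` from [fit_reference()].
#' @param ... Unused.
#' @return A tibble with one row per feature: `term`, `mean`, `variance`.
#' @method tidy resp_reference
#' @export
tidy.resp_reference <- function(x, ...) {
  nm <- names(x$mean)
  if (is.null(nm)) nm <- paste0("x", seq_along(x$mean))
  tibble(term = nm, mean = unname(x$mean), variance = unname(diag(x$cov)))
}

#' One-row summary of a reference model
#'
#' @param x A `resp_reference`.
#' @param ... Unused.
#' @return A one-row tibble: training size, dimension, shrinkage intensity,
#'   subject.
#' @method glance resp_reference
#' @export
glance.resp_reference <- function(x, ...) {
  tibble(n = x$n, dim = length(x$mean), lambda = x$lambda,
         pca = !is.null(x$pca), subject = x$subject_id)
}

#' Tidy the fixed effects of a mixed logistic model
#'
#' @param x A `resp_glmm` from [fit_mixed_logistic()].
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (coefficients are on the scale of the internally standardized
#'   covariates).
#' @method tidy resp_glmm
#' @export
tidy.resp_glmm <- function(x, ...) {
  co <- summary(x$model)$coefficients
  if (inherits(x$model, "glmmTMB")) co <- co$cond
  co <- co[, 1:4, drop = FALSE]  # estimate, se, z, p under all three engines
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' One-row summary of a mixed logistic model
#'
#' @param x A `resp_glmm`.
#' @param ... Unused.
#' @return A one-row tibble: feature set, convergence flag, number of
#'   observations and subjects, AIC.
#' @method glance resp_glmm
#' @export
glance.resp_glmm <- function(x, ...) {
  fr <- stats::model.frame(x$model)
  tibble(feature_set = x$feature_set, fit_spec = x$spec, converged = x$converged,
         nobs = stats::nobs(x$model),
         n_subjects = if ("subject" %in% names(fr)) nlevels(fr$subject) else NA_integer_,
         aic = tryCatch(stats::AIC(x$model), error = function(e) NA_real_))
}

#' Plot a ROC curve
#'
#' @param object A `resp_roc`.
#' @param ... Unused.
#' @return A ggplot: the ROC curve with the chance diagonal and the selected
#'   upper-left-corner operating point.
#' @method autoplot resp_roc
#' @export
autoplot.resp_roc <- function(object, ...) {
  pt <- object$roc[which.min(abs(object$roc$threshold - object$cutoff)), ]
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = pt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC %.3f (%.3f-%.3f)", object$auc,
                      object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a recording with its regime annotation
#'
#' @param rec A `resp_recording`.
#' @param from,to Time range to show, seconds.
#' @return A ggplot of the pressure trace with regime spans shaded.
#' @export
plot_recording <- function(rec, from = 0, to = min(600, nrow(rec$signal) / rec$sampling_rate)) {
  sig <- dplyr::filter(rec$signal, .data$time_s >= from, .data$time_s <= to)
  sched <- rec$schedule |>
    dplyr::mutate(t_end = cumsum(.data$duration_s),
                  t_start = .data$t_end - .data$duration_s) |>
    dplyr::filter(.data$t_end > from, .data$t_start < to)
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$time_s, y = .data$pressure)) +
    ggplot2::geom_rect(
      data = sched, inherit.aes = FALSE,
      ggplot2::aes(xmin = pmax(.data$t_start, from), xmax = pmin(.data$t_end, to),
                   ymin = -Inf, ymax = Inf, fill = .data$regime),
      alpha = 0.15
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Nasal pressure (a.u.)",
                  title = sprintf("%s (%s)", rec$profile$subject_id, rec$kind)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_recording
#' @param object A `resp_recording`.
#' @param ... Passed to [plot_recording()].
#' @method autoplot resp_recording
#' @export
autoplot.resp_recording <- function(object, ...) plot_recording(object, ...)

#' Plot a feature-set comparison
#'
#' @param comparison Output of [build_comparison()].
#' @return A ggplot: AUC with confidence intervals per feature set, faceted
#'   by cohort and mode.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = factor(.data$feature_set, levels = rev(names(feature_sets()))),
                 y = .data$auc)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$auc_lo, ymax = .data$auc_hi)) +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(.data$cohort ~ .data$mode) +
    ggplot2::labs(x = NULL, y = "AUC (95% CI)") +
    ggplot2::theme_minimal()
}
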