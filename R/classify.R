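#' The six compared feature sets
#'
#' @return A named list mapping feature-set names to the feature columns they
#'   use. The `fourier` set is special-cased: its raw magnitude columns are
#'   reduced to principal components inside each training fold.
#' @export
feature_sets <- function() {
  list(
    rate = "breathing_rate",
    amplitude = "amplitude",
    arima = c("arima_mu", "arima_phi", "arima_theta"),
    rate_amplitude = c("breathing_rate", "amplitude"),
    rate_amplitude_arima = c("breathing_rate", "amplitude",
                             "arima_mu", "arima_phi", "arima_theta"),
    fourier = "fourier"
  )
}

feature_matrix <- function(features, feature_set) {
  cols <- if (identical(feature_set, "fourier")) {
    grep("^f_\\d{4}$", names(features), value = TRUE)
  } else {
    feature_sets()[[feature_set]]
  }
  if (length(cols) == 0 || !all(cols %in% names(features))) {
    stop("feature columns for set '", feature_set, "' not found", call. = FALSE)
  }
  as.matrix(features[, cols, drop = FALSE])
}

usable_rows <- function(features, feature_set) {
  x <- feature_matrix(features, feature_set)
  features$quality == "ok" & stats::complete.cases(x) &
    features$label %in% c("reference", "exercise")
}

# Schafer-Strimmer-style data-driven shrinkage intensity toward the diagonal:
# lambda* = sum_{i!=j} Var-hat(s_ij) / sum_{i!=j} s_ij^2, clamped to [0, 1].
shrinkage_intensity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  if (p < 2 || n < 3) return(0)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- stats::cov(x)
  num <- 0; den <- 0
  for (i in 1:(p - 1)) {
    for (j in (i + 1):p) {
      w <- xc[, i] * xc[, j]
      v <- n / (n - 1)^3 * sum((w - mean(w))^2)
      num <- num + v
      den <- den + s[i, j]^2
    }
  }
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Fit a per-subject reference (one-class) model
#'
#' Learns the mean vector and variance-covariance matrix of reference-class
#' feature vectors, the ingredients of the Mahalanobis novelty score
#' d(x) = sqrt((x - mu)' Sigma^-1 (x - mu)). The covariance is shrunk toward
#' its diagonal — Sigma_hat = (1 - lambda) S + lambda diag(S) — because the
#' small training folds (often ~18 windows with up to 5 features) can make
#' the raw sample covariance singular; by default lambda is estimated from
#' the data, and `lambda = 0` recovers the raw sample covariance.
#'
#' @param x Matrix (or data frame) of reference-window feature rows.
#' @param lambda Shrinkage intensity in `[0, 1]`, or `NULL` for data-driven.
#' @param subject_id Optional subject label carried in the model.
#' @param pca Optional `resp_pca` applied to rows before fitting (the Fourier
#'   case); it must have been fitted on these same training rows.
#' @return An object of class `resp_reference`: `mean`, `cov`, `lambda`,
#'   `chol` (upper-triangular Cholesky factor), `n`, `pca`, `subject_id`.
#' @export
fit_reference <- function(x, lambda = NULL, subject_id = NA_character_, pca = NULL) {
  if (!is.null(pca)) x <- project_pca(pca, x)
  x <- as.matrix(x)
  p <- ncol(x)
  if (nrow(x) < p + 2) {
    stop("reference model for subject '", subject_id, "' needs at least ",
         p + 2, " rows, got ", nrow(x), call. = FALSE)
  }
  if (is.null(lambda)) lambda <- shrinkage_intensity(x)
  stopifnot(lambda >= 0, lambda <= 1)
  s <- stats::cov(x)
  sh <- (1 - lambda) * s + lambda * diag(diag(s), p)
  # guard against zero-variance features
  eps <- 1e-10 * mean(diag(sh))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-10
  sh <- sh + diag(eps, p)
  structure(list(
    mean = colMeans(x),
    cov = sh,
    lambda = lambda,
    chol = chol(sh),
    n = nrow(x),
    pca = pca,
    subject_id = subject_id
  ), class = "resp_reference")
}

#' Mahalanobis novelty score
#'
#' Computes d(x) = sqrt((x - mu)' Sigma^-1 (x - mu)) against a fitted
#' reference model, via triangular solves with the stored Cholesky factor
#' (no explicit matrix inverse). Larger distances mean more novel — more
#' exercise-like — windows.
#'
#' @param model A `resp_reference` from [fit_reference()].
#' @param x A feature vector, or a matrix of row vectors.
#' @return Numeric vector of distances (>= 0); `NA` for rows with missing
#'   values.
#' @examples
#' m <- structure(list(mean = c(0, 0), chol = chol(diag(2)), pca = NULL),
#'                class = "resp_reference")
#' mahalanobis_score(m, c(3, 4))  # 5: Euclidean case
#' @export
mahalanobis_score <- function(model, x) {
  stopifnot(inherits(model, "resp_reference"))
  if (!is.null(model$pca)) x <- project_pca(model$pca, rbind(x))
  x <- rbind(x)
  stopifnot(ncol(x) == length(model$mean))
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok)) {
    d <- sweep(x[ok, , drop = FALSE], 2, model$mean, "-")
    z <- backsolve(model$chol, t(d), transpose = TRUE)
    out[ok] <- sqrt(colSums(z^2))
  }
  out
}

make_folds <- function(n, k, assignment = c("contiguous", "random"), seed = NULL) {
  assignment <- match.arg(assignment)
  if (assignment == "contiguous") {
    sort(rep_len(seq_len(k), n))  # blocks of near-equal size, temporal order
  } else {
    if (!is.null(seed)) withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    else sample(rep_len(seq_len(k), n))
  }
}

#' Per-subject one-class cross-validation
#'
#' For each subject, the usable reference windows are split into `k` folds
#' (contiguous blocks by default, preserving temporal autocorrelation): each
#' fold in turn is held out while the remaining folds provide the reference
#' model (mean and shrunk covariance; for the `fourier` set a PCA is refit on
#' the training rows inside each fold). Held-out windows are then scored by
#' Mahalanobis distance. Under the `"healthy"` scheme the few exercise
#' windows are scored in every fold (five predictions per exercise window,
#' one per reference window); under the `"copd"` scheme exercise windows are
#' also partitioned into `k` folds, giving exactly one prediction per usable
#' window.
#'
#' @param features Feature tibble (see [extract_features()]), any number of
#'   subjects.
#' @param feature_set One of `names(feature_sets())`.
#' @param scheme `"healthy"` or `"copd"` exercise-scoring rule.
#' @param k Number of folds.
#' @param config A [resp_config()].
#' @param seed Seed used when `fold_assignment = "random"`.
#' @param min_reference Minimum usable reference windows per subject; subjects
#'   below it are skipped with a warning.
#' @return A tibble of scored windows: `subject`, `window`, `fold`, `label`,
#'   `score` (Mahalanobis distance), `feature_set`, `mode = "one_class"`.
#' @export
one_class_cv <- function(features, feature_set, scheme = c("healthy", "copd"),
                         k = 5, config = resp_config(), seed = 1L,
                         min_reference = 10) {
  scheme <- match.arg(scheme)
  is_fourier <- identical(feature_set, "fourier")
  use <- usable_rows(features, feature_set)
  feats <- features[use, , drop = FALSE]

  purrr::map_dfr(split(feats, feats$subject), function(fs) {
    ref <- fs[fs$label == "reference", , drop = FALSE]
    exe <- fs[fs$label == "exercise", , drop = FALSE]
    if (nrow(ref) < min_reference) {
      warning("subject ", fs$subject[1], ": only ", nrow(ref),
              " usable reference windows, skipped", call. = FALSE)
      return(tibble())
    }
    ref <- ref[order(ref$window), , drop = FALSE]
    exe <- exe[order(exe$window), , drop = FALSE]
    ref_fold <- make_folds(nrow(ref), k, config$fold_assignment, seed)
    exe_fold <- if (scheme == "copd" && nrow(exe) > 0) {
      make_folds(nrow(exe), k, config$fold_assignment, seed + 1L)
    } else NULL

    purrr::map_dfr(seq_len(k), function(fold) {
      train <- ref[ref_fold != fold, , drop = FALSE]
      test_ref <- ref[ref_fold == fold, , drop = FALSE]
      test_exe <- if (scheme == "healthy") exe else exe[exe_fold == fold, , drop = FALSE]
      test <- dplyr::bind_rows(test_ref, test_exe)
      if (nrow(test) == 0) return(tibble())
      xtr <- feature_matrix(train, feature_set)
      pca <- if (is_fourier) fit_pca(xtr, config$pca_components) else NULL
      model <- fit_reference(xtr, lambda = config$shrinkage,
                             subject_id = fs$subject[1], pca = pca)
      tibble(
        subject = test$subject, window = test$window, fold = fold,
        label = test$label,
        score = mahalanobis_score(model, feature_matrix(test, feature_set)),
        feature_set = feature_set, mode = "one_class"
      )
    })
  })
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}
standardize_apply <- function(x, sc) sweep(sweep(x, 2, sc$mean, "-"), 2, sc$sd, "/")

#' Fit a supervised mixed-effects logistic model
#'
#' Fits a binomial GLMM with logit link: exercise vs reference as outcome,
#' the feature set's covariates as fixed effects, and per-subject random
#' intercepts and random slopes on every covariate (diagonal random-effect
#' covariance), accounting for inter-individual variability in how subjects
#' adapt to load. Fitting uses Laplace-approximated maximum likelihood via
#' [lme4::glmer()]. Covariates are standardized internally (the scaling is
#' stored and re-applied at prediction); for the `fourier` set, the raw
#' magnitudes are first reduced by a PCA fitted on the supplied (training)
#' rows. On non-convergence the model falls back to random intercepts only.
#'
#' @param features Feature tibble with `subject`, `label` and feature columns
#'   (reference and exercise rows only are used).
#' @param feature_set One of `names(feature_sets())`.
#' @param config A [resp_config()].
#' @return An object of class `resp_glmm`: the `lme4` fit plus the scaling,
#'   optional PCA, covariate names and a convergence flag.
#' @export
fit_mixed_logistic <- function(features, feature_set, config = resp_config()) {
  use <- usable_rows(features, feature_set)
  feats <- features[use, , drop = FALSE]
  if (length(unique(feats$subject)) < 2) {
    stop("supervised GLMM needs at least 2 subjects", call. = FALSE)
  }
  if (length(unique(feats$label)) < 2) {
    stop("supervised GLMM needs both classes present", call. = FALSE)
  }
  x <- feature_matrix(feats, feature_set)
  pca <- NULL
  if (identical(feature_set, "fourier")) {
    pca <- fit_pca(x, config$pca_components)
    x <- project_pca(pca, x)
    colnames(x) <- paste0("PC", seq_len(ncol(x)))
  }
  sc <- standardize_fit(x)
  xs <- standardize_apply(x, sc)
  covars <- colnames(xs)
  dat <- data.frame(.y = as.integer(feats$label == "exercise"),
                    subject = factor(feats$subject), xs, check.names = FALSE)
  rhs <- paste(covars, collapse = " + ")
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", optCtrl = list(maxfun = 1e5),
                             check.conv.singular = "ignore")
  try_fit <- function(expr) {
    fit <- tryCatch(suppressMessages(suppressWarnings(expr)), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    fe <- tryCatch(
      if (inherits(fit, "glmmTMB")) glmmTMB::fixef(fit)$cond else
        if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit),
      error = function(e) NA_real_)
    if (all(is.finite(fe))) fit else NULL
  }
  # Fitting ladder. Laplace glmer with diagonal random slopes is the primary
  # estimator; its PIRLS step breaks down under (near-)complete separation,
  # which clean synthetic cohorts readily produce, so glmmTMB fits the same
  # model as a robust fallback, then random intercepts only, then (last
  # resort) a plain fixed-effects logistic regression.
  f_full <- function() lme4::glmer(
    stats::as.formula(paste0(".y ~ ", rhs, " + (1 + ", rhs, " || subject)")),
    data = dat, family = stats::binomial("logit"), control = ctrl)
  f_full0 <- function() lme4::glmer(
    stats::as.formula(paste0(".y ~ ", rhs, " + (1 + ", rhs, " || subject)")),
    data = dat, family = stats::binomial("logit"), control = ctrl, nAGQ = 0L)
  f_tmb <- function() glmmTMB::glmmTMB(
    stats::as.formula(paste0(".y ~ ", rhs, " + diag(1 + ", rhs, " | subject)")),
    data = dat, family = stats::binomial("logit"))
  f_int <- function() lme4::glmer(
    stats::as.formula(paste0(".y ~ ", rhs, " + (1 | subject)")),
    data = dat, family = stats::binomial("logit"), control = ctrl)
  f_tmb_int <- function() glmmTMB::glmmTMB(
    stats::as.formula(paste0(".y ~ ", rhs, " + (1 | subject)")),
    data = dat, family = stats::binomial("logit"))
  f_glm <- function() stats::glm(
    stats::as.formula(paste0(".y ~ ", rhs)),
    data = dat, family = stats::binomial("logit"))
  ladder <- list(slopes_laplace = f_full, slopes_nAGQ0 = f_full0,
                 slopes_tmb = f_tmb, intercept_laplace = f_int,
                 intercept_tmb = f_tmb_int, fixed_glm = f_glm)
  fit <- NULL; spec <- NA_character_
  for (nm in names(ladder)) {
    fit <- try_fit(ladder[[nm]]())
    if (!is.null(fit)) { spec <- nm; break }
  }
  if (is.null(fit)) stop("GLMM failed to fit", call. = FALSE)
  structure(list(model = fit, feature_set = feature_set, scaling = sc, pca = pca,
                 covariates = covars, converged = spec == "slopes_laplace",
                 spec = spec),
            class = "resp_glmm")
}

#' Predicted exercise probabilities from a fitted GLMM
#'
#' @param object A `resp_glmm`.
#' @param features Feature tibble of rows to score.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1); `NA` for rows with
#'   missing features.
#' @export
predict.resp_glmm <- function(object, features, ...) {
  x <- feature_matrix(features, object$feature_set)
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x) & features$quality == "ok"
  if (!any(ok)) return(out)
  xo <- x[ok, , drop = FALSE]
  if (!is.null(object$pca)) {
    xo <- project_pca(object$pca, xo)
    colnames(xo) <- paste0("PC", seq_len(ncol(xo)))
  }
  xs <- standardize_apply(xo, object$scaling)
  nd <- data.frame(subject = factor(features$subject[ok]), xs, check.names = FALSE)
  out[ok] <- if (inherits(object$model, "glm")) {
    stats::predict(object$model, newdata = nd, type = "response")
  } else {
    stats::predict(object$model, newdata = nd, type = "response",
                   allow.new.levels = TRUE)
  }
  out
}

glmm_fixef <- function(model) {
  if (inherits(model, "glmmTMB")) glmmTMB::fixef(model)$cond
  else if (inherits(model, "merMod")) lme4::fixef(model)
  else stats::coef(model)
}

#' @export
print.resp_glmm <- function(x, ...) {
  cat(sprintf("<resp_glmm> feature set '%s', fit: %s\n", x$feature_set, x$spec))
  print(glmm_fixef(x$model))
  invisible(x)
}

#' Cross-validated supervised classification
#'
#' Produces predicted exercise probabilities for every usable window under
#' the supervised mixed-model framework. In `"cv"` mode (default), windows
#' are assigned to `k` folds stratified within subject and class, so that
#' every subject contributes to every training fold (its random effects stay
#' estimable) and each window is predicted exactly once by a model that never
#' saw it; the Fourier PCA is refit inside each training fold. `"insample"`
#' mode fits once on all rows and scores them in-sample.
#'
#' @inheritParams fit_mixed_logistic
#' @param k Number of folds.
#' @param eval `"cv"` or `"insample"`.
#' @param seed Seed for the stratified fold assignment.
#' @return A tibble of scored windows: `subject`, `window`, `fold`, `label`,
#'   `score` (probability), `feature_set`, `mode = "supervised"`.
#' @export
supervised_cv <- function(features, feature_set, k = 5, eval = c("cv", "insample"),
                          config = resp_config(), seed = 1L) {
  eval <- match.arg(eval)
  use <- usable_rows(features, feature_set)
  feats <- features[use, , drop = FALSE]

  if (eval == "insample") {
    model <- fit_mixed_logistic(feats, feature_set, config)
    return(tibble(
      subject = feats$subject, window = feats$window, fold = 0L,
      label = feats$label, score = predict(model, feats),
      feature_set = feature_set, mode = "supervised"
    ))
  }

  fold <- integer(nrow(feats))
  withr::with_seed(seed, {
    for (grp in split(seq_len(nrow(feats)),
                      interaction(feats$subject, feats$label, drop = TRUE))) {
      fold[grp] <- sample(rep_len(seq_len(k), length(grp)))
    }
  })
  purrr::map_dfr(seq_len(k), function(f) {
    train <- feats[fold != f, , drop = FALSE]
    test <- feats[fold == f, , drop = FALSE]
    if (nrow(test) == 0) return(tibble())
    model <- fit_mixed_logistic(train, feature_set, config)
    tibble(
      subject = test$subject, window = test$window, fold = f,
      label = test$label, score = predict(model, test),
      feature_set = feature_set, mode = "supervised"
    )
  })
}
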