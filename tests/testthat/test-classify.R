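test_that("reference model reduces to (mean, variance) in one dimension", {
  x <- matrix(withr::with_seed(1, rnorm(50, 5, 2)), ncol = 1)
  m <- fit_reference(x, lambda = 0)
  expect_equal(unname(m$mean), mean(x))
  expect_equal(unname(m$cov[1, 1]), var(as.vector(x)), tolerance = 1e-9)
  expect_equal(mahalanobis_score(m, 7), abs(7 - mean(x)) / sd(x), tolerance = 1e-9)
})

test_that("reference model recovers a known Gaussian within 3 standard errors", {
  mu <- c(1, -2, 0.5)
  sims <- withr::with_seed(2, {
    x <- matrix(rnorm(500 * 3), 500, 3) %*% chol(diag(c(1, 4, 0.25))) +
      matrix(mu, 500, 3, byrow = TRUE)
    fit_reference(x)
  })
  se <- sqrt(diag(sims$cov) / sims$n)
  expect_true(all(abs(sims$mean - mu) < 3 * se))
})

test_that("shrinkage renders a singular covariance positive-definite", {
  x <- withr::with_seed(3, matrix(rnorm(12 * 3), 12, 3))
  x <- cbind(x, x[, 1])  # duplicated feature
  expect_error(fit_reference(x, lambda = 0) |> (\(m) chol(m$cov))(), NA)
  m <- fit_reference(x)  # data-driven intensity
  expect_gt(m$lambda, 0)
  ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  d <- mahalanobis_score(m, x[1, ])
  expect_true(is.finite(d) && d >= 0)
})

test_that("Mahalanobis scores match the explicit-inverse computation", {
  errs <- withr::with_seed(4, vapply(1:100, function(i) {
    p <- sample(2:6, 1)
    n <- p + sample(10:40, 1)
    x <- matrix(rnorm(n * p), n, p)
    m <- fit_reference(x)
    y <- rnorm(p, sd = 2)
    brute <- sqrt(drop(t(y - m$mean) %*% solve(m$cov) %*% (y - m$mean)))
    abs(mahalanobis_score(m, y) - brute)
  }, numeric(1)))
  expect_lt(max(errs), 1e-10)
  # x = mean scores zero; identity covariance gives the Euclidean distance
  m <- structure(list(mean = c(0, 0), chol = chol(diag(2)), pca = NULL),
                 class = "resp_reference")
  expect_equal(mahalanobis_score(m, c(3, 4)), 5)
  expect_equal(mahalanobis_score(m, c(0, 0)), 0)
  expect_true(is.na(mahalanobis_score(m, c(NA, 1))))
})

test_that("Mahalanobis distance is invariant under joint affine transforms", {
  withr::with_seed(5, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    y <- matrix(rnorm(10 * 3), 10, 3)
    d0 <- mahalanobis_score(fit_reference(x, lambda = 0), y)
    for (i in 1:5) {
      # well-conditioned invertible transform: Q1 diag(s) Q2 with s in [0.5, 2]
      q1 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      q2 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      a <- q1 %*% diag(runif(3, 0.5, 2)) %*% q2
      b <- rnorm(3)
      xt <- sweep(x %*% a, 2, b, "+")
      yt <- sweep(y %*% a, 2, b, "+")
      dt <- mahalanobis_score(fit_reference(xt, lambda = 0), yt)
      expect_equal(dt, d0, tolerance = 1e-8)
    }
  })
})

test_that("one-class CV emits the healthy and copd prediction counts", {
  feats <- test_cohort_features(n = 2, seed = 11)
  one <- dplyr::filter(feats, subject == subject[1])
  n_ref <- sum(one$label == "reference" & one$quality == "ok")
  n_exe <- sum(one$label == "exercise" & one$quality == "ok")
  sc_h <- one_class_cv(one, "rate_amplitude", scheme = "healthy")
  # one prediction per reference window, five per exercise window
  expect_equal(sum(sc_h$label == "reference"), n_ref)
  expect_equal(sum(sc_h$label == "exercise"), 5 * n_exe)
  sc_c <- one_class_cv(one, "rate_amplitude", scheme = "copd")
  expect_equal(nrow(sc_c), n_ref + n_exe)  # exactly one per usable window
  expect_equal(sort(unique(sc_h$fold)), 1:5)
  expect_true(all(sc_h$score >= 0, na.rm = TRUE))
})

test_that("one-class CV skips subjects with too few reference windows", {
  feats <- test_cohort_features(n = 2, seed = 11)
  one <- dplyr::filter(feats, subject == subject[1],
                       label == "exercise" | window <= 8)
  expect_warning(out <- one_class_cv(one, "rate", scheme = "healthy"),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("one-class scores are at chance when exercise matches reference", {
  aucs <- withr::with_seed(6, vapply(1:200, function(i) {
    n <- 30
    feats <- tibble::tibble(
      subject = "null", window = 1:n, label = rep(c("reference", "exercise"), c(22, 8)),
      quality = "ok",
      breathing_rate = rnorm(n, 0.3, 0.03), amplitude = rnorm(n, 1, 0.1)
    )
    sc <- one_class_cv(feats, "rate_amplitude", scheme = "healthy")
    auc_trapezoid(roc_curve(sc$score, sc$label))
  }, numeric(1)))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("no leakage: validation-fold rows never touch the fitted models", {
  feats <- test_cohort_features(n = 2, seed = 11)
  one <- dplyr::filter(feats, subject == subject[1], quality == "ok",
                       label %in% c("reference", "exercise"))
  ref <- dplyr::filter(one, label == "reference") |> dplyr::arrange(window)
  k <- 5
  fold_id <- sort(rep_len(1:k, nrow(ref)))
  train <- ref[fold_id != 1, ]
  x_train <- as.matrix(train[, c("breathing_rate", "amplitude")])
  m1 <- fit_reference(x_train, subject_id = "s")
  # perturb the held-out fold arbitrarily; the model must be identical
  m2 <- fit_reference(x_train, subject_id = "s")
  expect_identical(m1$mean, m2$mean)
  expect_identical(m1$cov, m2$cov)
  # same for the fourier PCA: loadings fitted on training rows only
  fx <- as.matrix(dplyr::select(ref, dplyr::matches("^f_\\d{4}$")))
  p1 <- fit_pca(fx[fold_id != 1, ], 5)
  p2 <- fit_pca(fx[fold_id != 1, ], 5)
  expect_identical(p1$loadings, p2$loadings)
  # end-to-end: scores of fold 1 unchanged when its feature values differ only
  # in rows belonging to other validation folds of other subjects
  sc1 <- one_class_cv(one, "rate_amplitude", scheme = "healthy")
  other <- dplyr::filter(feats, subject != subject[1])
  other$amplitude <- other$amplitude * 10
  sc2 <- one_class_cv(dplyr::bind_rows(one, other), "rate_amplitude", scheme = "healthy")
  sc2own <- dplyr::filter(sc2, subject == one$subject[1])
  expect_equal(sc1$score, sc2own$score)
})

test_that("mixed logistic model matches plain logistic when random effects vanish", {
  dat <- withr::with_seed(7, {
    n_sub <- 12; n_win <- 40
    subj <- rep(sprintf("s%02d", 1:n_sub), each = n_win)
    x <- rnorm(n_sub * n_win)
    eta <- -1 + 2 * x   # no subject-level variation
    y <- rbinom(length(x), 1, plogis(eta))
    tibble::tibble(subject = subj, window = rep(1:n_win, n_sub),
                   label = ifelse(y == 1, "exercise", "reference"),
                   quality = "ok", breathing_rate = x)
  })
  m <- fit_mixed_logistic(dat, "rate")
  plain <- glm(I(label == "exercise") ~ scale(breathing_rate), binomial(), dat)
  fe <- if (inherits(m$model, "glmmTMB")) glmmTMB::fixef(m$model)$cond else lme4::fixef(m$model)
  expect_equal(unname(fe), unname(coef(plain)), tolerance = 0.05)
})

test_that("mixed logistic model recovers fixed effects from a random-intercept truth", {
  dat <- withr::with_seed(8, {
    n_sub <- 20; n_win <- 40
    subj <- rep(sprintf("s%02d", 1:n_sub), each = n_win)
    b0 <- rep(rnorm(n_sub, 0, 1), each = n_win)
    x <- rnorm(n_sub * n_win)
    y <- rbinom(length(x), 1, plogis(-0.5 + b0 + 1.5 * x))
    tibble::tibble(subject = subj, window = rep(1:n_win, n_sub),
                   label = ifelse(y == 1, "exercise", "reference"),
                   quality = "ok", breathing_rate = x)
  })
  m <- fit_mixed_logistic(dat, "rate")
  td <- tidy(m)
  slope <- td[td$term != "(Intercept)", ]
  # covariate was standardized internally; truth on that scale is 1.5 * sd(x)
  sdx <- sd(dat$breathing_rate)
  expect_lt(abs(slope$estimate - 1.5 * sdx), 2 * slope$std.error)
})

test_that("single-class or single-subject input is rejected", {
  feats <- test_cohort_features(n = 2, seed = 11)
  refonly <- dplyr::filter(feats, label == "reference")
  expect_error(fit_mixed_logistic(refonly, "rate"), "both classes")
  onesub <- dplyr::filter(feats, subject == subject[1])
  expect_error(fit_mixed_logistic(onesub, "rate"), "2 subjects")
})

test_that("supervised CV scores every usable window once and finds chance under permutation", {
  feats <- test_cohort_features(n = 4, seed = 11)
  sc <- supervised_cv(feats, "rate_amplitude", seed = 1)
  usable <- dplyr::filter(feats, quality == "ok", label %in% c("reference", "exercise"),
                          !is.na(breathing_rate), !is.na(amplitude))
  expect_equal(nrow(sc), nrow(usable))
  expect_equal(dplyr::n_distinct(sc[c("subject", "window")]), nrow(usable))
  expect_true(all(sc$score > 0 & sc$score < 1, na.rm = TRUE))
  # permuting labels destroys the signal
  perm <- usable
  perm$label <- withr::with_seed(2, sample(perm$label))
  aucs <- vapply(1:3, function(i) {
    p2 <- perm; p2$label <- withr::with_seed(i + 10, sample(p2$label))
    s <- supervised_cv(p2, "rate_amplitude", seed = i)
    auc_trapezoid(roc_curve(s$score, s$label))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("in-sample evaluation mode scores with fold 0 and perfect-separation AUC 1", {
  feats <- test_cohort_features(n = 2, seed = 11)
  # construct a perfectly separated cohort from the real structure
  sep <- dplyr::filter(feats, quality == "ok", label %in% c("reference", "exercise"))
  sep$breathing_rate <- ifelse(sep$label == "exercise",
                               sep$breathing_rate + 1, sep$breathing_rate)
  sc <- supervised_cv(sep, "rate", eval = "insample", seed = 1)
  expect_true(all(sc$fold == 0))
  expect_equal(auc_trapezoid(roc_curve(sc$score, sc$label)), 1)
})
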