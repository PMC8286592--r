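# Shared fixtures and independent oracles for the test suite.

# A clean deterministic profile: no noise, no jitter, no drift.
clean_profile <- function(rest_rate = 20, seed = 1L, ...) {
  subject_profile("clean", rest_rate = rest_rate, noise_sd = 0,
                  breath_length_cv = 0, amplitude_cv = 0,
                  baseline_drift_amplitude = 0, seed = seed, ...)
}

# Small realistic cohort used by several classification tests (cached).
.test_cohort_env <- new.env()
test_cohort_features <- function(n = 6, seed = 11) {
  key <- sprintf("c_%d_%d", n, seed)
  if (is.null(.test_cohort_env[[key]])) {
    cohort <- simulate_cohort(n_healthy = n, n_copd = 0, seed = seed)
    .test_cohort_env[[key]] <- extract_cohort_features(cohort)
  }
  .test_cohort_env[[key]]
}

# Oracle: Mann-Whitney pair counting with ties scored 1/2.
mann_whitney_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Oracle: DeLong variance of the AUC from its structural components.
delong_ci_oracle <- function(scores, pos, conf = 0.95) {
  x <- scores[pos]; y <- scores[!pos]   # x: positives, y: negatives
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
  v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
  auc <- mean(v10)
  s10 <- sum((v10 - auc)^2) / (m - 1)
  s01 <- sum((v01 - auc)^2) / (n - 1)
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ci = c(auc - z * se, auc + z * se), se = se)
}

# Oracle: direct numerical evaluation of the Fourier coefficient integral
# c_n = (1/T) * sum f(t_j) exp(-i n (2 pi / T) t_j) dt  on the sample grid.
fourier_integral_oracle <- function(f, sampling_rate, bins) {
  n <- length(f)
  T_s <- n / sampling_rate
  tt <- (seq_len(n) - 1) / sampling_rate
  vapply(bins, function(k) Mod(sum(f * exp(-1i * k * 2 * pi / T_s * tt)) / n),
         numeric(1))
}

# Simulate the ARIMA(1,1,1) prediction equation literally:
# y_t = mu + y_(t-1) + Phi (y_(t-1) - y_(t-2)) - theta e_(t-1) + e_t
simulate_arima111 <- function(n, mu, phi, theta, sd = 1, burn = 100) {
  ntot <- n + burn
  e <- stats::rnorm(ntot, 0, sd)
  y <- numeric(ntot)
  y[1] <- 0; y[2] <- mu + y[1] + e[2]
  for (t in 3:ntot) {
    y[t] <- mu + y[t - 1] + phi * (y[t - 1] - y[t - 2]) - theta * e[t - 1] + e[t]
  }
  y[(burn + 1):ntot]
}
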