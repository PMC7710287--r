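# Short-time-series screening primitives: first-order differencing, an
# augmented Dickey-Fuller stationarity check, the lag-limited
# cross-correlation function with overlap-Pearson coefficients, nominal
# p-values, an autocorrelation (periodicity) check, and Benjamini-Hochberg
# FDR over a family of coefficients.

#' First-order difference of a series
#'
#' Each point is replaced by its change from the preceding point, removing
#' linear trends so that cross-correlations are computed on (approximately)
#' stationary series.
#'
#' @param series Numeric series, length >= 2, no missing values.
#' @return Numeric vector of length `length(series) - 1`.
#' @export
first_difference <- function(series) {
  if (length(series) < 2L) stop("series must have length >= 2")
  if (anyNA(series)) stop("missing values: difference undefined")
  diff(series)
}

# Dickey-Fuller t-statistic percentiles for the drift (constant, no trend)
# regression; rows are sample sizes, columns lower/upper tail probabilities.
# Interpolated bilinearly, as unit-root packages conventionally do.
.adf_table_n <- c(25, 50, 100, 250, 500, 1e5)
.adf_table_p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_table <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37,  0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60),
  nrow = 6, byrow = TRUE)

#' Augmented Dickey-Fuller test for a unit root (drift regression)
#'
#' Fits the OLS regression of the differenced series on an intercept, the
#' lagged level, and `max_lag` lagged differences; the statistic is the
#' t-ratio of the lagged-level coefficient, compared with small-sample
#' Dickey-Fuller critical values for the drift case. Rejection (small p)
#' supports stationarity. The default lag order is 0 for short series
#' (length <= 15, i.e. differenced length <= 14); the Schwert rule
#' `trunc(4 * (n/100)^(1/4))` engages for longer ones, since a dozen points
#' cannot support lagged augmentation.
#'
#' @param series Numeric series, nonconstant, no missing values.
#' @param max_lag Number of lagged-difference terms; `NULL` for the default
#'   above.
#' @param alpha Level for the reported stationarity decision.
#' @return List with `statistic`, `p_value` (clamped to the tabulated range
#'   0.01-0.99), `lag`, `n_regression`, and logical `stationary`.
#' @export
adf_stationarity_test <- function(series, max_lag = NULL, alpha = 0.05) {
  if (anyNA(series)) stop("missing values not allowed")
  n <- length(series)
  if (stats::sd(series) == 0) {
    stop("constant series: the unit-root question is degenerate")
  }
  if (is.null(max_lag)) {
    max_lag <- if (n - 1L <= 14L) 0L else trunc(4 * ((n - 1) / 100)^0.25)
  }
  max_lag <- as.integer(max_lag)
  if (n < max_lag + 4L) stop("series too short for lag order ", max_lag)
  dy <- diff(series)
  m <- length(dy)
  idx <- seq(max_lag + 1L, m)          # usable rows
  resp <- dy[idx]
  X <- cbind(1, series[idx])           # intercept, lagged level y_{t-1}
  if (max_lag > 0L) {
    for (j in seq_len(max_lag)) X <- cbind(X, dy[idx - j])
  }
  fit <- stats::lm.fit(X, resp)
  k <- ncol(X)
  rss <- sum(fit$residuals^2)
  dof <- length(resp) - k
  if (dof <= 0) stop("not enough observations for the ADF regression")
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  se <- sqrt(rss / dof * xtx_inv[2L, 2L])
  stat <- fit$coefficients[2L] / se
  # bilinear interpolation: first in sample size, then in tail probability
  crit <- apply(.adf_table, 2, function(col) {
    stats::approx(.adf_table_n, col, xout = min(n, 1e5), rule = 2)$y
  })
  p <- stats::approx(crit, .adf_table_p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lag = max_lag,
       n_regression = length(resp), stationary = p < alpha)
}

#' Lag-limited cross-correlation of two series
#'
#' For each lag `k` in `-max_lag..max_lag` the coefficient is the Pearson
#' correlation over the aligned overlapping pairs `(x_t, y_{t+k})`; a
#' positive lag therefore means events in `y` follow events in `x`. The
#' number of overlapping pairs is `n - |k|`. A zero-variance overlap yields
#' an `NA` coefficient (flagged undefined, never fabricated). The
#' `stationary = TRUE` variant divides by the full-series variance and `n`
#' (the classical stationary-process estimator, as in [stats::ccf()]) and is
#' provided for cross-checking only.
#'
#' @param x,y Numeric series of equal length `n`, `n - max_lag >= 3`.
#' @param max_lag Largest |lag| considered.
#' @param stationary Use the denominator-`n` estimator instead of the
#'   overlap-Pearson one.
#' @return Data.frame with columns `lag, coefficient, n_effective`.
#' @export
cross_correlation <- function(x, y, max_lag = 2L, stationary = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (n - max_lag < 3L) stop("need n - max_lag >= 3")
  lags <- seq(-max_lag, max_lag)
  coefs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k >= 0) {
      xs <- x[seq_len(n - k)]
      ys <- y[seq_len(n - k) + k]
    } else {
      xs <- x[seq_len(n + k) - k]
      ys <- y[seq_len(n + k)]
    }
    if (stationary) {
      coefs[i] <- sum((xs - mean(x)) * (ys - mean(y))) /
        (n * stats::sd(x) * stats::sd(y) * (n - 1) / n)
    } else {
      coefs[i] <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
      else stats::cor(xs, ys)
    }
  }
  data.frame(lag = lags, coefficient = coefs, n_effective = n - abs(lags))
}

#' Nominal two-sided p-value for a cross-correlation coefficient
#'
#' Standard Pearson theory on the overlap: `t = r * sqrt((m-2)/(1-r^2))`
#' referred to the t distribution with `m - 2` degrees of freedom, where `m`
#' is the number of overlapping pairs. `|r| = 1` gives p = 0; an undefined
#' coefficient or `m < 4` gives `NA`.
#'
#' @param coefficient Correlation in [-1, 1] (or `NA`).
#' @param n_effective Number of overlapping pairs.
#' @return Two-sided p-value (vectorised).
#' @export
ccf_pvalue <- function(coefficient, n_effective) {
  r <- coefficient
  m <- n_effective
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & m >= 4
  exact1 <- ok & abs(r) >= 1
  p[exact1] <- 0
  mid <- ok & !exact1
  tstat <- r[mid] * sqrt((m[mid] - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), m[mid] - 2)
  p
}

#' Autocorrelation (periodicity) check
#'
#' Sample autocorrelations at lags `1..max_lag` (lag 0 is 1 by definition)
#' with the white-noise bound `1.96 / sqrt(n)`; the periodicity flag is
#' raised when any lag exceeds the bound in absolute value.
#'
#' @param series Numeric series, nonconstant, length >= max_lag + 3.
#' @param max_lag Largest lag examined.
#' @return List with `acf` (lags 0..max_lag), `bound`, `flagged_lags`, and
#'   logical `periodicity`.
#' @export
autocorrelation_check <- function(series, max_lag = 2L) {
  n <- length(series)
  if (anyNA(series)) stop("missing values not allowed")
  if (n < max_lag + 3L) stop("series too short for max_lag = ", max_lag)
  xc <- series - mean(series)
  denom <- sum(xc^2)
  if (denom == 0) stop("constant series: ACF undefined")
  rho <- vapply(seq_len(max_lag), function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, 1)
  bound <- 1.96 / sqrt(n)
  flagged <- which(abs(rho) > bound)
  list(acf = c(1, rho), bound = bound, flagged_lags = flagged,
       periodicity = length(flagged) > 0L)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up rule at level `alpha` over the supplied family: with order
#' statistics `p_(1) <= ... <= p_(m)`, reject all `p_(i)` with
#' `i <= k* = max{i : p_(i) <= i * alpha / m}`. The q-values are the usual
#' monotone BH-adjusted p-values (via [stats::p.adjust()]), so rejection is
#' equivalently `q <= alpha`. `NA` entries are carried through unrejected.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NA allowed).
#' @param alpha FDR level.
#' @return List with `q_values` and logical `reject`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) {
    return(list(q_values = numeric(0), reject = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= alpha)
}
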