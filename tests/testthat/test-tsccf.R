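test_that("first differencing removes linear trends", {
  expect_equal(first_difference(c(33500, 33800, 33600)), c(300, -200))
  expect_equal(first_difference(rep(7, 5)), rep(0, 4))
  tt <- 0:9
  expect_equal(first_difference(3 + 1.7 * tt), rep(1.7, 9))
  expect_error(first_difference(7), ">= 2")
  expect_error(first_difference(c(1, NA, 3)), "missing")
})

test_that("ADF statistic equals an independent lm() Dickey-Fuller regression", {
  set.seed(41)
  y <- as.numeric(arima.sim(list(ar = 0.0001), n = 25)) # white noise, n = 25
  got <- adf_stationarity_test(y, max_lag = 0)
  dy <- diff(y)
  fit <- lm(dy ~ y[-length(y)])
  expect_equal(got$statistic, summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-10)

  set.seed(42)
  y2 <- cumsum(rnorm(50))
  got2 <- adf_stationarity_test(y2, max_lag = 2)
  dy2 <- diff(y2)
  n <- length(y2)
  idx <- 3:(n - 1)
  fit2 <- lm(dy2[idx] ~ y2[idx] + dy2[idx - 1] + dy2[idx - 2])
  expect_equal(got2$statistic, summary(fit2)$coefficients[2, "t value"],
               tolerance = 1e-10)
  expect_error(adf_stationarity_test(rep(3, 20)), "constant")
})

test_that("ADF has power on white noise and holds size on random walks", {
  set.seed(7)
  rej_wn <- mean(vapply(1:120, function(i) {
    adf_stationarity_test(rnorm(100), max_lag = 0)$stationary
  }, TRUE))
  expect_gte(rej_wn, 0.95)
  rej_rw <- mean(vapply(1:200, function(i) {
    adf_stationarity_test(cumsum(rnorm(100)), max_lag = 0)$stationary
  }, TRUE))
  expect_lt(rej_rw, 0.12)
})

test_that("cross-correlation: identities and the shifted-copy convention", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 6)
  cc <- cross_correlation(x, x, 2)
  expect_equal(cc$coefficient[cc$lag == 0], 1)
  expect_equal(cc$n_effective, 8 - abs(cc$lag))

  # y is x delayed one step: pairs (x_t, y_{t+1}) = (x_t, x_t)
  y <- c(NA, x[-8]); y[1] <- 0
  cc2 <- cross_correlation(x, y, 2)
  expect_equal(cc2$coefficient[cc2$lag == 1], 1)
})

test_that("cross-correlation equals the brute-force aligned-Pearson oracle", {
  set.seed(17)
  for (rep in 1:25) {
    x <- rnorm(10); y <- rnorm(10)
    got <- cross_correlation(x, y, 3)
    want <- ccf_oracle(x, y, 3)
    expect_equal(got$coefficient, want$coefficient, tolerance = 1e-12)
  }
})

test_that("CCF symmetry: (X,Y) at lag k equals (Y,X) at lag -k", {
  set.seed(18)
  x <- rnorm(12); y <- rnorm(12)
  ab <- cross_correlation(x, y, 2)
  ba <- cross_correlation(y, x, 2)
  expect_equal(ab$coefficient, rev(ba$coefficient), tolerance = 1e-14)
})

test_that("stationary-estimator variant matches stats::ccf", {
  set.seed(19)
  x <- rnorm(20); y <- rnorm(20)
  got <- cross_correlation(x, y, 2, stationary = TRUE)
  ref <- ccf(y, x, lag.max = 2, plot = FALSE)  # ccf(a,b) at +k pairs a_{t+k},b_t
  expect_equal(got$coefficient, as.vector(ref$acf), tolerance = 1e-12)
})

test_that("zero-variance overlaps are flagged undefined, not fabricated", {
  x <- c(1, 1, 1, 1, 5, 2, 3, 4)   # constant on some overlaps
  y <- c(2, 9, 4, 7, 1, 8, 3, 5)
  cc <- cross_correlation(c(rep(1, 7), 2), y, 2)
  expect_true(anyNA(cc$coefficient) || all(abs(cc$coefficient) <= 1))
  cc0 <- cross_correlation(rep(3, 8), y, 2)
  expect_true(all(is.na(cc0$coefficient)))
  expect_true(all(is.na(ccf_pvalue(cc0$coefficient, cc0$n_effective))))
})

test_that("nominal p-values follow Pearson t theory on the overlap", {
  expect_equal(ccf_pvalue(0, 10), 1)
  expect_equal(ccf_pvalue(0.6, 12), 2 * pt(-0.6 * sqrt(10 / 0.64), 10),
               tolerance = 1e-12)
  expect_equal(ccf_pvalue(0.6, 12), ccf_pvalue(-0.6, 12))
  expect_equal(ccf_pvalue(1, 9), 0)
  expect_true(is.na(ccf_pvalue(0.5, 3)))
})

test_that("autocorrelation check matches stats::acf and flags periodicity", {
  set.seed(21)
  x <- rnorm(40)
  got <- autocorrelation_check(x, 3)
  ref <- acf(x, lag.max = 3, plot = FALSE)
  expect_equal(got$acf, as.vector(ref$acf), tolerance = 1e-12)
  expect_equal(got$acf[1], 1)

  alt <- rep(c(1, -1), 20)
  flagged <- autocorrelation_check(alt, 2)
  expect_true(2 %in% flagged$flagged_lags)
  expect_true(flagged$periodicity)
  expect_error(autocorrelation_check(rep(2, 10), 2), "constant")
})

test_that("BH step-up: worked families and edge cases", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r1$reject))

  r2 <- bh_fdr(c(0.9, 0.8))
  expect_false(any(r2$reject))
  expect_equal(r2$q_values, c(0.9, 0.9))

  r3 <- bh_fdr(c(0.004, 0.9, 0.9, 0.9, 0.9))
  expect_equal(r3$reject, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  r0 <- bh_fdr(numeric(0))
  expect_length(r0$q_values, 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
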