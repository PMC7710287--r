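# Independent brute-force oracles. Each reimplements the checked quantity by
# direct enumeration or explicit arithmetic, never by calling the package
# code path it verifies.

# Pearson correlation from the definition (no stats::cor)
pearson_by_hand <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# cross-correlation by explicit index loops over the overlap
ccf_oracle <- function(x, y, max_lag) {
  n <- length(x)
  out <- data.frame(lag = integer(0), coefficient = numeric(0))
  for (k in seq(-max_lag, max_lag)) {
    a <- c(); b <- c()
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) {
        a <- c(a, x[t]); b <- c(b, y[t + k])
      }
    }
    r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else pearson_by_hand(a, b)
    out <- rbind(out, data.frame(lag = k, coefficient = r))
  }
  out
}

# exact signed-rank p by enumerating every sign assignment (n <= ~14)
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# exact Mann-Whitney p by enumerating every group assignment (no ties)
mann_whitney_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  u_all <- apply(combs, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact Spearman p by looping over all permutations, cor() per permutation
spearman_oracle <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(rank(x), rank(y))
  perm_recurse <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_recurse(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perm_recurse(y), function(yp) cor(rank(x), rank(yp)), 1)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# sustained-contraction status by checking every window of the trace
contraction_oracle <- function(pct, threshold, min_duration = 2L) {
  n <- length(pct)
  d <- diff(pct)
  for (t0 in seq_len(n - 1L)) {
    if (t0 + min_duration > n) break
    for (t1 in seq(t0 + min_duration, n)) {
      if (all(d[t0:(t1 - 1L)] <= 0) && pct[t0] - pct[t1] > threshold) {
        return("contracting")
      }
    }
  }
  "noncontracting"
}
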