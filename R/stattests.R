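# Group-contrast tests used throughout the cohort analyses. Ordinary fits go
# through stats (t.test, chisq.test, lm); the rank tests are implemented here
# because their contracts require exact permutation p-values that remain
# exact under tied ranks, which stats::wilcox.test does not provide.

# all permutations of 1..n as an (n! x n) matrix; used only for small n
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# exact null distribution of the doubled signed-rank statistic under sign
# flips: counts over support 0..sum(r2), by polynomial convolution
signed_rank_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (with an error when none remain). For up to
#' 25 nonzero pairs the two-sided p-value is the exact sign-permutation
#' probability, computed on the tied-rank statistic itself, so it stays exact
#' under ties; beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Paired numeric vectors; alternatively pass the differences as
#'   `x` and leave `y = NULL`.
#' @param exact_max Largest n for which the exact distribution is enumerated.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`, `n`
#'   (nonzero pairs), and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(r2)
    total <- sum(r2)
    w2 <- round(2 * V)
    dev <- abs(seq(0, total) - total / 2)
    p <- sum(counts[dev >= abs(w2 - total / 2) - 1e-9]) / 2^n
    method <- "exact sign permutation"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, n_zero_dropped = n_zero,
       method = method)
}

#' Mann-Whitney U test for two independent samples
#'
#' Exact two-sided p (via the null U distribution) when both groups have at
#' most `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Per-group size limit for the exact distribution.
#' @return List with `statistic` (U of the first sample), `p_value`, and
#'   `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 10L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && na <= exact_max && nb <= exact_max) {
    p <- if (U > mu) {
      2 * (1 - stats::pwilcox(U - 1, na, nb))
    } else {
      2 * stats::pwilcox(U, na, nb)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- na + nb
    ties <- table(r)
    sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) stop("degenerate samples: all values tied")
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Pooled-variance two-sample t test
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return List with `statistic` (t), `df` (nA + nB - 2), `p_value`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Spearman rank correlation with a tie-aware exact permutation p-value
#'
#' rho is the Pearson correlation of average ranks. For n <= `exact_max` the
#' two-sided p enumerates all n! permutations of one argument's ranks (valid
#' with or without ties); beyond that the usual t approximation on rho with
#' n - 2 degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @param exact_max Largest n for full enumeration (8! = 40320 permutations).
#' @return List with `rho`, `p_value`, and `method`.
#' @export
spearman <- function(x, y, exact_max = 8L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    P <- all_permutations(n)
    ry_perm <- matrix(ry[P], nrow(P), n)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2) * sum((ry - mean(ry))^2))
    rho_perm <- as.vector(ry_perm %*% cx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects ANOVA: the ratio of between-group to within-group
#' mean squares, referred to the F distribution.
#'
#' @param groups List of numeric samples, each with n >= 2.
#' @return List with `statistic` (F), `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, function(g) sum(!is.na(g)), 1L) < 2L)) {
    stop("each group needs n >= 2")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  at <- stats::anova(stats::lm(y ~ g))
  list(statistic = at$`F value`[1L], df_between = at$Df[1L],
       df_within = at$Df[2L], p_value = at$`Pr(>F)`[1L])
}
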