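# Independent statistical oracles, written from first principles so the
# package's estimator and test wrappers can be checked against them.

# OLS of y on x via the normal equations, with slope SE and two-sided
# t-test p-value.
ols_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  cov_beta <- s2 * solve(XtX)
  se <- unname(sqrt(diag(cov_beta)))
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_intercept = se[1], se_slope = se[2],
       p_slope = unname(p[2]))
}

# Welch's t statistic, Welch-Satterthwaite df and two-sided p from the
# textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df = df)
  list(t = t_stat, df = df, p = p)
}

# Exact two-sided rank-sum p-value for small untied samples by full
# enumeration of group assignments.
rank_sum_exact_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n)])
  combos <- utils::combn(n + m, n)
  all_ranks <- rank(c(a, b))  # tied data would need mid-ranks; assume none
  w_all <- apply(combos, 2, function(idx) sum(all_ranks[idx]))
  # two-sided: double the smaller tail (the symmetric-null convention)
  mu <- n * (n + m + 1) / 2
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Kruskal-Wallis H with ties correction from the defining formula.
kruskal_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  df <- length(groups) - 1
  list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

# Convenience: a small exact linear dilution fixture k = mu - m * D.
linear_dilution_points <- function(mu = 1, m = 5,
                                   fractions = c(1, 0.8, 0.4, 0.2),
                                   replicates = 3) {
  d <- rep(fractions, each = replicates)
  data.frame(fraction_wsw = d, k = mu - m * d,
             replicate = rep(seq_len(replicates), length(fractions)))
}
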