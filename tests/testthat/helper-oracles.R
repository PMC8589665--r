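# From-scratch statistical oracles, independent of the implementation paths
# they check: explicit moment formulas, trapezoidal integration of the t
# density, and bisection on the normal CDF.

oracle_t_pdf <- function(t, df) {
  exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
    (1 + t^2 / df)^(-(df + 1) / 2)
}

# Central-t CDF by trapezoidal integration from 0 to |q|.
oracle_t_cdf <- function(q, df, n_grid = 200001L) {
  if (q == 0) return(0.5)
  a <- abs(q)
  xs <- seq(0, a, length.out = n_grid)
  ys <- oracle_t_pdf(xs, df)
  area <- sum((ys[-1] + ys[-n_grid]) / 2) * (a / (n_grid - 1))
  if (q > 0) 0.5 + area else 0.5 - area
}

# Standard-normal quantile by bisection on pnorm.
oracle_norm_quantile <- function(p) {
  lo <- -10
  hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_t_to_z <- function(t, df) oracle_norm_quantile(oracle_t_cdf(t, df))

oracle_pearson_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_pearson_p <- function(x, y, direction = "positive") {
  r <- oracle_pearson_r(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  if (direction == "positive") 1 - oracle_t_cdf(tt, n - 2) else oracle_t_cdf(tt, n - 2)
}

# Average ranks with ties, written out longhand.
oracle_rank <- function(x) {
  sapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  })
}

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  tt <- md / (sd_d / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * (1 - oracle_t_cdf(abs(tt), n - 1)))
}

oracle_two_sample <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  m1 <- sum(x1) / n1
  m2 <- sum(x2) / n2
  v1 <- sum((x1 - m1)^2) / (n1 - 1)
  v2 <- sum((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- (m1 - m2) / sqrt(sp2)
  list(t = tt, df = df, p = 2 * (1 - oracle_t_cdf(abs(tt), df)),
       cohen_d = d, hedges_d = d * (1 - 3 / (4 * df - 1)))
}

# Gaussian log-likelihood and AIC from the explicit closed form.
oracle_gaussian_aic <- function(x, mu, s2, n_params = 2) {
  n <- length(x)
  ll <- -n / 2 * log(2 * pi * s2) - sum((x - mu)^2) / (2 * s2)
  2 * n_params - 2 * ll
}
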