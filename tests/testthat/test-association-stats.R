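test_that("one-tailed Pearson p-values follow the directional tail", {
  x <- 1:10
  r1 <- pearson_one_tailed(x, x + 0)
  expect_equal(r1$r, 1)
  expect_equal(r1$p_one_tailed, 0)

  r2 <- pearson_one_tailed(x, -x, direction = "positive")
  expect_equal(r2$r, -1)
  expect_equal(r2$p_one_tailed, 1)

  expect_error(pearson_one_tailed(rep(1, 5), 1:5), "constant")
})

test_that("Pearson r and p match the brute-force oracle on toy vectors", {
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 2.9)
  y <- c(1.0, 2.2, 1.5, 4.9, 3.1, 2.0)
  for (dir in c("positive", "negative")) {
    res <- pearson_one_tailed(x, y, dir)
    expect_equal(res$r, oracle_pearson_r(x, y), tolerance = 1e-10)
    expect_equal(res$p_one_tailed, oracle_pearson_p(x, y, dir),
                 tolerance = 1e-8)
  }
  # cross-check against the reference implementation too
  ct <- cor.test(x, y, alternative = "greater")
  res <- pearson_one_tailed(x, y, "positive")
  expect_equal(res$p_one_tailed, unname(ct$p.value), tolerance = 1e-12)
})

test_that("one-tailed p relates to the two-tailed p through the observed sign", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12) + 0.4 * x
    p2 <- cor.test(x, y)$p.value
    res <- pearson_one_tailed(x, y, "positive")
    if (res$r > 0) {
      expect_equal(res$p_one_tailed, p2 / 2, tolerance = 1e-10)
    } else {
      expect_equal(res$p_one_tailed, 1 - p2 / 2, tolerance = 1e-10)
    }
  }
})

test_that("Spearman check is rank-invariant and handles ties by average rank", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_check(x, exp(x))$r, 1)

  xt <- c(1, 2, 2, 3, 4)
  yt <- c(2, 1, 3, 3, 5)
  res <- spearman_check(xt, yt)
  expect_equal(res$r, oracle_pearson_r(oracle_rank(xt), oracle_rank(yt)),
               tolerance = 1e-10)
  expect_error(spearman_check(rep(2, 5), 1:5), "constant")
})

test_that("the 2-SD outlier trigger uses the sample SD", {
  # {0,0,0,10}: mean 2.5, SD 5, max |z| = 1.5 -> no outlier
  expect_false(needs_nonparametric(c(0, 0, 0, 10)))
  # one 10 among nine 0s: z = 9/sqrt(10) = 2.85 -> outlier
  expect_true(needs_nonparametric(c(rep(0, 9), 10)))
  expect_false(needs_nonparametric(c(1, 2, 3, 4, 5)))
  expect_false(needs_nonparametric(rep(3, 3)))  # zero SD: none by convention
})

test_that("stepwise selection finds the single true predictor", {
  set.seed(14)
  n <- 20
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.3)
  res <- stepwise_regress(y, data.frame(re = x1, avoid = x2, hyper = x3))
  expect_equal(res$selected, "re")
  expect_gt(res$r_squared, 0.9)
  # every candidate carries a reported beta (unselected ones added singly)
  expect_true(all(is.finite(res$coefficients$beta)))
  expect_equal(res$df[1], 1)
  expect_equal(res$df[2], n - 2)
})

test_that("stepwise selects nothing on pure noise and errors when n is too small", {
  set.seed(8)
  n <- 20
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  res <- stepwise_regress(rnorm(n), cand)
  expect_length(res$selected, 0)
  expect_true(is.na(res$model_p))
  expect_equal(res$r_squared, 0)
  expect_error(stepwise_regress(rnorm(4), cand[1:4, ]), "candidates")
  expect_error(stepwise_regress(rnorm(n), cbind(cand, d = cand$a)), "rank")
})

test_that("single-candidate stepwise reduces to the standardized simple regression", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- 0.8 * x + rnorm(15)
    res <- stepwise_regress(y, data.frame(x = x), p_enter = 1 - 1e-12)
    expect_equal(res$coefficients$beta[1], cor(x, y), tolerance = 1e-10)
  }
})

test_that("null stepwise selection rate is liberal but bounded", {
  # family-wise selection rate of forward selection on pure noise,
  # 3 candidates, n = 20: documented to land between alpha and ~3*alpha*k
  selected <- vapply(1:1000, function(s) {
    dat <- withr::with_seed(s, matrix(rnorm(20 * 4), 20))
    res <- stepwise_regress(dat[, 1], as.data.frame(dat[, 2:4]))
    length(res$selected) > 0
  }, logical(1))
  rate <- mean(selected)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.25)
})

test_that("multicollinearity check reports pairwise r with two-tailed p", {
  set.seed(6)
  x <- rnorm(20)
  res <- multicollinearity_check(data.frame(a = x, b = x, c = rnorm(20)))
  expect_equal(res$r["a", "b"], 1)
  expect_equal(res$r, t(res$r))
  y <- rnorm(20)
  y_orth <- as.numeric(residuals(lm(y ~ x)))
  r2 <- multicollinearity_check(data.frame(a = x, b = y_orth))
  expect_lt(abs(r2$r["a", "b"]), 1e-10)
  ct <- cor.test(x, y)
  r3 <- multicollinearity_check(data.frame(a = x, b = y))
  expect_equal(r3$p["a", "b"], unname(ct$p.value), tolerance = 1e-10)
  expect_error(multicollinearity_check(data.frame(a = x)), "at least 2")
})

test_that("group comparison matches the pooled-variance hand computation", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$hedges_d, 0)

  res <- group_compare(c(1, 2, 3), c(2, 3, 4))
  # pooled variance 1, t = -1/sqrt(2/3), df = 4, J = 1 - 3/15 = 0.8
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$cohen_d, -1)
  expect_equal(res$hedges_d, -0.8)
  tt <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p, unname(tt$p.value), tolerance = 1e-12)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("required sample size follows the normal-approximation formula", {
  expect_equal(required_n_per_group(0.60), 44L)
  expect_equal(required_n_per_group(1.2), 11L)
  expect_error(required_n_per_group(0), "positive")
  # strictly decreasing in d, increasing in power
  d <- seq(0.2, 1.4, by = 0.2)
  ns <- vapply(d, required_n_per_group, integer(1))
  expect_true(all(diff(ns) < 0))
  pw <- c(0.5, 0.7, 0.8, 0.9, 0.99)
  np <- vapply(pw, function(p) required_n_per_group(0.6, power = p), integer(1))
  expect_true(all(diff(np) > 0))
})
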