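# Inferential statistics used throughout the pipeline: one-tailed
# correlations, outlier-triggered nonparametric checks, forward stepwise
# regression, multicollinearity, effect sizes, and sample-size planning.

check_xy <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (length(x) < 3) abort_validation("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_validation("non-finite values in x or y")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_validation("constant vector: correlation undefined")
  }
}

cor_one_tailed <- function(x, y, direction, method) {
  n <- length(x)
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    tv <- sign(r) * Inf
  } else {
    tv <- r * sqrt(df / (1 - r^2))
  }
  p <- if (direction == "positive") {
    stats::pt(tv, df, lower.tail = FALSE)
  } else {
    stats::pt(tv, df)
  }
  structure(list(r = r, p_one_tailed = p, n = n, df = df, t = tv,
                 direction = direction, method = method),
            class = "correlation_result")
}

#' One-tailed Pearson correlation
#'
#' Pearson correlation with a directional (one-tailed) p-value:
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` df, upper tail for `direction = "positive"`, lower tail for
#' `"negative"`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-constant).
#' @param direction Hypothesized sign of the association.
#' @return Object of class `"correlation_result"`: list with `r`,
#'   `p_one_tailed`, `n`, `df`, `t`, `direction`, `method`.
#' @export
pearson_one_tailed <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  check_xy(x, y)
  cor_one_tailed(x, y, direction, "pearson")
}

#' One-tailed Spearman rank correlation
#'
#' Nonparametric robustness companion to [pearson_one_tailed()]: both
#' vectors are rank-transformed (average ranks for ties) and the Pearson
#' machinery, including the one-tailed t-approximation for the p-value, is
#' applied to the ranks.
#'
#' @inheritParams pearson_one_tailed
#' @return Object of class `"correlation_result"` with `method = "spearman"`.
#' @export
spearman_check <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  check_xy(x, y)
  cor_one_tailed(rank(x), rank(y), direction, "spearman")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, one-tailed p = %.4f (%s direction, n = %d)\n",
              x$method, x$r, x$p_one_tailed, x$direction, x$n))
  invisible(x)
}

#' Does a variable contain 2-SD outliers?
#'
#' Returns `TRUE` when any value lies more than 2 sample standard
#' deviations from the sample mean, the trigger used to re-run an analysis
#' nonparametrically.  A zero-SD sample has no outliers by convention.
#'
#' @param values Numeric vector (n >= 3).
#' @return Logical scalar.
#' @export
needs_nonparametric <- function(values) {
  if (length(values) < 3) abort_validation("need at least 3 values")
  if (any(!is.finite(values))) abort_validation("non-finite values")
  s <- stats::sd(values)
  if (s == 0) return(FALSE)
  any(abs(values - mean(values)) > 2 * s)
}

#' Forward stepwise regression with backward pruning
#'
#' Automatic model selection over standardized candidate predictors: at
#' each step the candidate with the largest |t| whose p-value is below
#' `p_enter` joins the model; after each addition any included predictor
#' whose p-value exceeds `p_remove` is dropped (worst first); the procedure
#' stops when no change occurs.  All variables are standardized internally
#' so coefficients are reported as standardized betas.  For reporting, each
#' unselected candidate's beta is obtained by adding it alone to the final
#' selected model, which is how a single coefficient table can display both
#' selected and unselected predictors.
#'
#' @param y Response vector.
#' @param candidates Data frame (or named matrix) of candidate predictors.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return Object of class `"stepwise_result"`: list with `selected`
#'   (in entry order), `coefficients` (data frame: `term`, `beta`, `p`,
#'   `selected`), `r_squared`, `df` (model, residual), `model_p` (overall
#'   F-test; `NA` when nothing is selected), `p_enter`, `p_remove`, `n`.
#' @export
stepwise_regress <- function(y, candidates, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(candidates)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) abort_validation("y and candidates must have equal length")
  if (n <= k + 2) {
    abort_validation("need n > number of candidates + 2 (got n = ", n,
                     ", candidates = ", k, ")")
  }
  if (any(vapply(X, stats::sd, numeric(1)) == 0) || stats::sd(y) == 0) {
    abort_validation("constant response or candidate predictor")
  }
  if (qr(scale(as.matrix(X)))$rank < k) {
    abort_validation("rank-deficient candidate design")
  }
  ys <- as.numeric(scale(y))
  Xs <- as.data.frame(scale(as.matrix(X)))
  names(Xs) <- names(X)

  coef_p <- function(terms) {
    # standardized betas and p-values for `terms` fitted jointly
    fit <- stats::lm(ys ~ ., data = Xs[, terms, drop = FALSE])
    sm <- summary(fit)$coefficients
    sm[-1, c(1, 4), drop = FALSE]
  }

  selected <- character(0)
  repeat {
    changed <- FALSE
    remaining <- setdiff(names(Xs), selected)
    if (length(remaining) > 0) {
      stats_in <- t(vapply(remaining, function(cand) {
        fit <- stats::lm(ys ~ ., data = Xs[, c(selected, cand), drop = FALSE])
        sm <- summary(fit)$coefficients
        c(t = sm[cand, 3], p = sm[cand, 4])
      }, numeric(2)))
      best <- remaining[which.max(abs(stats_in[, "t"]))]
      if (stats_in[best, "p"] < p_enter) {
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    while (length(selected) > 0) {
      cp <- coef_p(selected)
      worst <- rownames(cp)[which.max(cp[, 2])]
      if (cp[worst, 2] > p_remove) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  tab <- data.frame(term = names(Xs), beta = NA_real_, p = NA_real_,
                    selected = names(Xs) %in% selected,
                    stringsAsFactors = FALSE)
  if (length(selected) > 0) {
    cp <- coef_p(selected)
    tab$beta[match(selected, tab$term)] <- cp[selected, 1]
    tab$p[match(selected, tab$term)] <- cp[selected, 2]
  }
  for (cand in setdiff(names(Xs), selected)) {
    cp <- coef_p(c(selected, cand))
    tab$beta[tab$term == cand] <- cp[cand, 1]
    tab$p[tab$term == cand] <- cp[cand, 2]
  }
  if (length(selected) > 0) {
    fit <- stats::lm(ys ~ ., data = Xs[, selected, drop = FALSE])
    sm <- summary(fit)
    fstat <- sm$fstatistic
    model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    r2 <- sm$r.squared
    dfs <- c(fstat[2], fstat[3])
  } else {
    model_p <- NA_real_
    r2 <- 0
    dfs <- c(0, n - 1)
  }
  structure(list(selected = selected, coefficients = tab, r_squared = r2,
                 df = unname(dfs), model_p = unname(model_p),
                 p_enter = p_enter, p_remove = p_remove, n = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  sel <- if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"
  cat(sprintf("Stepwise regression (n = %d): selected %s\n", x$n, sel))
  if (length(x$selected)) {
    cat(sprintf("  model r^2 = %.3f, df = %d, %d, p = %.4f\n",
                x$r_squared, x$df[1], x$df[2], x$model_p))
  }
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pairwise predictor intercorrelations
#'
#' Multicollinearity screen: symmetric matrix of pairwise Pearson
#' correlations among candidate predictors with two-tailed p-values.
#'
#' @param candidates Data frame of at least 2 non-constant predictors.
#' @return List with matrices `r` and `p` and the sample size `n`.
#' @export
multicollinearity_check <- function(candidates) {
  X <- as.data.frame(candidates)
  if (ncol(X) < 2) abort_validation("need at least 2 candidate predictors")
  if (any(vapply(X, stats::sd, numeric(1)) == 0)) {
    abort_validation("constant candidate predictor")
  }
  n <- nrow(X)
  r <- stats::cor(X)
  df <- n - 2
  tv <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tv), df)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Two-group comparison with Hedge's d
#'
#' Pooled-variance two-sample t-test (`df = n1 + n2 - 2`, two-tailed p)
#' with Cohen's d on the pooled SD and Hedge's small-sample correction
#' `J = 1 - 3 / (4 * df - 1)`.
#'
#' @param x1,x2 Numeric vectors, each with at least 2 values.
#' @param compute_required_n If `TRUE`, also report
#'   [required_n_per_group()] at `|hedges_d|`.
#' @return List with `t`, `df`, `p`, `cohen_d`, `hedges_d`, group means,
#'   and optionally `required_n_per_group`.
#' @export
group_compare <- function(x1, x2, compute_required_n = FALSE) {
  if (length(x1) < 2 || length(x2) < 2) {
    abort_validation("each group needs at least 2 observations")
  }
  if (any(!is.finite(c(x1, x2)))) abort_validation("non-finite values")
  n1 <- length(x1)
  n2 <- length(x2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / df
  dm <- mean(x1) - mean(x2)
  if (sp2 == 0) {
    tval <- if (dm == 0) 0 else sign(dm) * Inf
    d <- if (dm == 0) 0 else sign(dm) * Inf
  } else {
    tval <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- dm / sqrt(sp2)
  }
  J <- 1 - 3 / (4 * df - 1)
  res <- list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
              cohen_d = d, hedges_d = d * J,
              mean1 = mean(x1), mean2 = mean(x2), n1 = n1, n2 = n2)
  if (compute_required_n) {
    res$required_n_per_group <- required_n_per_group(abs(res$hedges_d))
  }
  res
}

#' Required per-group sample size for a two-sample t-test
#'
#' Normal-approximation sample-size formula
#' `ceil(2 * (z_(1 - alpha/2) + z_power)^2 / d^2)` for detecting a
#' standardized mean difference `d` between two equal groups.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer sample size per group.
#' @export
#' @examples
#' required_n_per_group(0.60)  # 44
required_n_per_group <- function(d, alpha = 0.05, power = 0.80) {
  if (!is_scalar_number(d) || d <= 0) abort_validation("d must be positive")
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort_validation("power must be in (0, 1)")
  as.integer(ceiling(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2))
}
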