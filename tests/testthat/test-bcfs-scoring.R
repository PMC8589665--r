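test_that("trial exclusion removes incorrect and 5-SD-outlier trials only", {
  clean <- make_session()
  res <- exclude_trials(clean)
  expect_equal(nrow(res$kept), 48)
  expect_equal(res$n_excluded, 0)

  # plant one trial 6 condition-SDs above the mean of its condition peers
  tr <- make_session(rts = {
    set.seed(1); 2500 + rnorm(48, 0, 100)
  })
  ang <- which(tr$expression == "angry")
  peers <- tr$rt_ms[ang[-1]]
  tr$rt_ms[ang[1]] <- mean(peers) + 6 * sd(peers)
  res <- exclude_trials(tr)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$report$reason, "outlier_above_5sd")
  expect_equal(res$report$rt_ms, mean(peers) + 6 * sd(peers))

  # an incorrect trial is excluded with its own reason
  tr2 <- make_session()
  tr2$correct[5] <- FALSE
  res2 <- exclude_trials(tr2)
  expect_equal(res2$report$reason, "incorrect")

  # one-sided rule: an extreme *fast* trial is kept
  tr3 <- make_session(rts = {set.seed(2); 2500 + rnorm(48, 0, 100)})
  tr3$rt_ms[1] <- tr3$rt_ms[1] - 2000
  tr3$rt_ms[1] <- max(tr3$rt_ms[1], 50)
  expect_equal(exclude_trials(tr3)$n_excluded, 0)
})

test_that("exclusion warns at 3% and errors with too few correct trials", {
  tr <- make_session()
  tr$correct[c(1, 7)] <- FALSE  # 2/48 = 4.2%
  expect_warning(exclude_trials(tr), "3%")
  tr2 <- make_session()
  tr2$correct[tr2$expression == "angry"] <- FALSE
  expect_error(suppressWarnings(exclude_trials(tr2)), "correct trials")
})

test_that("dyads pair angry and neutral trials by face and position", {
  full <- make_session()
  d <- build_dyads(full)
  expect_equal(nrow(d$dyads), 24)
  expect_equal(nrow(d$incomplete), 0)

  # dropping one angry trial loses exactly one dyad
  miss <- full[-which(full$expression == "angry")[1], ]
  d2 <- build_dyads(miss)
  expect_equal(nrow(d2$dyads), 23)
  expect_equal(nrow(d2$incomplete), 1)

  expect_equal(nrow(build_dyads(full[0, ])$dyads), 0)
  expect_error(build_dyads(rbind(full, full[1, ])), "duplicate")
})

test_that("dyad bias sign convention is configurable and consistent", {
  full <- make_session()
  tow <- build_dyads(full, "toward_positive")$dyads
  lit <- build_dyads(full, "angry_minus_neutral")$dyads
  expect_equal(tow$bias, tow$rt_neutral - tow$rt_angry)
  expect_equal(lit$bias, -tow$bias)
})

test_that("bias summary decomposes TAB into toward and away components", {
  d <- data.frame(bias = c(100, 50, -30))
  s <- summarize_bias(d)
  expect_equal(s$tab, 40)
  expect_equal(s$ab_toward, 75)
  expect_equal(s$ab_away, 30)
  expect_equal(s$pct_toward, 100 * 2 / 3)

  sym <- summarize_bias(data.frame(bias = c(120, -120)))
  expect_equal(sym$tab, 0)
  expect_equal(sym$ab_toward, sym$ab_away)

  allpos <- summarize_bias(data.frame(bias = c(10, 20, 30)))
  expect_true(is.na(allpos$ab_away))
  expect_equal(allpos$pct_toward, 100)

  expect_error(summarize_bias(data.frame(bias = numeric())), "empty")
})

test_that("zero biases count in TAB and ABV but in neither sign class", {
  s <- summarize_bias(data.frame(bias = c(0, 100, -50)))
  expect_equal(s$tab, 50 / 3)
  expect_equal(s$n_toward, 1)
  expect_equal(s$n_away, 1)
  expect_equal(s$pct_toward, 50)
  expect_equal(s$abv, sd(c(0, 100, -50)))
})

test_that("TAB decomposition identity and convention-flip properties hold", {
  set.seed(11)
  for (i in 1:20) {
    b <- round(rnorm(24, 0, 150))
    s <- summarize_bias(data.frame(bias = b))
    lhs <- s$tab * s$n_dyads
    rhs <- sum(b[b > 0]) + sum(b[b < 0])
    expect_equal(lhs, rhs)
    f <- summarize_bias(data.frame(bias = -b))
    expect_equal(f$tab, -s$tab)
    expect_equal(f$ab_toward, s$ab_away)
    expect_equal(f$ab_away, s$ab_toward)
    expect_equal(f$sd_toward, s$sd_away)
    expect_equal(f$abv, s$abv)
    if (s$n_toward + s$n_away > 0) {
      expect_equal(f$pct_toward, 100 * s$n_away / (s$n_toward + s$n_away))
    }
  }
})

test_that("bias indices are invariant to a constant RT shift", {
  set.seed(3)
  tr <- make_session(rts = 2500 + rnorm(48, 0, 150))
  tr2 <- tr
  tr2$rt_ms <- tr2$rt_ms + 500
  s1 <- summarize_bias(build_dyads(tr))
  s2 <- summarize_bias(build_dyads(tr2))
  expect_equal(s1$tab, s2$tab)
  expect_equal(s1$ab_toward, s2$ab_toward)
  expect_equal(s1$abv, s2$abv)
})

test_that("error-rate comparison is a paired t-test across subjects", {
  # identical error patterns in both conditions -> t = 0, p = 1
  trials <- do.call(rbind, lapply(1:4, function(i) {
    tr <- make_session(sprintf("S%d", i))
    tr$correct[tr$expression == "angry"][seq_len(i)] <- FALSE
    tr$correct[tr$expression == "neutral"][seq_len(i)] <- FALSE
    tr
  }))
  res <- suppressWarnings(compare_error_rates(trials))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # hand-built 5-subject error counts vs the closed-form paired-t oracle
  n_err <- list(angry = c(1, 3, 0, 2, 4), neutral = c(0, 1, 1, 2, 2))
  trials <- do.call(rbind, lapply(1:5, function(i) {
    tr <- make_session(sprintf("S%d", i))
    for (e in c("angry", "neutral")) {
      k <- n_err[[e]][i]
      if (k > 0) tr$correct[tr$expression == e][seq_len(k)] <- FALSE
    }
    tr
  }))
  res <- suppressWarnings(compare_error_rates(trials))
  orc <- oracle_paired_t(100 * n_err$angry / 24, 100 * n_err$neutral / 24)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-6)
  expect_equal(res$df, 4)

  # a 20-subject cohort yields df = 19
  trials20 <- do.call(rbind, lapply(1:20, function(i) {
    tr <- make_session(sprintf("S%02d", i))
    tr$correct[i %% 48 + 1] <- FALSE
    tr
  }))
  expect_equal(suppressWarnings(compare_error_rates(trials20))$df, 19)
  expect_error(compare_error_rates(make_session()), "2 subjects")
})

test_that("second-scale reaction times are auto-converted on read", {
  tr <- make_session(rts = runif(48, 1.2, 6.8))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tr, path, row.names = FALSE)
  expect_message(out <- read_trial_table(path), "seconds")
  expect_true(all(out$rt_ms > 1000))
})
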