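test_that("the generator is a pure function of config and seed", {
  cfg <- cohort_config(n_patients = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$profiles, b$profiles)
  c2 <- simulate_cohort(cohort_config(n_patients = 3, seed = 100))
  expect_false(identical(a$trials$rt_ms, c2$trials$rt_ms))
})

test_that("cohorts have the full task design shape", {
  co <- simulate_cohort(cohort_config(n_patients = 20, seed = 1))
  expect_equal(nrow(co$trials), 20 * 48)
  expect_equal(nrow(co$profiles), 20)
  expect_equal(nrow(co$ground_truth), 20)
  one <- co$trials[co$trials$subject_id == "S07", ]
  expect_equal(nrow(unique(one[, c("face_id", "expression", "position")])), 48)
  # profiles respect their scale bounds
  expect_true(all(co$profiles$re_exp >= 0 & co$profiles$re_exp <= 40))
  expect_true(all(co$profiles$avoid >= 0 & co$profiles$avoid <= 56))
})

test_that("a frozen chain with an under-state start never leaves the under state", {
  cfg <- cohort_config(n_patients = 2, markov_stay_prob = 1,
                       initial_state = "under", threat_effect = 1200,
                       rt_noise_sd = 150, seed = 5)
  sim <- simulate_patient(cfg, 1)
  expect_true(all(sim$trials$state == "under"))
  expect_equal(sim$truth$occupancy_under, 1)
  # all-under sessions show an almost pure toward bias
  s <- summarize_bias(build_dyads(sim$trials[sim$trials$correct,
                                             c("subject_id", "face_id",
                                               "expression", "position",
                                               "rt_ms", "correct")]))
  expect_gt(s$pct_toward, 95)
})

test_that("a null generator yields no attentional bias and unimodal verdicts", {
  cfg <- cohort_config(n_patients = 30, state_offset = 0, threat_effect = 0,
                       coupling = 0, seed = 17)
  co <- simulate_cohort(cfg)
  sc <- score_cohort(co$trials[, 1:6])
  # TAB averages near zero: SE of the cohort mean ~ dyad noise / sqrt(24 * 30)
  se <- 150 * sqrt(2) / sqrt(24 * 30)
  expect_lt(abs(mean(sc$tab)), 4 * se)
  verdicts <- vapply(unique(co$trials$subject_id), function(s) {
    tr <- co$trials[co$trials$subject_id == s & co$trials$correct, ]
    analyze_bimodality(normalize_conditions(tr$rt_ms, tr$expression),
                       seed = 1)$preferred
  }, character(1))
  expect_lt(mean(verdicts == "bimodal"), 0.25)
})

test_that("threat effect and state offset couple monotonically to behavior", {
  mean_abs_bias <- vapply(c(0, 300, 700), function(delta) {
    co <- simulate_cohort(cohort_config(n_patients = 25, state_offset = 0,
                                        threat_effect = delta, seed = 23))
    d <- build_dyads(co$trials[co$trials$correct, 1:6])$dyads
    mean(abs(d$bias))
  }, numeric(1))
  expect_true(all(diff(mean_abs_bias) > 0))

  mean_dist <- vapply(c(200, 700, 1400), function(off) {
    co <- simulate_cohort(cohort_config(n_patients = 15, state_offset = off,
                                        threat_effect = 0, seed = 29))
    d <- vapply(unique(co$trials$subject_id), function(s) {
      tr <- co$trials[co$trials$subject_id == s & co$trials$correct, ]
      kmeans_peaks(normalize_conditions(tr$rt_ms, tr$expression),
                   seed = 3)$peak_distance
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(mean_dist) > 0))
})

test_that("mixture fits recover the generator's two peaks", {
  cfg <- cohort_config(n_patients = 1, state_offset = 1200, threat_effect = 0,
                       rt_noise_sd = 150, severity_range = c(1, 1), seed = 3)
  sim <- simulate_patient(cfg, 1)
  tr <- sim$trials[sim$trials$correct, ]
  x <- normalize_conditions(tr$rt_ms, tr$expression)
  f <- fit_gmm(x, 2, seed = 8)
  # true peaks at base +/- 600; grand-mean recentring shifts both equally
  expect_equal(diff(f$means), 1200, tolerance = 0.15 * 1200)
})

test_that("meta tables are deterministic with the requested shape and t fraction", {
  cfg <- meta_config(n_studies = 16, target_rho = 0.5,
                     outcome_kind = "amygdala_left", fraction_t = 1, seed = 2)
  a <- simulate_meta_table(cfg)
  b <- simulate_meta_table(cfg)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 16)
  expect_true(all(a$records$raw_stat_kind == "t"))
  expect_true(all(is.finite(a$records$t_df)))
  # the harmonization path recovers the planted imbalance exactly
  h <- harmonize_studies(a$records)
  expect_equal(h$imbalance, a$truth$imbalance, tolerance = 1e-10)
  expect_error(meta_config(n_studies = 2), "at least 3")
})

test_that("planted meta correlations are recovered on average", {
  rs <- vapply(1:100, function(i) {
    tab <- simulate_meta_table(meta_config(n_studies = 16, target_rho = 0.55,
                                           seed = i))
    run_meta(tab$records, "tab_ms")$correlation$r
  }, numeric(1))
  # E[r] carries the usual small-sample shrinkage; 100 tables give SE ~ 0.02
  expect_lt(abs(mean(rs) - 0.55), 0.06)
})

test_that("written cohorts are readable by the analysis CSV readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(n_patients = 4, seed = 12))
  paths <- write_cohort(co, dir)
  tr <- read_trial_table(paths[["trials"]])
  expect_equal(nrow(tr), 4 * 48)
  expect_false("state" %in% names(tr))  # latent truth never leaks to inputs
  pf <- read_symptom_table(paths[["symptoms"]])
  expect_equal(pf$subject_id, co$profiles$subject_id)
})
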