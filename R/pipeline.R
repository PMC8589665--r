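# End-to-end orchestration of the experiment-level and meta-level analyses.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis.  Defaults equal the
#' method's fixed values: 5-SD trial exclusion, AIC-difference margin of 2,
#' 100 k-means initializations, one-tailed correlation tests.
#'
#' @param bias_sign Dyad sign convention (see [build_dyads()]).  The
#'   TAB-imbalance correlation direction follows it: under
#'   `"toward_positive"` the model predicts TAB to fall with imbalance
#'   (avoidance-dominant patients look away from threat), so the
#'   hypothesized direction is `"negative"`; under the literal
#'   `"angry_minus_neutral"` convention TAB and imbalance share orientation
#'   and the hypothesized direction is `"positive"`.
#' @param exclusion_sd Outlier threshold in SD units (default 5).
#' @param gmm_restarts,gmm_tol,gmm_max_iter EM settings for [fit_gmm()].
#' @param delta_aic_threshold AIC margin for [classify_modality()].
#' @param kmeans_iterations Iterations of the peak-distance correlation.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(bias_sign = BIAS_SIGNS, exclusion_sd = 5,
                            gmm_restarts = 20L, gmm_tol = 1e-6,
                            gmm_max_iter = 500L, delta_aic_threshold = 2,
                            kmeans_iterations = 100L, p_enter = 0.05,
                            p_remove = 0.10, seed = 1L) {
  bias_sign <- match.arg(bias_sign, BIAS_SIGNS)
  structure(as.list(environment()), class = "pipeline_config")
}

# Per-subject pooled normalized reaction times, in subject order.
rt_samples_from_trials <- function(kept, subjects) {
  out <- lapply(subjects, function(s) {
    sel <- kept$subject_id == s
    normalize_conditions(kept$rt_ms[sel], kept$expression[sel])
  })
  names(out) <- subjects
  out
}

#' Run the full experiment-level analysis
#'
#' Composes the pipeline on trial-level b-CFS data and per-patient symptom
#' profiles: trial exclusion, dyad bias scoring, per-patient bimodality
#' (mixture AIC verdicts, k-means peaks, plus a pooled all-patient fit),
#' TAB-imbalance correlation (with nonparametric robustness check when
#' either variable carries a 2-SD outlier), stepwise regressions of
#' AB_TOWARD / AB_AWAY and their within-class SDs on the three diagnostic
#' symptom clusters, a multicollinearity block, the angry/neutral
#' error-rate comparison, the iterated peak-distance / symptom-sum
#' correlation, and a dissociation-augmented sensitivity re-run when
#' depersonalization/derealization scores are available.
#'
#' @param trials Trial data frame (see [read_trial_table()]).
#' @param profiles Symptom profile data frame (see [read_symptom_table()]);
#'   every trial subject must have a symptom row.
#' @param config A [pipeline_config()].
#' @return Object of class `"experiment_report"`.
#' @export
run_experiment_pipeline <- function(trials, profiles,
                                    config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  trials <- validate_trials(trials)
  subjects <- unique(trials$subject_id)
  missing <- setdiff(subjects, profiles$subject_id)
  if (length(missing) > 0) {
    abort_validation("symptom table is missing subject(s): ",
                     paste(missing, collapse = ", "))
  }
  profiles <- profiles[match(subjects, profiles$subject_id), , drop = FALSE]

  scored <- score_cohort(trials, bias_sign = config$bias_sign,
                         sd_mult = config$exclusion_sd)
  scored <- scored[match(subjects, scored$subject_id), , drop = FALSE]
  excl <- exclude_trials(trials, sd_mult = config$exclusion_sd)
  rt_list <- rt_samples_from_trials(excl$kept, subjects)

  bimod <- do.call(rbind, lapply(seq_along(subjects), function(j) {
    a <- analyze_bimodality(rt_list[[j]], seed = derive_seed(config$seed, 7, j),
                            n_restarts = config$gmm_restarts,
                            tol = config$gmm_tol,
                            max_iter = config$gmm_max_iter,
                            threshold = config$delta_aic_threshold)
    data.frame(subject_id = subjects[j], delta_aic = a$delta_aic,
               preferred = a$preferred, aic1 = a$aic1, aic2 = a$aic2,
               center_lo = a$centers[1], center_hi = a$centers[2],
               peak_distance = a$peak_distance, stringsAsFactors = FALSE)
  }))
  pooled <- analyze_bimodality(unlist(rt_list, use.names = FALSE),
                               seed = derive_seed(config$seed, 8),
                               n_restarts = config$gmm_restarts,
                               tol = config$gmm_tol,
                               max_iter = config$gmm_max_iter,
                               threshold = config$delta_aic_threshold)

  norm <- symptom_imbalance(profiles)
  hyper_norm <- normalize_cluster(profiles$hyper, profiles$hyper_min,
                                  profiles$hyper_max, "hyper")
  predictors <- data.frame(re_exp = norm$re_norm, avoid = norm$avoid_norm,
                           hyper = hyper_norm)

  direction <- if (config$bias_sign == "toward_positive") "negative" else "positive"
  tab_imbalance <- pearson_one_tailed(norm$imbalance, scored$tab, direction)
  tab_imbalance_spearman <- if (needs_nonparametric(scored$tab) ||
                                  needs_nonparametric(norm$imbalance)) {
    spearman_check(norm$imbalance, scored$tab, direction)
  }

  run_stepwise <- function(y) {
    ok <- stats::complete.cases(y, predictors)
    if (sum(ok) <= ncol(predictors) + 2) return(NULL)
    stepwise_regress(y[ok], predictors[ok, , drop = FALSE],
                     p_enter = config$p_enter, p_remove = config$p_remove)
  }
  stepwise <- list(ab_toward = run_stepwise(scored$ab_toward),
                   ab_away = run_stepwise(scored$ab_away),
                   sd_toward = run_stepwise(scored$sd_toward),
                   sd_away = run_stepwise(scored$sd_away))

  dist_corr <- distance_symptom_correlation(
    rt_list, norm$symptom_sum, n_iterations = config$kmeans_iterations,
    seed = derive_seed(config$seed, 9))

  augmented <- NULL
  if (!any(is.na(profiles$depder))) {
    aug <- augmented_avoidance(profiles)
    augmented <- list(imbalance = aug$imbalance,
                      tab_correlation = pearson_one_tailed(aug$imbalance,
                                                           scored$tab,
                                                           direction))
  }

  n_tests <- 2L +  # TAB-imbalance, distance-symptom
    sum(!vapply(stepwise, is.null, logical(1))) +
    !is.null(tab_imbalance_spearman) + !is.null(augmented) + 1L  # error rates
  structure(list(
    subjects = subjects,
    bias = cbind(scored, norm[, c("re_norm", "avoid_norm", "imbalance",
                                  "symptom_sum")],
                 hyper_norm = hyper_norm),
    bimodality = bimod,
    pooled_bimodality = pooled[c("delta_aic", "preferred", "aic1", "aic2",
                                 "peak_distance")],
    tab_imbalance = tab_imbalance,
    tab_imbalance_spearman = tab_imbalance_spearman,
    stepwise = stepwise,
    multicollinearity = multicollinearity_check(predictors),
    error_rates = compare_error_rates(trials),
    distance_correlation = dist_corr,
    augmented_avoidance = augmented,
    exclusion = list(n_excluded = excl$n_excluded,
                     excluded_fraction = excl$excluded_fraction),
    n_tests = n_tests,
    config = unclass(config)
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %d subjects, %.1f%% trials excluded\n",
              length(x$subjects), 100 * x$exclusion$excluded_fraction))
  cat(sprintf("  TAB-imbalance: r = %.3f, one-tailed p = %.4f (%s direction)\n",
              x$tab_imbalance$r, x$tab_imbalance$p_one_tailed,
              x$tab_imbalance$direction))
  cat(sprintf("  bimodal verdicts: %d/%d patients (pooled: %s)\n",
              sum(x$bimodality$preferred == "bimodal"), nrow(x$bimodality),
              x$pooled_bimodality$preferred))
  cat(sprintf("  peak distance vs symptom sum: mean r = %.3f over %d iterations\n",
              x$distance_correlation$mean_r,
              x$distance_correlation$n_iterations))
  for (nm in names(x$stepwise)) {
    sw <- x$stepwise[[nm]]
    if (!is.null(sw)) {
      cat(sprintf("  stepwise %s: selected %s\n", nm,
                  if (length(sw$selected)) paste(sw$selected, collapse = ", ")
                  else "(none)"))
    }
  }
  invisible(x)
}

#' Run the meta-analysis pipeline
#'
#' For every outcome kind present with at least 3 records, computes the
#' imbalance-outcome correlation; for the behavioral (TAB) outcome a
#' PTSD-only re-analysis is added when at least 3 diagnosed populations
#' are available.  Outcome kinds absent from the table are simply absent
#' from the report.
#'
#' @param records Study record data frame (see [read_meta_table()]).
#' @param config A [pipeline_config()] (reserved for future options).
#' @return Object of class `"meta_report"`: named list of
#'   `"meta_result"` objects among `tab_ms`, `tab_ms_ptsd_only`,
#'   `amygdala_left`, `amygdala_right`, plus `n_tests`.
#' @export
run_meta_pipeline <- function(records, config = pipeline_config()) {
  records <- validate_study_records(records)
  if (nrow(records) == 0) abort_validation("empty study record table")
  out <- list()
  for (kind in OUTCOME_KINDS) {
    n_kind <- sum(records$outcome_kind == kind)
    if (n_kind >= 3) {
      out[[kind]] <- run_meta(records, kind)
      if (kind == "tab_ms" &&
            sum(records$outcome_kind == kind & as.logical(records$is_ptsd)) >= 3) {
        out$tab_ms_ptsd_only <- run_meta(records, kind, ptsd_only = TRUE)
      }
    }
  }
  if (length(out) == 0) {
    abort_validation("no outcome kind has at least 3 records")
  }
  out$n_tests <- sum(vapply(out, inherits, logical(1), "meta_result"))
  structure(out, class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  for (nm in setdiff(names(x), "n_tests")) print(x[[nm]])
  invisible(x)
}

#' Write a report as JSON
#'
#' Serializes an experiment or meta report to machine-readable JSON.
#' Reports carry no timestamps, so identical inputs, configuration and
#' seed reproduce byte-identical files.
#'
#' @param report An `"experiment_report"` or `"meta_report"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
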