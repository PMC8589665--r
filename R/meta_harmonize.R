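# Study-level meta-analysis records: t-to-z conversion, symptom
# harmonization of population means, and the imbalance-outcome correlation.
#
# A study record table has one row per participant population with columns
#   study_id, population_id, n, is_ptsd, dsm_version,
#   the cluster mean/min/max columns of the symptom table
#   (re_exp, re_exp_min, ..., depder_max; population-mean valued),
#   outcome_kind ("tab_ms", "amygdala_left", "amygdala_right"),
#   outcome_value (TAB in ms, or a z/t statistic),
#   raw_stat_kind ("z" or "t"), t_df (required when raw_stat_kind = "t").

OUTCOME_KINDS <- c("tab_ms", "amygdala_left", "amygdala_right")

#' Convert a t statistic to a z-score
#'
#' Probability-matched conversion `z = qnorm(pt(t, df))`: the z-score with
#' the same cumulative tail probability as the observed central-t
#' statistic, the standard conversion applied when primary studies report
#' region-of-interest activations as t-statistics rather than z-scores.
#' Tails are computed on the log scale for numerical accuracy and the
#' result is clamped to +/- 8 to avoid infinities at extreme values.
#'
#' @param t t statistic(s), finite.
#' @param df Degrees of freedom (> 0), recycled against `t`.
#' @return z-score(s).
#' @export
#' @examples
#' t_to_z(2.0, 30)
t_to_z <- function(t, df) {
  if (any(!is.finite(t))) abort_validation("non-finite t statistic")
  if (any(!is.finite(df)) || any(df <= 0)) {
    abort_validation("df must be finite and positive")
  }
  z <- ifelse(t <= 0,
              stats::qnorm(stats::pt(t, df, log.p = TRUE), log.p = TRUE),
              stats::qnorm(stats::pt(t, df, lower.tail = FALSE, log.p = TRUE),
                           lower.tail = FALSE, log.p = TRUE))
  pmin(8, pmax(-8, z))
}

validate_study_records <- function(records) {
  require_columns(records, c("study_id", "population_id", "n", "is_ptsd",
                             "dsm_version", "re_exp", "re_exp_min",
                             "re_exp_max", "avoid", "avoid_min", "avoid_max",
                             "outcome_kind", "outcome_value", "raw_stat_kind",
                             "t_df"),
                  "study record table")
  if (any(!records$outcome_kind %in% OUTCOME_KINDS)) {
    abort_validation("outcome_kind must be one of: ",
                     paste(OUTCOME_KINDS, collapse = ", "))
  }
  tt <- records$raw_stat_kind == "t"
  if (any(tt & (is.na(records$t_df) | records$t_df <= 0))) {
    abort_validation("t-statistic outcome(s) missing positive t_df: row(s) ",
                     paste(which(tt & (is.na(records$t_df) | records$t_df <= 0)),
                           collapse = ", "))
  }
  key <- paste(records$study_id, records$population_id, records$outcome_kind)
  if (anyDuplicated(key)) {
    abort_validation("duplicate (study, population, outcome_kind) record(s)")
  }
  records
}

#' Read a meta-analysis study table
#'
#' Reads the CSV interchange format for study-level records (see the
#' package vignette for the column list).
#'
#' @param path Path to a CSV file.
#' @return Validated study record data frame.
#' @export
read_meta_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("numb", "numb_min", "numb_max", "hyper", "hyper_min",
                "hyper_max", "depder", "depder_min", "depder_max", "t_df")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  validate_study_records(df)
}

#' Harmonize study records
#'
#' For each record computes the population-mean symptom imbalance (via the
#' same normalization and DSM harmonization applied to patient-level data)
#' and the harmonized outcome: TAB values pass through unchanged; imaging
#' outcomes reported as t-statistics are converted to z-scores with
#' [t_to_z()].
#'
#' @param records Validated study record data frame.
#' @return Data frame with `study_id`, `population_id`, `outcome_kind`,
#'   `is_ptsd`, `imbalance`, `outcome`.
#' @export
harmonize_studies <- function(records) {
  records <- validate_study_records(records)
  prof <- records
  prof$subject_id <- paste(records$study_id, records$population_id, sep = ":")
  imb <- symptom_imbalance(prof)$imbalance
  outcome <- records$outcome_value
  conv <- records$outcome_kind != "tab_ms" & records$raw_stat_kind == "t"
  if (any(conv)) {
    outcome[conv] <- t_to_z(records$outcome_value[conv], records$t_df[conv])
  }
  data.frame(study_id = records$study_id,
             population_id = records$population_id,
             outcome_kind = records$outcome_kind,
             is_ptsd = as.logical(records$is_ptsd),
             imbalance = imb, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Harmonize a single study record
#'
#' @param record One-row study record data frame.
#' @return One-row output of [harmonize_studies()].
#' @export
harmonize_study <- function(record) {
  if (nrow(record) != 1) abort_validation("harmonize_study expects one row")
  harmonize_studies(record)
}

#' Imbalance-outcome meta-analysis correlation
#'
#' Retains the records of the requested outcome kind (optionally PTSD-only
#' populations), harmonizes them, and correlates population symptom
#' imbalance with the harmonized outcome (one-tailed Pearson, positive
#' direction).  Population means enter unweighted, mirroring a plain
#' correlation across study populations.
#'
#' @param records Study record data frame.
#' @param outcome_kind `"tab_ms"`, `"amygdala_left"` or `"amygdala_right"`.
#' @param ptsd_only If `TRUE`, keep only populations of diagnosed patients.
#' @return Object of class `"meta_result"`: list with `n_populations`,
#'   `data` (harmonized pairs) and `correlation`
#'   (a `"correlation_result"`).
#' @export
run_meta <- function(records, outcome_kind = OUTCOME_KINDS, ptsd_only = FALSE) {
  outcome_kind <- match.arg(outcome_kind, OUTCOME_KINDS)
  records <- validate_study_records(records)
  keep <- records$outcome_kind == outcome_kind
  if (ptsd_only) keep <- keep & as.logical(records$is_ptsd)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 3) {
    abort_validation("need at least 3 retained records for outcome '",
                     outcome_kind, "'", if (ptsd_only) " (PTSD-only)")
  }
  h <- harmonize_studies(records)
  ct <- pearson_one_tailed(h$imbalance, h$outcome, direction = "positive")
  structure(list(n_populations = nrow(h), outcome_kind = outcome_kind,
                 ptsd_only = ptsd_only, data = h, correlation = ct),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s%s): %d populations\n", x$outcome_kind,
              if (x$ptsd_only) ", PTSD-only" else "", x$n_populations))
  print(x$correlation)
  invisible(x)
}
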