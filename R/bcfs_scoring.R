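# b-CFS trial scoring: exclusion, dyad construction, attentional-bias indices.
#
# A trial table has one row per trial with columns
#   subject_id, face_id (1-6), expression ("angry"/"neutral"),
#   position (1-4), rt_ms (> 0), correct (logical or 0/1).
# The full task design is 6 face identities x 2 expressions x 4 positions
# = 48 trials per subject, pairing into at most 24 angry/neutral dyads.

BIAS_SIGNS <- c("toward_positive", "angry_minus_neutral")

validate_trials <- function(trials) {
  require_columns(trials, c("subject_id", "face_id", "expression", "position",
                            "rt_ms", "correct"), "trial table")
  if (any(!trials$expression %in% c("angry", "neutral"))) {
    abort_validation("expression must be 'angry' or 'neutral'")
  }
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0)) {
    abort_validation("rt_ms must be finite and positive")
  }
  trials$correct <- as.logical(trials$correct)
  if (any(is.na(trials$correct))) abort_validation("correct must be logical or 0/1")
  trials
}

#' Read a b-CFS trial table
#'
#' Reads the CSV interchange format for trial-level b-CFS data (columns
#' `subject_id, face_id, expression, position, rt_ms, correct`).  Reaction
#' times recorded in seconds are auto-detected (all values below 20) and
#' converted to milliseconds with a message.
#'
#' @param path Path to a CSV file.
#' @return Validated trial data frame with `rt_ms` in milliseconds.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_trials(df)
  if (all(df$rt_ms < 20)) {
    message("rt_ms values all below 20; assuming seconds and converting to ms")
    df$rt_ms <- df$rt_ms * 1000
  }
  df
}

#' Exclude incorrect and extreme-outlier trials
#'
#' Removes trials with incorrect responses, then removes correct trials
#' whose reaction time exceeds the subject's condition mean by more than
#' `sd_mult` sample standard deviations (one-sided, above the mean only;
#' mean and SD per subject per expression over correct trials).  The mean
#' and SD for each trial are computed leave-one-out, i.e. over the other
#' correct trials of its condition: with the candidate included, the
#' largest attainable z-score in a sample of n trials is `(n - 1) /
#' sqrt(n)` (about 4.7 at the task's 24 trials per condition), so an
#' inclusive 5-SD rule could never fire.  A warning (not an error) is
#' emitted if the overall excluded fraction reaches `warn_fraction`, since
#' the rule is expected to remove well under 3% of trials in clean
#' sessions.
#'
#' @param trials Trial data frame (may contain several subjects).
#' @param sd_mult Outlier threshold in SD units (default 5).
#' @param warn_fraction Excluded-fraction warning threshold (default 0.03).
#' @return A list with `kept` (trial data frame), `report` (one row per
#'   excluded trial with a `reason` column), `n_excluded` and
#'   `excluded_fraction`.
#' @export
exclude_trials <- function(trials, sd_mult = 5, warn_fraction = 0.03) {
  trials <- validate_trials(trials)
  key <- interaction(trials$subject_id, trials$expression, drop = TRUE)
  n_correct <- tapply(trials$correct, key, sum)
  if (any(n_correct < 2)) {
    abort_validation("fewer than 2 correct trials in condition(s): ",
                     paste(names(n_correct)[n_correct < 2], collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(trials))
  reason[!trials$correct] <- "incorrect"
  for (k in levels(key)) {
    idx <- which(key == k & trials$correct)
    if (length(idx) < 3) next  # leave-one-out SD needs two other trials
    x <- trials$rt_ms[idx]
    for (j in seq_along(idx)) {
      others <- x[-j]
      if (x[j] > mean(others) + sd_mult * stats::sd(others)) {
        reason[idx[j]] <- "outlier_above_5sd"
      }
    }
  }
  excluded <- !is.na(reason)
  report <- trials[excluded, , drop = FALSE]
  report$reason <- reason[excluded]
  frac <- mean(excluded)
  if (frac >= warn_fraction) {
    warning(sprintf("excluded fraction %.1f%% reaches %.0f%% of all trials",
                    100 * frac, 100 * warn_fraction), call. = FALSE)
  }
  list(kept = trials[!excluded, , drop = FALSE],
       report = report,
       n_excluded = sum(excluded),
       excluded_fraction = frac)
}

#' Build matched angry/neutral dyads
#'
#' Pairs, within each subject, the angry and the neutral trial that share a
#' face identity and screen position.  Cells missing either member (e.g.
#' because a trial was excluded) are dropped whole and counted.  The signed
#' dyad bias score is computed under the configured sign convention:
#' `"toward_positive"` (default) stores `rt_neutral - rt_angry`, so a
#' positive score means the angry face broke suppression faster (attention
#' toward threat); `"angry_minus_neutral"` stores the literal difference
#' `rt_angry - rt_neutral` (positive = slower threat detection).
#'
#' @param trials Kept trial data frame.
#' @param bias_sign Sign convention (see Details).
#' @return A list with `dyads` (columns `subject_id, face_id, position,
#'   rt_angry, rt_neutral, bias`) and `incomplete` (dropped cells).
#' @export
build_dyads <- function(trials, bias_sign = BIAS_SIGNS) {
  bias_sign <- match.arg(bias_sign, BIAS_SIGNS)
  if (nrow(trials) == 0) {
    empty <- data.frame(subject_id = character(), face_id = integer(),
                        position = integer(), rt_angry = numeric(),
                        rt_neutral = numeric(), bias = numeric())
    return(list(dyads = empty, incomplete = empty[, 1:3]))
  }
  trials <- validate_trials(trials)
  cell <- interaction(trials$subject_id, trials$face_id, trials$expression,
                      trials$position, drop = TRUE)
  if (anyDuplicated(cell)) {
    abort_validation("duplicate trial(s) for the same (subject, face, ",
                     "expression, position) cell")
  }
  ang <- trials[trials$expression == "angry", ]
  neu <- trials[trials$expression == "neutral", ]
  dy <- merge(ang[, c("subject_id", "face_id", "position", "rt_ms")],
              neu[, c("subject_id", "face_id", "position", "rt_ms")],
              by = c("subject_id", "face_id", "position"),
              suffixes = c("_angry", "_neutral"))
  names(dy)[names(dy) == "rt_ms_angry"] <- "rt_angry"
  names(dy)[names(dy) == "rt_ms_neutral"] <- "rt_neutral"
  dy$bias <- if (bias_sign == "toward_positive") {
    dy$rt_neutral - dy$rt_angry
  } else {
    dy$rt_angry - dy$rt_neutral
  }
  all_cells <- unique(trials[, c("subject_id", "face_id", "position")])
  paired <- paste(dy$subject_id, dy$face_id, dy$position)
  incomplete <- all_cells[!paste(all_cells$subject_id, all_cells$face_id,
                                 all_cells$position) %in% paired, , drop = FALSE]
  dy <- dy[order(dy$subject_id, dy$face_id, dy$position), ]
  rownames(dy) <- NULL
  list(dyads = dy, incomplete = incomplete)
}

#' Summarize one subject's dyad bias scores
#'
#' Computes the traditional attentional bias (TAB, mean of all signed dyad
#' scores), the mean of the strictly positive scores (`ab_toward`), the
#' absolute mean of the strictly negative scores (`ab_away`), within-class
#' SDs (`NA` when a class has fewer than 2 members), the SD of all scores
#' (`abv`, attentional bias variability) and the percentage of positive
#' scores among signed ones (`pct_toward`).  Zero-valued scores count in
#' `tab` and `abv` but in neither sign class.
#'
#' @param dyads Dyad data frame for a single subject (from [build_dyads()]).
#' @return An object of class `"bias_summary"`: a list with elements `tab`,
#'   `ab_toward`, `ab_away`, `sd_toward`, `sd_away`, `abv`, `pct_toward`,
#'   `n_dyads`, `n_toward`, `n_away`.
#' @export
summarize_bias <- function(dyads) {
  if (is.list(dyads) && !is.data.frame(dyads) && !is.null(dyads$dyads)) {
    dyads <- dyads$dyads
  }
  b <- dyads$bias
  if (is.null(b) || length(b) == 0) abort_validation("empty dyad set")
  pos <- b[b > 0]
  neg <- b[b < 0]
  res <- list(
    tab = mean(b),
    ab_toward = if (length(pos)) mean(pos) else NA_real_,
    ab_away = if (length(neg)) abs(mean(neg)) else NA_real_,
    sd_toward = if (length(pos) >= 2) stats::sd(pos) else NA_real_,
    sd_away = if (length(neg) >= 2) stats::sd(neg) else NA_real_,
    abv = if (length(b) >= 2) stats::sd(b) else NA_real_,
    pct_toward = if (length(pos) + length(neg) > 0) {
      100 * length(pos) / (length(pos) + length(neg))
    } else NA_real_,
    n_dyads = length(b),
    n_toward = length(pos),
    n_away = length(neg)
  )
  structure(res, class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "b-CFS bias summary: %d dyads\n  TAB %.1f ms  AB_TOWARD %.1f ms  AB_AWAY %.1f ms\n  ABV %.1f ms  toward trials %.1f%%\n",
    x$n_dyads, x$tab, x$ab_toward, x$ab_away, x$abv, x$pct_toward))
  invisible(x)
}

#' Score a whole cohort of b-CFS sessions
#'
#' Runs trial exclusion, dyad construction and bias summarization per
#' subject and returns one row per subject.
#'
#' @inheritParams exclude_trials
#' @inheritParams build_dyads
#' @return Data frame with one row per subject: the [summarize_bias()]
#'   fields plus `n_excluded_trials` and `excluded_fraction`.
#' @export
score_cohort <- function(trials, bias_sign = BIAS_SIGNS, sd_mult = 5) {
  bias_sign <- match.arg(bias_sign, BIAS_SIGNS)
  excl <- exclude_trials(trials, sd_mult = sd_mult)
  dy <- build_dyads(excl$kept, bias_sign = bias_sign)
  subjects <- unique(trials$subject_id)
  rows <- lapply(subjects, function(s) {
    sm <- summarize_bias(dy$dyads[dy$dyads$subject_id == s, , drop = FALSE])
    n_exc <- sum(excl$report$subject_id == s)
    data.frame(subject_id = s, tab = sm$tab, ab_toward = sm$ab_toward,
               ab_away = sm$ab_away, sd_toward = sm$sd_toward,
               sd_away = sm$sd_away, abv = sm$abv,
               pct_toward = sm$pct_toward, n_dyads = sm$n_dyads,
               n_excluded_trials = n_exc,
               excluded_fraction = n_exc / sum(trials$subject_id == s))
  })
  do.call(rbind, rows)
}

#' Compare error rates between angry and neutral trials
#'
#' Computes each subject's percentage error rate per facial expression and
#' runs a paired t-test across subjects (df = number of subjects - 1).
#'
#' @param trials Trial data frame with at least 2 subjects, both
#'   expressions present for every subject.
#' @return List with `t`, `df`, `p` (two-tailed), `mean_angry`,
#'   `mean_neutral` (mean percent error per condition).
#' @export
compare_error_rates <- function(trials) {
  trials <- validate_trials(trials)
  subjects <- unique(trials$subject_id)
  if (length(subjects) < 2) abort_validation("need at least 2 subjects")
  pct <- function(s, e) {
    sel <- trials$subject_id == s & trials$expression == e
    if (!any(sel)) abort_validation("subject ", s, " has no '", e, "' trials")
    100 * mean(!trials$correct[sel])
  }
  ang <- vapply(subjects, pct, numeric(1), e = "angry")
  neu <- vapply(subjects, pct, numeric(1), e = "neutral")
  d <- ang - neu
  n <- length(d)
  if (stats::sd(d) == 0) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    tval <- mean(d) / (stats::sd(d) / sqrt(n))
  }
  list(t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), n - 1),
       mean_angry = mean(ang), mean_neutral = mean(neu))
}
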