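# Symptom-cluster scores: normalization, DSM harmonization, imbalance.
#
# A symptom profile is one row of a data frame with columns
#   subject_id, dsm_version ("IV" or "V"),
#   re_exp,  re_exp_min,  re_exp_max,
#   avoid,   avoid_min,   avoid_max,
#   numb,    numb_min,    numb_max,     (DSM-V only; NA otherwise)
#   hyper,   hyper_min,   hyper_max,
#   depder,  depder_min,  depder_max    (optional)
# Scores are raw instrument values; each cluster carries its own scale
# bounds because different studies use different instruments.

CLUSTERS <- c("re_exp", "avoid", "numb", "hyper", "depder")

#' CAPS (DSM-IV) scale preset
#'
#' Scale bounds for the Clinician-Administered PTSD Scale under DSM-IV:
#' each item is scored 0-8 (frequency 0-4 plus intensity 0-4), with 5
#' re-experiencing items, 7 combined avoidance/numbing items, 5
#' hypervigilance (arousal) items and 2 depersonalization/derealization
#' associated-feature items.
#'
#' @return A one-row data frame of `*_min` / `*_max` bounds plus
#'   `dsm_version = "IV"`, suitable for `cbind()`ing with raw scores.
#' @export
caps_dsm4_scale <- function() {
  data.frame(
    dsm_version = "IV",
    re_exp_min = 0, re_exp_max = 40,
    avoid_min = 0, avoid_max = 56,
    numb_min = NA_real_, numb_max = NA_real_,
    hyper_min = 0, hyper_max = 40,
    depder_min = 0, depder_max = 16
  )
}

#' Normalize a raw cluster score to the unit interval
#'
#' Maps a raw symptom-cluster score to `[0, 1]` so that the lowest possible
#' instrument value becomes 0 and the highest possible value becomes 1.
#' This is the normalization applied before symptom scores from different
#' instruments are compared or subtracted.
#'
#' @param raw Raw score(s).
#' @param min,max Scale bounds (lowest/highest possible raw value).
#' @param cluster Cluster name used in error messages.
#' @return Normalized score(s) in `[0, 1]`.
#' @export
#' @examples
#' normalize_cluster(10, 0, 20)  # 0.5
normalize_cluster <- function(raw, min, max, cluster = "cluster") {
  if (any(!is.finite(raw)) || any(!is.finite(min)) || any(!is.finite(max))) {
    abort_validation("non-finite score or bounds for cluster '", cluster, "'")
  }
  if (any(max <= min)) {
    abort_validation("degenerate scale bounds (max <= min) for cluster '", cluster, "'")
  }
  if (any(raw < min) || any(raw > max)) {
    abort_validation("raw score outside [min, max] for cluster '", cluster, "'")
  }
  (raw - min) / (max - min)
}

#' Harmonize avoidance scores across DSM versions
#'
#' DSM-IV instruments report a single combined avoidance/numbing cluster;
#' DSM-V instruments split it into separate avoidance and numbing clusters.
#' For DSM-V profiles the two raw scores and their bounds are summed so that
#' the combined cluster is directly comparable with DSM-IV avoidance.
#'
#' @param profiles Data frame of symptom profiles (see module header).
#' @return Data frame with columns `avoid`, `avoid_min`, `avoid_max`
#'   holding the harmonized combined cluster, one row per profile.
#' @export
harmonize_avoidance <- function(profiles) {
  require_columns(profiles, c("dsm_version", "avoid", "avoid_min", "avoid_max"),
                  "symptom profile table")
  v5 <- profiles$dsm_version == "V"
  if (any(!profiles$dsm_version %in% c("IV", "V"))) {
    abort_validation("dsm_version must be 'IV' or 'V'")
  }
  out <- profiles[, c("avoid", "avoid_min", "avoid_max")]
  if (any(v5)) {
    require_columns(profiles, c("numb", "numb_min", "numb_max"),
                    "DSM-V symptom profile table")
    bad <- v5 & (is.na(profiles$numb) | is.na(profiles$numb_min) |
                   is.na(profiles$numb_max))
    if (any(bad)) {
      abort_validation("DSM-V profile(s) missing numbing score or bounds: row(s) ",
                       paste(which(bad), collapse = ", "))
    }
    out$avoid[v5] <- profiles$avoid[v5] + profiles$numb[v5]
    out$avoid_min[v5] <- profiles$avoid_min[v5] + profiles$numb_min[v5]
    out$avoid_max[v5] <- profiles$avoid_max[v5] + profiles$numb_max[v5]
  }
  out
}

#' Symptom imbalance and symptom sum
#'
#' Computes, per profile, normalized re-experiencing and (harmonized)
#' avoidance scores, their difference (the symptom imbalance,
#' `avoid_norm - re_norm`, a proxy for the balance between emotional over-
#' and undermodulation) and their sum (`re_norm + avoid_norm`, a proxy for
#' how far apart the two modulatory states sit).
#'
#' @param profiles Data frame of symptom profiles.
#' @return Data frame with columns `subject_id` (if present), `re_norm`,
#'   `avoid_norm`, `imbalance` in `[-1, 1]` and `symptom_sum` in `[0, 2]`.
#' @export
symptom_imbalance <- function(profiles) {
  require_columns(profiles, c("re_exp", "re_exp_min", "re_exp_max"),
                  "symptom profile table")
  av <- harmonize_avoidance(profiles)
  re_norm <- normalize_cluster(profiles$re_exp, profiles$re_exp_min,
                               profiles$re_exp_max, "re_exp")
  avoid_norm <- normalize_cluster(av$avoid, av$avoid_min, av$avoid_max, "avoid")
  out <- data.frame(re_norm = re_norm, avoid_norm = avoid_norm,
                    imbalance = avoid_norm - re_norm,
                    symptom_sum = re_norm + avoid_norm)
  if (!is.null(profiles$subject_id)) {
    out <- cbind(subject_id = profiles$subject_id, out)
  }
  out
}

#' Imbalance with dissociation-augmented avoidance
#'
#' Sensitivity variant in which the avoidance score is replaced by the sum
#' of avoidance and depersonalization/derealization scores (bounds summed
#' likewise) before normalization, reflecting the view that dissociative
#' symptoms also index the overmodulatory state.
#'
#' @inheritParams symptom_imbalance
#' @return As [symptom_imbalance()].
#' @export
augmented_avoidance <- function(profiles) {
  require_columns(profiles, c("depder", "depder_min", "depder_max"),
                  "symptom profile table")
  if (any(is.na(profiles$depder) | is.na(profiles$depder_min) |
            is.na(profiles$depder_max))) {
    abort_validation("depersonalization/derealization score or bounds absent; ",
                     "cannot compute augmented avoidance")
  }
  av <- harmonize_avoidance(profiles)
  aug <- profiles
  aug$dsm_version <- "IV"  # already harmonized; avoid double numbing add
  aug$avoid <- av$avoid + profiles$depder
  aug$avoid_min <- av$avoid_min + profiles$depder_min
  aug$avoid_max <- av$avoid_max + profiles$depder_max
  symptom_imbalance(aug)
}

#' Read a symptom-score table
#'
#' Reads the CSV interchange format for per-subject symptom-cluster scores:
#' header row with columns `subject_id, dsm_version, re_exp, re_exp_min,
#' re_exp_max, avoid, avoid_min, avoid_max, numb, numb_min, numb_max,
#' hyper, hyper_min, hyper_max, depder, depder_min, depder_max` (optional
#' columns may be empty).
#'
#' @param path Path to a CSV file.
#' @return Data frame of symptom profiles.
#' @export
read_symptom_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subject_id", "dsm_version",
                        "re_exp", "re_exp_min", "re_exp_max",
                        "avoid", "avoid_min", "avoid_max",
                        "hyper", "hyper_min", "hyper_max"),
                  basename(path))
  for (col in c("numb", "numb_min", "numb_max", "depder", "depder_min",
                "depder_max")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  df
}
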