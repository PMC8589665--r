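# Programmatic fixtures: complete b-CFS sessions and symptom profiles.

# One full 48-trial session (6 faces x 2 expressions x 4 positions).
make_session <- function(subject_id = "S1", rts = NULL, correct = TRUE) {
  g <- expand.grid(face_id = 1:6, expression = c("angry", "neutral"),
                   position = 1:4, stringsAsFactors = FALSE)
  if (is.null(rts)) rts <- 2000 + 10 * seq_len(nrow(g))
  data.frame(subject_id = subject_id, face_id = g$face_id,
             expression = g$expression, position = g$position,
             rt_ms = rep(rts, length.out = nrow(g)),
             correct = rep(correct, length.out = nrow(g)),
             stringsAsFactors = FALSE)
}

# A CAPS-like DSM-IV profile row.
make_profile <- function(subject_id = "S1", re = 20, avoid = 28, hyper = 20,
                         depder = 4) {
  data.frame(subject_id = subject_id, dsm_version = "IV",
             re_exp = re, re_exp_min = 0, re_exp_max = 40,
             avoid = avoid, avoid_min = 0, avoid_max = 56,
             numb = NA_real_, numb_min = NA_real_, numb_max = NA_real_,
             hyper = hyper, hyper_min = 0, hyper_max = 40,
             depder = depder, depder_min = 0, depder_max = 16,
             stringsAsFactors = FALSE)
}

# Study records lying on a known imbalance-outcome relationship.
make_meta_records <- function(imbalance, outcome,
                              outcome_kind = "tab_ms",
                              raw_stat_kind = "z", t_df = NA_real_,
                              is_ptsd = TRUE) {
  n <- length(imbalance)
  data.frame(study_id = sprintf("ST%02d", seq_len(n)),
             population_id = sprintf("P%02d", seq_len(n)),
             n = 30, is_ptsd = rep(is_ptsd, length.out = n),
             dsm_version = "IV",
             re_exp = (0.5 - imbalance / 2) * 40, re_exp_min = 0, re_exp_max = 40,
             avoid = (0.5 + imbalance / 2) * 56, avoid_min = 0, avoid_max = 56,
             numb = NA_real_, numb_min = NA_real_, numb_max = NA_real_,
             hyper = 20, hyper_min = 0, hyper_max = 40,
             depder = NA_real_, depder_min = NA_real_, depder_max = NA_real_,
             outcome_kind = outcome_kind,
             outcome_value = outcome,
             raw_stat_kind = rep(raw_stat_kind, length.out = n),
             t_df = rep(t_df, length.out = n),
             stringsAsFactors = FALSE)
}
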