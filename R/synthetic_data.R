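# Synthetic cohorts and meta tables with the statistical structure the
# analysis assumes: a two-state (emotional under-/overmodulatory) Markov
# process generates trial-level reaction times, symptom-cluster scores are
# coupled to state occupancy and severity, and study-level tables carry a
# planted imbalance-outcome correlation.

#' Configuration for a synthetic b-CFS cohort
#'
#' Parameters of the two-state generative model.  Each patient alternates
#' between an undermodulatory state (fast threat detection) and an
#' overmodulatory state (globally slowed detection) according to a
#' two-state Markov chain.  Each patient carries two independent depth
#' multipliers drawn from `severity_range`: `severity_under` scales how far
#' the under-state peak sits below baseline and how much faster angry faces
#' break suppression there; `severity_over` does the same for the
#' over-state peak and its threat slowdown.  A trial's expected reaction
#' time is
#' \deqn{base\_rt - (state\_offset/2) s_u [under] + (state\_offset/2) s_o [over]
#'   - \delta s_u [angry, under] + \delta s_o [angry, over]}
#' plus noise, with `delta = threat_effect`; the true peak separation is
#' `(state_offset / 2) * (severity_under + severity_over)`.  Per-patient
#' under-state occupancy is drawn from `occupancy_range`; symptom scores
#' are coupled to depth x occupancy (see [simulate_cohort()]).
#'
#' @param n_patients Number of patients (default 20, a typical clinical
#'   b-CFS sample).
#' @param n_faces,n_positions Task design (6 identities x 4 quadrants; a
#'   session is `n_faces * 2 * n_positions` trials).
#' @param markov_stay_prob State persistence in `[0, 1]`; transition
#'   probabilities are scaled so each patient's stationary under-state
#'   occupancy equals their drawn occupancy.
#' @param base_rt Baseline detection time, ms.
#' @param state_offset Peak separation at unit depths, ms.
#' @param threat_effect Threat-detection speedup/slowdown at unit depth, ms.
#' @param rt_noise_sd Trial noise SD, ms.
#' @param error_rate Probability of an incorrect response per trial.
#' @param coupling Depth-and-occupancy-to-symptom coupling on the
#'   normalized score scale (0 disables the state-symptom link).
#' @param symptom_noise_sd Noise SD on normalized symptom scores.
#' @param occupancy_range Range of per-patient under-state occupancies.
#' @param severity_range Range of the per-patient state-depth multipliers.
#' @param initial_state `"random"` (stationary draw), `"under"` or `"over"`.
#' @param rt_distribution `"gaussian"` (default; exact mixture-recovery
#'   oracles) or `"lognormal"` (robustness testing).
#' @param scale_bounds Named list of `c(min, max)` bounds for the generated
#'   CAPS-like clusters (`re_exp`, `avoid`, `hyper`, `depder`).
#' @param seed Master seed; every draw is a pure function of it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 20L, n_faces = 6L, n_positions = 4L,
                          markov_stay_prob = 0.8, base_rt = 2500,
                          state_offset = 600, threat_effect = 350,
                          rt_noise_sd = 150, error_rate = 0.02,
                          coupling = 0.5, symptom_noise_sd = 0.06,
                          occupancy_range = c(0.35, 0.60),
                          severity_range = c(0.7, 1.6),
                          initial_state = c("random", "under", "over"),
                          rt_distribution = c("gaussian", "lognormal"),
                          scale_bounds = list(re_exp = c(0, 40),
                                              avoid = c(0, 56),
                                              hyper = c(0, 40),
                                              depder = c(0, 16)),
                          seed = 1L) {
  initial_state <- match.arg(initial_state)
  rt_distribution <- match.arg(rt_distribution)
  if (markov_stay_prob < 0 || markov_stay_prob > 1) {
    abort_validation("markov_stay_prob must be in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 1) {
    abort_validation("error_rate must be in [0, 1]")
  }
  if (rt_noise_sd < 0 || symptom_noise_sd < 0) {
    abort_validation("noise SDs must be nonnegative")
  }
  if (threat_effect < 0) abort_validation("threat_effect must be nonnegative")
  if (any(occupancy_range < 0) || any(occupancy_range > 1)) {
    abort_validation("occupancy_range must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# One realization of the two-state chain; states are "under"/"over".
markov_states <- function(n, stay, occupancy, initial_state) {
  p_uo <- min(1, 2 * (1 - stay) * (1 - occupancy))  # under -> over
  p_ou <- min(1, 2 * (1 - stay) * occupancy)        # over  -> under
  s <- character(n)
  s[1] <- switch(initial_state,
                 under = "under",
                 over = "over",
                 random = if (stats::runif(1) < occupancy) "under" else "over")
  for (t in seq_len(n - 1)) {
    p_switch <- if (s[t] == "under") p_uo else p_ou
    s[t + 1] <- if (stats::runif(1) < p_switch) {
      if (s[t] == "under") "over" else "under"
    } else s[t]
  }
  s
}

#' Simulate one patient's b-CFS session
#'
#' Generates a full randomized session (`n_faces` x 2 expressions x
#' `n_positions` trials) with a latent two-state Markov sequence, together
#' with the patient's ground truth.  Deterministic given `(config, i)`:
#' the patient seed is derived from the master seed with [derive_seed()].
#'
#' @param config A [cohort_config()].
#' @param i Patient index (1-based).
#' @return List with `trials` (trial-table data frame) and `truth`
#'   (one-row data frame: `subject_id`, `severity_under`, `severity_over`,
#'   `occupancy_under`, `true_separation`, `states` in a list column).
#' @export
simulate_patient <- function(config, i) {
  stopifnot(inherits(config, "cohort_config"))
  subject_id <- sprintf("S%02d", i)
  n_trials <- config$n_faces * 2L * config$n_positions
  with_seed(derive_seed(config$seed, 101, i), {
    sev_u <- stats::runif(1, config$severity_range[1], config$severity_range[2])
    sev_o <- stats::runif(1, config$severity_range[1], config$severity_range[2])
    occ_target <- stats::runif(1, config$occupancy_range[1],
                               config$occupancy_range[2])
    grid <- expand.grid(face_id = seq_len(config$n_faces),
                        expression = c("angry", "neutral"),
                        position = seq_len(config$n_positions),
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(n_trials), ]
    states <- markov_states(n_trials, config$markov_stay_prob, occ_target,
                            config$initial_state)
    angry <- grid$expression == "angry"
    under <- states == "under"
    half <- config$state_offset / 2
    delta <- config$threat_effect
    mu <- config$base_rt +
      ifelse(under, -half * sev_u, half * sev_o) +
      delta * angry * ifelse(under, -sev_u, sev_o)
    rt <- if (config$rt_distribution == "gaussian") {
      mu + stats::rnorm(n_trials, 0, config$rt_noise_sd)
    } else {
      mu * stats::rlnorm(n_trials, 0, config$rt_noise_sd / config$base_rt)
    }
    rt <- pmax(rt, 150)  # detection times cannot be arbitrarily small
    correct <- stats::runif(n_trials) > config$error_rate
    trials <- data.frame(subject_id = subject_id, face_id = grid$face_id,
                         expression = grid$expression,
                         position = grid$position, rt_ms = rt,
                         correct = correct, state = states,
                         stringsAsFactors = FALSE)
    rownames(trials) <- NULL
    truth <- data.frame(subject_id = subject_id, severity_under = sev_u,
                        severity_over = sev_o,
                        occupancy_under = mean(under),
                        true_separation = half * (sev_u + sev_o),
                        stringsAsFactors = FALSE)
    truth$states <- list(states)
    list(trials = trials, truth = truth)
  })
}

#' Simulate a full cohort with coupled symptom scores
#'
#' Simulates `n_patients` sessions and draws CAPS-like symptom-cluster
#' scores coupled to each patient's realized state depths and occupancy:
#' on the normalized scale, re-experiencing increases with
#' `coupling * severity_under * (0.75 + 0.5 * occupancy(under))` and
#' avoidance with `coupling * severity_over * (0.75 + 0.5 *
#' occupancy(over))` (plus noise, clipped to the scale bounds), i.e.
#' symptom severity chiefly indexes how deep the corresponding state is,
#' modulated by how much time the patient spends in it; hypervigilance is
#' an uncoupled filler cluster and
#' depersonalization/derealization tracks the over-state depth weakly.
#' Thus symptom imbalance tracks the over-minus-under dominance while the
#' symptom sum tracks the combined state depth, which also sets the true
#' reaction-time peak separation.
#'
#' @param config A [cohort_config()].
#' @return List with `trials` (stacked trial table, including the latent
#'   `state` column), `profiles` (symptom table in the CSV schema) and
#'   `ground_truth` (per-patient truth data frame).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sims <- lapply(seq_len(config$n_patients), simulate_patient, config = config)
  trials <- do.call(rbind, lapply(sims, `[[`, "trials"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  sb <- config$scale_bounds
  profiles <- do.call(rbind, lapply(seq_len(config$n_patients), function(i) {
    with_seed(derive_seed(config$seed, 202, i), {
      occ <- truth$occupancy_under[i]
      re_true <- 0.15 + config$coupling * truth$severity_under[i] *
        (0.75 + 0.5 * occ)
      av_true <- 0.15 + config$coupling * truth$severity_over[i] *
        (0.75 + 0.5 * (1 - occ))
      nz <- function(mu, sd) clip01(mu + stats::rnorm(1, 0, sd))
      re_n <- nz(re_true, config$symptom_noise_sd)
      av_n <- nz(av_true, config$symptom_noise_sd)
      hy_n <- nz(0.45, 0.15)
      dd_n <- nz(0.15 + 0.4 * config$coupling * truth$severity_over[i],
                 0.08)
      data.frame(subject_id = truth$subject_id[i], dsm_version = "IV",
                 re_exp = sb$re_exp[1] + re_n * diff(sb$re_exp),
                 re_exp_min = sb$re_exp[1], re_exp_max = sb$re_exp[2],
                 avoid = sb$avoid[1] + av_n * diff(sb$avoid),
                 avoid_min = sb$avoid[1], avoid_max = sb$avoid[2],
                 numb = NA_real_, numb_min = NA_real_, numb_max = NA_real_,
                 hyper = sb$hyper[1] + hy_n * diff(sb$hyper),
                 hyper_min = sb$hyper[1], hyper_max = sb$hyper[2],
                 depder = sb$depder[1] + dd_n * diff(sb$depder),
                 depder_min = sb$depder[1], depder_max = sb$depder[2],
                 stringsAsFactors = FALSE)
    })
  }))
  truth$re_norm_true <- 0.15 + config$coupling * truth$severity_under *
    (0.75 + 0.5 * truth$occupancy_under)
  truth$avoid_norm_true <- 0.15 + config$coupling * truth$severity_over *
    (0.75 + 0.5 * (1 - truth$occupancy_under))
  rownames(trials) <- rownames(profiles) <- rownames(truth) <- NULL
  list(trials = trials, profiles = profiles, ground_truth = truth)
}

#' Configuration for a synthetic meta-analysis table
#'
#' @param n_studies Number of participant populations (>= 3).
#' @param target_rho Planted expected Pearson correlation between symptom
#'   imbalance and the outcome, in `[-1, 1]`.
#' @param outcome_kind `"tab_ms"`, `"amygdala_left"` or `"amygdala_right"`.
#' @param fraction_t For imaging outcomes, the fraction of populations
#'   reporting t-statistics (with drawn dfs) rather than z-scores.
#' @param df_range Range of drawn t degrees of freedom.
#' @param dsm_v_fraction Fraction of populations assessed under DSM-V
#'   (exercising the avoidance + numbing harmonization path).
#' @param ptsd_fraction Fraction of populations with a PTSD diagnosis.
#' @param seed Master seed.
#' @return A list of class `"meta_config"`.
#' @export
meta_config <- function(n_studies = 16L, target_rho = 0.55,
                        outcome_kind = OUTCOME_KINDS, fraction_t = 0.5,
                        df_range = c(10, 40), dsm_v_fraction = 0.5,
                        ptsd_fraction = 0.75, seed = 1L) {
  outcome_kind <- match.arg(outcome_kind, OUTCOME_KINDS)
  if (n_studies < 3) abort_validation("n_studies must be at least 3")
  if (abs(target_rho) > 1) abort_validation("target_rho must be in [-1, 1]")
  if (fraction_t < 0 || fraction_t > 1) {
    abort_validation("fraction_t must be in [0, 1]")
  }
  structure(as.list(environment()), class = "meta_config")
}

#' Simulate a study-level meta-analysis table
#'
#' Draws population symptom imbalances uniformly on `[-0.5, 0.5]` and
#' generates outcomes as `rho * imbalance / sd(imbalance) +
#' sqrt(1 - rho^2) * noise` (so the expected Pearson correlation equals
#' `target_rho`), then rescales to the outcome's natural units.  Cluster
#' means and bounds are emitted such that the harmonization path recovers
#' the planted imbalance exactly, with a configured fraction of DSM-V
#' populations (split avoidance/numbing) and, for imaging outcomes, of
#' t-statistic reports obtained by inverting [t_to_z()].
#'
#' @param config A [meta_config()].
#' @return List with `records` (study table in the CSV schema) and `truth`
#'   (data frame of planted `imbalance` and standardized clean outcome).
#' @export
simulate_meta_table <- function(config = meta_config()) {
  stopifnot(inherits(config, "meta_config"))
  n <- config$n_studies
  rho <- config$target_rho
  with_seed(derive_seed(config$seed, 303), {
    imb <- stats::runif(n, -0.5, 0.5)
    sd_pop <- sqrt(1 / 12)  # population SD of Uniform(-0.5, 0.5)
    std <- rho * imb / sd_pop + sqrt(1 - rho^2) * stats::rnorm(n)
    outcome <- if (config$outcome_kind == "tab_ms") {
      5 + 25 * std
    } else {
      1.5 + 1.0 * std
    }
    is_ptsd <- stats::runif(n) < config$ptsd_fraction
    if (sum(is_ptsd) < 3) is_ptsd[seq_len(3)] <- TRUE
    dsm_v <- stats::runif(n) < config$dsm_v_fraction
    re_norm <- 0.5 - imb / 2
    av_norm <- 0.5 + imb / 2
    use_t <- config$outcome_kind != "tab_ms" &
      stats::runif(n) < config$fraction_t
    t_df <- ifelse(use_t,
                   round(stats::runif(n, config$df_range[1],
                                      config$df_range[2])),
                   NA_real_)
    outcome_value <- outcome
    outcome_value[use_t] <- stats::qt(stats::pnorm(outcome[use_t]),
                                      t_df[use_t])
    records <- data.frame(
      study_id = sprintf("ST%02d", seq_len(n)),
      population_id = sprintf("P%02d", seq_len(n)),
      n = round(stats::runif(n, 15, 60)),
      is_ptsd = is_ptsd,
      dsm_version = ifelse(dsm_v, "V", "IV"),
      re_exp = re_norm * 40, re_exp_min = 0, re_exp_max = 40,
      avoid = ifelse(dsm_v, av_norm * 20, av_norm * 56),
      avoid_min = 0, avoid_max = ifelse(dsm_v, 20, 56),
      numb = ifelse(dsm_v, av_norm * 20, NA_real_),
      numb_min = ifelse(dsm_v, 0, NA_real_),
      numb_max = ifelse(dsm_v, 20, NA_real_),
      hyper = 20, hyper_min = 0, hyper_max = 40,
      depder = NA_real_, depder_min = NA_real_, depder_max = NA_real_,
      outcome_kind = config$outcome_kind,
      outcome_value = outcome_value,
      raw_stat_kind = ifelse(use_t, "t", "z"),
      t_df = t_df,
      stringsAsFactors = FALSE
    )
    list(records = records,
         truth = data.frame(imbalance = imb, outcome_std = std))
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact CSV dialects consumed by the scoring functions
#' (`trials.csv` without the latent state column, `symptoms.csv`) plus the
#' ground truth as JSON (never read by any analysis stage).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- cohort$trials[, c("subject_id", "face_id", "expression",
                              "position", "rt_ms", "correct")]
  paths <- c(trials = file.path(dir, "trials.csv"),
             symptoms = file.path(dir, "symptoms.csv"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(trials, paths["trials"], row.names = FALSE)
  utils::write.csv(cohort$profiles, paths["symptoms"], row.names = FALSE)
  truth <- cohort$ground_truth
  truth$states <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
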