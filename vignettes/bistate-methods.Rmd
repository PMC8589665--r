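---
title: "Methods: two-state analysis of attentional bias in PTSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state analysis of attentional bias in PTSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bistate)
```

## The model

`bistate` operationalizes a two-state view of PTSD: patients alternate
between an emotional *undermodulatory* state (threat is detected fast;
re-experiencing symptoms dominate) and an *overmodulatory* state (detection
is globally slowed; avoidance symptoms dominate).  Three observable
consequences organize the package:

1. **Symptom imbalance.** With cluster scores normalized to the unit
   interval of their instrument, the difference
   `imbalance = avoid_norm - re_norm` indexes which state dominates a
   patient, and the sum `re_norm + avoid_norm` indexes how deep the two
   states are in total.  DSM-IV instruments report one combined
   avoidance/numbing cluster; DSM-V instruments split it, so DSM-V
   avoidance and numbing scores (and their bounds) are summed before
   normalization.
2. **Attentional bias.** In a b-CFS session each angry face trial is paired
   with the neutral trial of the same face identity and screen position; the
   signed difference of the two suppression-breaking times is a dyad bias
   score.  The mean of all scores (TAB), the means of the positive and
   negative scores separately (AB_TOWARD, AB_AWAY), and their SDs summarize
   a patient's bias and its variability.
3. **Bimodality.** If states alternate within a session, the pooled
   reaction times of a patient should be bimodal.  The package fits 1- and
   2-component Gaussian mixtures, compares them by AIC, and quantifies the
   between-state separation as the distance between the two k-means cluster
   centers.

## Sign conventions

Two orientation choices interact and both are explicit in the API:

- The dyad score defaults to `rt_neutral - rt_angry` (`bias_sign =
  "toward_positive"`), so a positive score means the angry face reached
  awareness faster — a bias *toward* threat.  The literal convention
  `rt_angry - rt_neutral` is available as `"angry_minus_neutral"`;
  switching negates every score and TAB and swaps the toward/away class
  labels.
- Imbalance is `avoid_norm - re_norm`, i.e. overmodulation-positive.

Under the default convention the model therefore predicts TAB to *fall*
with imbalance (an avoidance-dominant patient detects threat slowly), and
the pipeline's one-tailed TAB–imbalance test is run in the negative
direction.  Under the literal convention TAB and imbalance share
orientation and the same association appears with a positive sign; scatter
plots and the acceptance script report that shared orientation because it
is the one in which both axes increase with overmodulation.

## Trial exclusion

Incorrect trials are removed, and a correct trial is removed when its
reaction time exceeds the mean of the *other* correct trials of its
condition (subject x expression) by more than 5 of their SDs.  The
leave-one-out form is deliberate: with the candidate trial included, the
largest attainable z-score in a sample of n is `(n - 1) / sqrt(n)` — about
4.69 at the 24 trials per condition of the standard design — so an
inclusive 5-SD rule could never fire at all.  The rule is one-sided (slow
tail only): unusually fast detections are part of the phenomenon under
study, not artifacts.  Exclusions at or above 3% of trials trigger a
warning, not an error.  Exact zero-valued dyad scores count toward TAB and
ABV but belong to neither sign class, since the classes are defined by
strict positivity/negativity; dyads that lost a member to exclusion are
dropped whole rather than imputed.

## Mixture fitting and the bimodality verdict

Reaction times enter the mixture on the raw millisecond scale after
*condition-mean normalization*: each expression condition is recentred onto
the pooled grand mean (`rt - mean_condition + grand_mean`), so that the
angry/neutral mean difference cannot masquerade as a second mode.  The
k = 1 fit is the closed-form Gaussian MLE (2 parameters).  The k = 2 fit
(5 parameters, unconstrained component variances) runs EM with 20 restarts,
tolerance 1e-6 on the log-likelihood, at most 500 iterations.  Two restarts
are deterministic: one starts *at* the k = 1 solution duplicated into both
components — a stationary point of EM, which guarantees the maximized
2-component log-likelihood never falls below the 1-component one — and one
splits it at the mean +/- 1 SD; the rest draw starting means from the data.
A restart whose components collapse (weight below 2/n, or variance below
1e-6 of the sample variance) is discarded as degenerate rather than allowed
to inflate the likelihood; if no restart survives, the fit is flagged
non-converged and the verdict is "indeterminate".

The verdict is "bimodal" only when `AIC(k=1) - AIC(k=2) > 2`, the
conventional margin for a meaningful AIC difference; otherwise "unimodal".
Because the parameter-count gap is fixed at 3, this is equivalent to
requiring the log-likelihood to improve by more than 4.

k-means (2 clusters, squared-Euclidean, 1-D) uses a *single* random
initialization per call on purpose: the initialization-to-initialization
variability of the peak distance is real, and the peak-distance vs
symptom-sum correlation is therefore recomputed over 100 independent
initializations (per-iteration and per-patient seeds derived
deterministically from one master seed) with the mean and range of r and p
reported.

## Inference

All correlation tests are one-tailed, reflecting directional hypotheses;
`p = P(T_{n-2} >= t_obs)` with `t_obs = r sqrt((n-2)/(1-r^2))`.  Variables
containing any observation more than 2 sample SDs from the mean are flagged
and re-tested with a Spearman rank correlation (average ranks for ties).
Stepwise regression standardizes all variables, enters at each step the
candidate with the largest |t| whose p < 0.05, and removes included
predictors whose p rises above 0.10 — conventional automatic-selection
thresholds; backward pruning is retained because a forward-only variant is
a special case (it never triggers in the package's test scenarios).
Coefficients for *unselected* candidates are reported by adding each alone
to the final selected model, which is how one table can display a beta for
every candidate.  No multiple-testing correction is applied anywhere; the
report instead carries the count of tests performed.  Group contrasts use
the pooled-variance t (df = n1 + n2 - 2) with Hedge's correction
`J = 1 - 3/(4 df - 1)`, and sample-size planning uses the normal
approximation `ceil(2 (z_{1-a/2} + z_{power})^2 / d^2)` with alpha = 0.05
two-tailed and power = 0.80 as defaults.

For meta tables, population means enter an unweighted Pearson correlation
(no inverse-variance weighting, no heterogeneity statistics — the analysis
is a correlation across populations, not an effect-size pooling).
t-statistics are converted by probability matching, `z = qnorm(pt(t, df))`,
computed on the log scale for tail accuracy and clamped at +/-8; left and
right amygdala populations are analyzed strictly separately.

## The synthetic-cohort generator

`simulate_cohort()` is a first-class module, not a test fixture: it encodes
the data-generating process the analysis presumes, so recovery of planted
structure is a meaningful check of the whole pipeline.

Each patient follows a two-state Markov chain across the 48 trials
(persistence `markov_stay_prob = 0.8`, transition probabilities scaled so
the stationary under-state occupancy matches a per-patient draw from
0.35–0.60).  Two independent per-patient depth multipliers from 0.7–1.6
govern the states: the under-state sits `severity_under * state_offset/2`
below the 2500 ms baseline with angry faces detected another
`severity_under * threat_effect` faster; the over-state mirrors this with
`severity_over`.  Defaults — 600 ms peak separation at unit depths, 350 ms
threat effect, 150 ms Gaussian trial noise, 2% error rate — give suppression
times in the 1.5–4 s range typical of b-CFS, an average peak separation
near 4.5 noise SDs (so most but not all patients earn a bimodal verdict),
and toward-trial percentages near 47%.

Symptom scores are drawn on the normalized scale as
`0.15 + coupling * depth * (0.75 + 0.5 * occupancy)` for the matching
cluster (re-experiencing from the under state, avoidance from the over
state) plus Gaussian noise, then mapped to CAPS-like bounds (0–40, 0–56,
0–40, 0–16).  Symptom severity thus chiefly indexes how deep the
corresponding state is, modulated by how much time the patient spends in
it.  The depth-dominant form is a deliberate choice: the magnitude-based
AB_TOWARD/AB_AWAY class means load *negatively* on own-state occupancy
through class composition (dyads that straddle the two states produce the
largest scores, and their share of a sign class grows with the opposite
state's occupancy), so a purely occupancy-driven symptom model cannot
produce the cluster-specific associations the analysis is designed to
detect — under this generator or, we conjecture, any random-pairing
two-state process.

With these couplings the generator plants exactly the structure the
pipeline estimates: TAB tracks -imbalance, AB_TOWARD loads on
re-experiencing and AB_AWAY on avoidance (with symmetric cross-talk from
the straddling dyads), and the true peak separation
`(state_offset/2)(severity_under + severity_over)` tracks the symptom sum.
The default coupling (0.5, noise SD 0.06) is a *realistic* regime in which
20-patient stepwise selection is unstable, as it is in comparable clinical
samples; the validation scenario labelled "strong coupling" (coupling 0.6,
noise SD 0.02, threat effect 600 ms) is used where tests must verify that
planted structure is recovered rather than how often it survives realistic
noise.

`simulate_meta_table()` plants an expected imbalance–outcome correlation
exactly: imbalances are uniform on [-0.5, 0.5] and the outcome is
`rho * imb / sd + sqrt(1 - rho^2) * noise`, rescaled to natural units, with
configurable fractions of DSM-V populations (exercising the
avoidance + numbing path) and of t-statistic reports (constructed by
inverting the t-to-z map, so harmonization recovers the planted values
exactly).

**What the generator does not emulate:** lognormal/skewed reaction-time
shapes (available behind `rt_distribution = "lognormal"` but not the
default, so that mixture-recovery tests have exact Gaussian oracles),
slow drifts or session-scale nonstationarity, item-level symptom structure,
comorbidity, and any neural dynamics — the Markov chain is the minimal
process consistent with state persistence and alternation, and its
trial-scale dwell times are a modeling convenience, not a claim about the
physiological time scale of state switching.  Passing recovery tests
therefore shows the *estimators* are faithful, not that real data satisfy
the generative assumptions.

## Numerical and validation choices

Validation problem sizes were chosen to make Monte-Carlo error small
relative to the asserted margins while keeping the default suite fast:
mixture operating characteristics use 200 replicates at the task's n = 48
(false-bimodal rate bounded below 25% — the AIC margin of 2 is a lenient
rule — and detection above 90% at 4-sigma separation); meta calibration
uses 500 replicate tables at 16 (behavioral) and 8 (imaging) populations,
recovering planted correlations within 0.05 including the usual
small-sample shrinkage of E[r]; null-coupling checks average 8–15 cohorts.
Oracle comparisons (explicit covariance formulas, trapezoidal integration
of the t density, bisection on the normal CDF) agree with the
implementation to 1e-6 on randomized small cases.

Degenerate inputs are handled explicitly: constant samples yield a
peak distance of 0 with a warning (not an error); a zero-SD variable has no
2-SD outliers by convention; identical paired error rates give t = 0,
p = 1; sign classes with fewer than 2 members report no SD.  All
randomness in the package flows through per-stage seeds derived from one
master seed by a deterministic integer mixer, so reports are byte-identical
across reruns and carry no timestamps.

## Limitations

The AIC rule with freely estimated variances is liberal; a patient with a
heavy-tailed but unimodal distribution can earn a bimodal verdict (the
package deliberately implements no dip test or k > 2 mixtures).  The
stepwise procedure has the usual liberal family-wise selection behavior
(measured at roughly 15% under the null with three candidates at n = 20),
which is reported as a property, not corrected away.  AB_TOWARD and
AB_AWAY are undefined for sessions whose dyad scores all share one sign,
and such subjects drop out of the corresponding regressions.  Meta-analytic
harmonization treats population means as plain values; between-study
differences in instruments beyond scale bounds, and in task variants, are
outside its scope.
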