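---
title: "Pathway-driven chronic-disease management: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-driven chronic-disease management: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronicare)
```

`chronicare` has two halves that deliberately mirror each other: a
rule-driven care-pathway engine that turns patient self-monitoring data into
management actions, and an evaluation stack that asks — on synthetic cohorts
with known ground truth — whether the statistical machinery used to assess
such systems retrospectively actually recovers what it should. This
vignette records the models, the defaults and their rationale, and the
design decisions that were genuinely open.

## The care-pathway model

Out-of-hospital management of hypertension (HTN), type 2 diabetes (T2DM)
and COPD shares a common task inventory: risk assessment, hierarchical
(level) management, regular follow-up, abnormal-condition intervention,
medication guidance, lifestyle guidance, health education, and compliance
management. Diagnosis happens in hospital before enrollment and is not an
engine task, so the engine enumerates exactly eight task kinds
(`task_kinds()`). The supported disease sets are the three single diseases
plus HTN+T2DM (labelled HM); COPD is managed alone.

Pathway knowledge is declarative: YAML rules with a trigger (periodic, with
a frequency in days, or event, gated on the uploading record kind), a
condition that is a conjunction of positive predicates over the published
fact schema (`fact_schema()`), and an action naming a task kind. The
evaluator (`evaluate_to_fixpoint()`) forward-chains: each pass fires every
applicable rule whose condition holds, inserts the fired tasks — which sets
`task.<kind>.exists` facts, so one task's generation can satisfy another
rule's condition — and repeats until a pass fires nothing.

Three semantic choices keep this well behaved:

* **Monotonicity.** Conditions cannot test for absence; absence tests are
  pre-computed boolean facts (e.g. `agg.no_bp_record_7d`). With positive
  conjunctions only, adding facts can only add derivable tasks, and the
  fixpoint is unique.
* **At-most-once firing.** Every fired instance carries a dedup key
  `task_kind : disease_scope : period-index` (for periodic rules the index
  is `floor(days_enrolled / frequency_days)`), and a key may appear at most
  once per fact base. The disease scope is part of the key so that, for a
  multimorbid patient, the HTN and T2DM rulesets can each stratify the
  patient in the same period without colliding; two rules of the *same*
  scope proposing the same task in the same period collapse to one
  instance. This bound also guarantees termination; a guard at
  `10 × n_rules` passes reports the firing cycle should a ruleset somehow
  defeat it.
* **Order-independence.** Facts update only between passes (simultaneous
  semantics) and the evaluator re-imposes the canonical order (priority
  descending, then rule id) on whatever ordering it is handed, so permuting
  a ruleset cannot change the derived task set.

Tasks may carry a valid duration; `expire_tasks()` prunes stale instances
and re-derives the existence facts, which is how a transient state (e.g. an
abnormal-condition intervention, valid 3 days) stops influencing later
inference.

## Disease-specific parameters

All thresholds live in `default_config()` and are overridable from YAML;
they are standard guideline values chosen as reasonable defaults, not
claims about any particular deployment, and every one of them is a tunable.

* **Targets.** BP < 140/90 mmHg (attainment = 7-day mean strictly below
  both); FBG < 7.0 and PBG < 10.0 mmol/L; PEF ≥ 80 % of personal best.
* **Urgent single values.** SBP ≥ 180, DBP ≥ 110, SBP < 90 or DBP < 60
  mmHg; glucose < 3.9 (hypoglycemia) or ≥ 16.7 mmol/L; any positive ketone;
  PEF < 60 % of personal best (< 80 % is a notice); any reported acute
  exacerbation. A CAT score ≥ 10 raises a scale warning. The weekly check
  fires when the trailing 7-day mean BP is at or above target with ≥ 3
  readings.
* **Levels.** HTN has two levels (I iff the window mean meets target).
  T2DM has three; the stated criterion — whether the patient reaches target
  glucose — is refined monotonically into: I = FBG and PBG both at target,
  II = exactly one, III = neither or any hypoglycemia event in the window
  (an unobserved component counts as at-target, since there is no evidence
  of failure). COPD has four levels taken directly from the risk category:
  the standard 2×2 grid of symptom burden (CAT ≥ 10 or PEF < 80 % of best)
  by exacerbation risk (≥ 2 exacerbations or ≥ 1 hospitalization in 12
  months), ordered I (neither), II (symptoms), III (risk), IV (both) by
  increasing intervention intensity.
* **Follow-up intervals.** HTN I = 90 days; HTN II defaults to 14 days and
  is configurable in [14, 28] — the intensive end of the plausible range,
  on the view that a freshly level-II patient warrants the closest
  attention. T2DM I/II/III = 90/30/14 days; COPD = 14 days at every level.
  Calendar arithmetic is plain day counts: "3 months" = 90 days, "1 month"
  = 30 days; dates are ISO-8601 and all windows are half-open `[start,
  end)`, so a record stamped exactly at a window's end belongs to the next
  window.
* **Compliance.** Fraction of scheduled self-monitoring items completed
  over a trailing 7-day window, updated daily; per-kind completions are
  capped at the scheduled count so over-reporting one kind cannot mask
  neglect of another. Below 0.5 the patient is flagged and an
  extra-follow-up compliance task is generated. Published guidance pins
  down neither the window nor the threshold, so both are exposed in the
  configuration.
* **Insufficient data.** Stratification wants ≥ 3 relevant readings in the
  window; with fewer, the patient is provisionally assigned the
  most-intensive level (II / III / IV). This mirrors the initial management
  period that precedes classification: new patients get close attention
  until the data say otherwise.
* **HTN risk factors.** Age above 55 (male) / 65 (female), smoking,
  obesity, diabetes comorbidity; target-organ damage forces the high
  category, otherwise the count maps 0 → low, 1–2 → moderate, ≥ 3 → high.

Multimorbid plans are merged conservatively (`merge_plans()`): minimum
follow-up interval, per-kind maximum monitoring frequency, set union of
lifestyle prescriptions with duplicates collapsed, and conflicts resolved by
the HM merge ruleset — when both an intensity-increasing and a moderate
exercise prescription are present, the moderate one (appropriate under
comorbidity) wins. Merging is idempotent and commutative; the single-plan
case returns its input unchanged.

## The cohort simulator

The simulator exists to give the evaluation stack inputs whose right answer
is known. Its defaults emulate a deployed telehealth cohort: age 58 (SD
12.3) years, 57.1 % male, disease mix 77.3 % HTN / 12.9 % T2DM / 4.4 %
HTN+T2DM / 5.4 % COPD, and disease-appropriate record streams (BP for
HTN/HM, glucose for T2DM/HM, peak flow plus a monthly CAT scale for COPD,
medication records for everyone) with submission gaps drawn from a
patient-level daily compliance probability (mean 0.7, SD 0.15).

Outcome dynamics are a patient baseline — SBP 145 (10) mmHg for
uncontrolled hypertension, FBG 8.5 (1.5) mmol/L, PEF 320 (40) L/min,
realistic ranges rather than calibrations to any particular dataset — plus
an AR(1) deviation (coefficient 0.7, the simplest model with realistic
day-to-day persistence) plus independent measurement noise (SBP 8 mmHg, FBG
1.0 mmol/L, PEF 25 L/min).

Treatment follows the four-confounder causal structure the evaluation
assumes: in each 30-day block, the probability of a provider intervention
is logistic in standardized age, ordinal management level, an
abnormal-warning indicator, and standardized management time (defaults
−0.5 intercept; 0.6, 0.5, 1.0, 0.4), and the same four variables enter the
outcome additively (for SBP: 4, 3, 5, −2 mmHg), so treated and control
episodes are genuinely confounded unless the propensity coefficients are
zeroed. Each completed intervention shifts the patient's baselines by the
configured true effect (defaults −5 mmHg SBP, −1.5 mmol/L FBG, +10 L/min
PEF) as a **step at the completion day**. A ramp spread over the following
month was considered and rejected: the treated episode outcome is defined
as the 30-day post-intervention mean, so a 30-day ramp would make the
episode-level estimand about half the configured effect and every
recovery check would be structurally biased against the documented ground
truth. The step keeps "true effect" and "estimand" the same number.

Two supporting outputs matter for evaluation. First, the simulator emits
the *system logs* a deployment database would hold — the stratification
history (`levels`) and the abnormal-warning records (`warnings`) — because
the retrospective analysis treats level and warning as observable
covariates; warning days are spread through the block (days 2, 12, 22) so
any 14-day episode window inside a block observes the block's warning
state. Second, `ground_truth` (true effects, latent baselines, the
treatment-assignment log with propensities) is written separately and is
never consumed by the engine or the estimators; tests use it only to
compare estimates against the truth.

`simulate_causal_episodes()` draws episode-level rows directly from the
same confounded model (confounders → logistic propensity → treatment;
outcome = baseline + confounder effects + treatment effect + noise). It is
the reference distribution for validating the estimators at scale without
paying for full trajectories; the trajectory-plus-extraction pipeline
exercises the identical structure end to end at smaller n.

What the simulator does **not** emulate: real missingness beyond the
stated compliance model (no weekend effects, no informative dropout),
provider behavior change over time, measurement-device error structure,
or outcome distributions calibrated to a specific deployment. Passing
tests therefore demonstrate the correctness of the machinery under the
assumed data-generating process, not the clinical effect of any real
system.

## The retrospective evaluation

**Before/after comparison.** For a span *s*, each patient's "before" mean
is taken over records in `[enrollment, enrollment + 14d)` and the "after"
mean over `[enrollment + s, enrollment + s + 14d)`; patients lacking
records in either window are excluded, and a two-sided paired *t* test is
applied to the per-patient means (`t = mean(d)/(sd(d)/sqrt(n))`, `df = n −
1`). Per-span p values are reported uncorrected for multiple testing — the
CLI output carries an explicit `p_value_adjusted = NA` column and metadata
noting this — and the package-wide significance convention is two-sided 5 %.

**Causal episodes.** Each completed intervention yields a treated episode
with outcome `Y` = mean outcome over `(t, t + 30d]`; controls are 14-day
intervention-free windows, at most one per patient per 30-day block,
placed seed-controlled to limit within-patient dependence. Confounders are
evaluated at the episode's start: age, latest recorded level (ordinal,
pooled across diseases), whether any abnormal warning fell in the episode
window (0/1), and days since enrollment. Episodes without outcome records
are dropped and counted.

**Estimators.** The propensity model is a main-effects logistic regression
on the four confounders (age and management time standardized). PSM is 1:1
nearest-neighbor matching on the score, with replacement, ties broken by
seed-controlled randomization, an optional caliper (off by default; when
on, a treated unit with no control inside it raises a positivity error);
the estimate averages treated-minus-matched-control differences over the
treated — the ATT, which equals the ATE under the homogeneous effects the
simulator generates and is reported in the ATE slot as is conventional for
this estimator. PSS cuts equal-frequency strata (5 by default), drops
strata missing either class (reported in diagnostics), and weights stratum
effects by stratum share of the retained sample. Degenerate propensity
fits are handled explicitly: fitted scores are clamped away from 0/1 by
1e-8, and a fit in which every treated unit sits at 1 and every control at
0 is rejected as perfect separation.

**Refutation checks.** `placebo_treatment` permutes the labels and expects
the re-estimate near zero; `random_common_cause` adds an independent
standard-normal covariate to the propensity model and expects the estimate
to barely move; `subset` re-estimates on random 80 % subsets and expects
stability. Default pass tolerance is 0.5 outcome units, configurable.

**Efficiency.** Per provider: the histogram of follow-up counts per active
day (an active day has ≥ 1 completed follow-up) and response days
(completion minus request) grouped by calendar month of the request,
summarized as median, quartiles and 1.5-IQR outliers.

## Numerical and testing choices

Randomness is always seeded explicitly: the simulator takes its seed from
the configuration, matching and refutation take seed arguments, and the
acceptance script threads one `--seed` through everything. Rule
tie-breaking, plan-merge ordering, and control-window placement are all
deterministic given the seed, so identical inputs yield byte-identical
outputs.

Problem sizes in the test suite are chosen to make Monte-Carlo conclusions
stable at interactive runtimes: estimator validation uses 5 000 episodes
from the episode-level generator (where the matching standard error is a
fraction of a mmHg), the end-to-end pipeline uses cohorts of 250–300
patients over 120 days (about 1 000 episodes; patient-level baselines
cluster the episodes, so the Monte-Carlo standard error there is about
1 mmHg, and tolerances are set accordingly), and distributional checks on
the cohort generator use 3 000 patients with a 3-binomial-SD band.

## Known limitations

* The rule dialect is intentionally small: positive conjunctions, scalar
  comparators, no arithmetic in conditions. Anything else must be
  pre-computed into the fact schema.
* Only the HTN+T2DM multimorbidity is supported end to end; other
  combinations are rejected at validation.
* COPD medication guidance is not generated by the engine (plans carry no
  engine medication items for COPD), matching the scope of the system the
  package models.
* The simulator's compounding interventions mean long-horizon cohorts
  drift downward in SBP; evaluation windows in the shipped analyses stay
  within horizons where this is the intended treated-minus-control
  contrast rather than an accumulation artifact.
* PSS retains the usual residual stratification bias (5 strata remove most
  but not all confounding); PSM with replacement has higher variance than
  1:k or caliper matching. Both behaviors are visible in the reported
  diagnostics rather than hidden.
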