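#' Simulation configuration
#'
#' Defaults emulate the deployed cohort: age 58 (SD 12.3) years, 57.1% male,
#' disease mix 77.3% hypertension / 12.9% type 2 diabetes / 4.4% HTN+T2DM /
#' 5.4% COPD.  Outcome trajectories are first-order autoregressive
#' deviations (AR coefficient 0.7) around a patient baseline — systolic BP
#' 145 (10) mmHg for uncontrolled hypertension, FBG 8.5 (1.5) mmol/L, PEF
#' 320 (40) L/min — with each completed intervention shifting the baseline
#' by the ground-truth treatment effect.  Treatment propensity is logistic
#' in the four confounders (standardized age, ordinal management level,
#' abnormal-warning indicator, standardized management time), which also
#' enter the outcome, so treated and control episodes are confounded unless
#' the propensity coefficients are zeroed.
#'
#' @param n_patients Number of patients.
#' @param disease_mix Probability vector over HTN, T2DM, HM, COPD.
#' @param age_mean,age_sd Age distribution, years.
#' @param male_fraction Fraction of male patients.
#' @param horizon_days Length of follow-up, days (>= 60).
#' @param true_ate Ground-truth treatment effect per outcome (SBP mmHg,
#'   FBG mmol/L, PEF L/min).
#' @param propensity_coefs Logistic coefficients of the four confounders on
#'   treatment (intercept, age, level, warning, mgmt_time); set the
#'   non-intercept terms to 0 for an unconfounded design.
#' @param outcome_coefs Per-outcome additive confounder effects on the
#'   outcome (age, level, warning, mgmt_time), in outcome units.
#' @param compliance_model Mean daily submission probability and its
#'   patient-level SD.
#' @param measurement_noise_sd Per-outcome measurement noise SD.
#' @param ar_coef AR(1) coefficient of the day-to-day deviations.
#' @param delay Provider response-delay distribution:
#'   `list(kind = "uniform", min, max)` or `list(kind = "constant", value)`.
#' @param n_providers Number of simulated care providers.
#' @param start_date Enrollment date of the cohort.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200,
                       disease_mix = c(HTN = 0.773, T2DM = 0.129,
                                       HM = 0.044, COPD = 0.054),
                       age_mean = 58, age_sd = 12.3, male_fraction = 0.571,
                       horizon_days = 180,
                       true_ate = c(SBP = -5, FBG = -1.5, PEF = 10),
                       propensity_coefs = c(intercept = -0.5, age = 0.6,
                                            level = 0.5, warning = 1.0,
                                            mgmt_time = 0.4),
                       outcome_coefs = list(
                         SBP = c(age = 4, level = 3, warning = 5,
                                 mgmt_time = -2),
                         FBG = c(age = 0.5, level = 0.4, warning = 0.6,
                                 mgmt_time = -0.2),
                         PEF = c(age = -15, level = -10, warning = -20,
                                 mgmt_time = 5)),
                       compliance_model = c(mean = 0.7, sd = 0.15),
                       measurement_noise_sd = c(SBP = 8, FBG = 1.0, PEF = 25),
                       ar_coef = 0.7,
                       delay = list(kind = "uniform", min = 1, max = 5),
                       n_providers = 3,
                       start_date = as.Date("2019-01-01"),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$disease_mix) - 1) > 1e-8)
    stop("disease_mix must sum to 1")
  if (!setequal(names(cfg$disease_mix), c("HTN", "T2DM", "HM", "COPD")))
    stop("disease_mix must be named over HTN, T2DM, HM, COPD")
  if (cfg$horizon_days < 60) stop("horizon_days must be >= 60")
  if (cfg$age_sd <= 0 || any(cfg$measurement_noise_sd < 0))
    stop("dispersion parameters must be positive")
  if (cfg$ar_coef < 0 || cfg$ar_coef >= 1)
    stop("ar_coef must lie in [0, 1)")
  invisible(cfg)
}

draw_delay <- function(n, delay) {
  switch(delay$kind,
    constant = rep(delay$value, n),
    uniform = sample(seq(delay$min, delay$max), n, replace = TRUE),
    stop("unknown delay distribution kind: ", delay$kind))
}

BASELINE_MEANS <- c(SBP = 145, FBG = 8.5, PEF = 320)
BASELINE_SDS <- c(SBP = 10, FBG = 1.5, PEF = 40)

outcome_for_group <- function(grp) {
  switch(grp, HTN = "SBP", T2DM = "FBG", HM = c("SBP", "FBG"), COPD = "PEF")
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Generates profiles, self-monitoring record streams, provider intervention
#' logs and a ground-truth manifest (true effects, latent baselines,
#' treatment-assignment log with the confounder values treatment was
#' assigned on).  Interventions are assigned per 30-day block with a
#' logistic propensity in the four confounders; each completed intervention
#' shifts the patient's outcome baselines by the ground-truth effect from
#' the completion day onward.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `profiles`, `records`,
#'   `interventions`, `levels` and `warnings` (the stratification and
#'   abnormal-warning system logs, observable to the estimators), and
#'   `ground_truth` (true effects and latents, never consumed by the engine
#'   or the estimators).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  groups <- sample(names(config$disease_mix), n, replace = TRUE,
                   prob = config$disease_mix)
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 20), 95)
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    dz <- switch(groups[i], HTN = "HTN", T2DM = "T2DM",
                 HM = c("HTN", "T2DM"), COPD = "COPD")
    patient_profile(
      patient_id = sprintf("P%04d", i), age = age[i], sex = sex[i],
      diseases = dz, enrollment_date = config$start_date,
      pef_personal_best = if (groups[i] == "COPD") 450 else NA_real_,
      smoking = stats::runif(1) < 0.3, obesity = stats::runif(1) < 0.2
    )
  }))
  # patient-level latents
  compliance_p <- pmin(pmax(stats::rnorm(n, config$compliance_model[["mean"]],
                                         config$compliance_model[["sd"]]),
                            0.05), 1)
  baselines <- data.frame(patient_id = profiles$patient_id,
                          SBP = stats::rnorm(n, BASELINE_MEANS["SBP"],
                                             BASELINE_SDS["SBP"]),
                          FBG = stats::rnorm(n, BASELINE_MEANS["FBG"],
                                             BASELINE_SDS["FBG"]),
                          PEF = stats::rnorm(n, BASELINE_MEANS["PEF"],
                                             BASELINE_SDS["PEF"]),
                          compliance_p = compliance_p,
                          stringsAsFactors = FALSE)

  # treatment assignment per 30-day block on the four confounders
  n_blocks <- config$horizon_days %/% 30
  age_z <- (age - config$age_mean) / config$age_sd
  tl <- list()
  for (i in seq_len(n)) {
    grp <- groups[i]
    prim <- outcome_for_group(grp)[1]
    level <- 1L + (baselines[[prim]][i] > BASELINE_MEANS[[prim]]) +
      (baselines[[prim]][i] > BASELINE_MEANS[[prim]] + BASELINE_SDS[[prim]])
    for (b in seq_len(n_blocks)) {
      t0 <- (b - 1L) * 30L
      warning_b <- stats::runif(1) < (0.15 + 0.15 * (level - 1))
      time_z <- (t0 - config$horizon_days / 2) / (config$horizon_days / 2)
      pc <- config$propensity_coefs
      p <- stats::plogis(pc[["intercept"]] + pc[["age"]] * age_z[i] +
                           pc[["level"]] * (level - 2) +
                           pc[["warning"]] * warning_b +
                           pc[["mgmt_time"]] * time_z)
      treated <- stats::runif(1) < p
      tl[[length(tl) + 1]] <- data.frame(
        patient_id = profiles$patient_id[i], block = b,
        block_start = t0, treated = treated, propensity = p,
        age = age[i], management_level = level,
        abnormal_warning = warning_b, management_time = t0,
        stringsAsFactors = FALSE)
    }
  }
  treatment_log <- do.call(rbind, tl)
  treated_rows <- treatment_log[treatment_log$treated, , drop = FALSE]
  interventions <- simulate_provider_log(treated_rows, config)

  # observable system logs the deployment database would hold: the
  # stratification history and the abnormal-warning records.  Warning days
  # are spread through the block (days 2, 12, 22) so that any 14-day episode
  # window inside the block observes the block's warning state.
  levels_log <- data.frame(
    patient_id = treatment_log$patient_id[treatment_log$block == 1],
    date = config$start_date,
    level = treatment_log$management_level[treatment_log$block == 1],
    stringsAsFactors = FALSE)
  wb <- treatment_log[treatment_log$abnormal_warning, , drop = FALSE]
  warnings_log <- data.frame(
    patient_id = rep(wb$patient_id, each = 3),
    raised_at = config$start_date +
      rep(wb$block_start, each = 3) + c(2, 12, 22),
    stringsAsFactors = FALSE)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    prow <- profiles[i, , drop = FALSE]
    latent <- list(
      baselines = as.list(baselines[i, c("SBP", "FBG", "PEF")]),
      compliance_p = compliance_p[i],
      shift_days = interventions$completed_day[
        interventions$patient_id == prow$patient_id]
    )
    records[[i]] <- simulate_trajectory(prow, latent, config)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  structure(list(
    profiles = profiles, records = records,
    interventions = interventions[, c("provider_id", "patient_id", "kind",
                                      "requested_at", "completed_at",
                                      "notes"), drop = FALSE],
    levels = levels_log, warnings = warnings_log,
    ground_truth = list(true_ate = config$true_ate, baselines = baselines,
                        treatment_log = treatment_log)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$profiles), "patients,", nrow(x$records),
      "records,", nrow(x$interventions), "interventions\n")
  invisible(x)
}

#' Simulate one patient's self-monitoring stream
#'
#' Record kinds follow the disease: blood pressure for HTN and HM, blood
#' glucose for T2DM and HM, peak flow plus CAT scale for COPD, and
#' medication for everyone; submission gaps follow the patient's latent
#' daily submission probability.  Outcome values are the (intervention-
#' shifted) baseline plus an AR(1) deviation plus measurement noise.
#' Consumes the current RNG stream (the caller seeds it).
#'
#' @param profile One profile row.
#' @param latent List with `baselines` (per-outcome), `compliance_p`
#'   (daily submission probability) and `shift_days` (days, relative to
#'   enrollment, on which a completed intervention shifts the baselines).
#' @param config A [sim_config()].
#' @return A record data.frame.
#' @export
simulate_trajectory <- function(profile, latent, config) {
  grp <- disease_group(profile)
  outs <- outcome_for_group(grp)
  days <- seq_len(config$horizon_days) - 1L
  shift <- vapply(days, function(d) sum(latent$shift_days <= d), numeric(1))
  dev <- list()
  for (o in outs) {
    innov_sd <- config$measurement_noise_sd[[o]] / 2
    e <- stats::rnorm(length(days), 0, innov_sd)
    dev[[o]] <- as.numeric(stats::filter(e, config$ar_coef,
                                         method = "recursive"))
  }
  submit <- stats::runif(length(days)) < latent$compliance_p
  j <- which(submit)
  if (!length(j)) return(empty_records())
  pid <- profile$patient_id
  base_ts <- as.POSIXct(profile$enrollment_date, tz = "UTC") +
    days[j] * 86400 + 8 * 3600
  mk <- function(kind, ts_offset, ...) {
    r <- data.frame(
      record_id = sprintf("%s-%s-%05d", pid, kind, seq_along(j)),
      patient_id = pid, timestamp = base_ts + ts_offset, kind = kind,
      sbp = NA_real_, dbp = NA_real_, heart_rate = NA_real_,
      bg_type = NA_character_, bg_value = NA_real_, ketone = NA,
      pef = NA_real_, scale = NA_character_, score = NA_real_,
      detail = NA_character_, stringsAsFactors = FALSE)
    v <- list(...)
    for (nm in names(v)) r[[nm]] <- v[[nm]]
    r
  }
  parts <- list()
  if ("SBP" %in% outs) {
    sbp <- pmax(latent$baselines$SBP + shift[j] * config$true_ate[["SBP"]] +
                  dev$SBP[j] +
                  stats::rnorm(length(j), 0,
                               config$measurement_noise_sd[["SBP"]]), 75)
    dbp <- pmax(pmin(0.62 * sbp + stats::rnorm(length(j), 0, 4), sbp - 10), 40)
    parts$bp <- mk("BP", 0, sbp = round(sbp, 1), dbp = round(dbp, 1),
                   heart_rate = round(stats::rnorm(length(j), 72, 8)))
  }
  if ("FBG" %in% outs) {
    fbg <- latent$baselines$FBG + shift[j] * config$true_ate[["FBG"]] +
      dev$FBG[j] +
      stats::rnorm(length(j), 0, config$measurement_noise_sd[["FBG"]])
    parts$bg <- mk("BG", 600, bg_type = "FBG",
                   bg_value = round(pmax(fbg, 2.5), 1), ketone = FALSE)
  }
  if ("PEF" %in% outs) {
    pef <- latent$baselines$PEF + shift[j] * config$true_ate[["PEF"]] +
      dev$PEF[j] +
      stats::rnorm(length(j), 0, config$measurement_noise_sd[["PEF"]])
    parts$pef <- mk("PEF", 1200, pef = round(pmax(pef, 60), 1))
    monthly <- days[j] %% 30 == 0
    if (any(monthly)) {
      cat_scores <- pmin(pmax(round(stats::rnorm(sum(monthly), 12, 6)), 0), 40)
      p <- mk("psychological", 1800, scale = "CAT",
              score = NA_real_)[monthly, , drop = FALSE]
      p$score <- cat_scores
      p$record_id <- sprintf("%s-CAT-%05d", pid, seq_len(nrow(p)))
      parts$cat <- p
    }
  }
  parts$med <- mk("medication", 2400, detail = "taken_as_prescribed")
  out <- do.call(rbind, parts)
  out <- out[order(out$timestamp, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  validate_records(out)
  out
}

#' Simulate the provider intervention log
#'
#' Assigns each follow-up request to a provider (round-robin over patients)
#' and draws a completion delay from the configured distribution; all delays
#' are non-negative.
#'
#' @param requests Data.frame with `patient_id` and `block_start` (request
#'   day relative to enrollment), typically the treated rows of the
#'   ground-truth treatment log.
#' @param config A [sim_config()].
#' @return Intervention data.frame: `provider_id`, `patient_id`, `kind`,
#'   `requested_at`, `completed_at`, `notes`, plus `completed_day` (days
#'   since enrollment) used internally by the trajectory simulator.
#' @export
simulate_provider_log <- function(requests, config = sim_config()) {
  m <- nrow(requests)
  if (!m) {
    return(data.frame(provider_id = character(0), patient_id = character(0),
                      kind = character(0),
                      requested_at = as.Date(character(0)),
                      completed_at = as.Date(character(0)),
                      notes = character(0), completed_day = numeric(0),
                      stringsAsFactors = FALSE))
  }
  providers <- sprintf("GP%02d", seq_len(config$n_providers))
  prov_of_patient <- stats::setNames(
    providers[(as.integer(factor(unique(requests$patient_id))) - 1) %%
                config$n_providers + 1],
    unique(requests$patient_id))
  delays <- draw_delay(m, config$delay)
  requested <- config$start_date + requests$block_start
  data.frame(
    provider_id = unname(prov_of_patient[requests$patient_id]),
    patient_id = requests$patient_id, kind = "regular_followup",
    requested_at = requested, completed_at = requested + delays,
    notes = "pathway follow-up",
    completed_day = requests$block_start + delays,
    stringsAsFactors = FALSE
  )
}

#' Draw ground-truth causal episodes from the confounded outcome model
#'
#' Generates episode-level data directly from the causal graphical model the
#' retrospective evaluation assumes: the four confounders (age, management
#' level, abnormal warning, management time) affect both the treatment
#' propensity (logistic) and the outcome (additive), and treatment shifts
#' the outcome by the ground-truth effect.  This is the reference
#' distribution for validating the propensity-score estimators at scale;
#' the full trajectory simulator exercises the same structure end to end.
#'
#' @param n Number of episodes.
#' @param config A [sim_config()]; `propensity_coefs`, `outcome_coefs` and
#'   `true_ate` are used.
#' @param outcome Which outcome to generate (`"SBP"`, `"FBG"`, `"PEF"`).
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A data.frame of class `causal_data` with columns `treatment`,
#'   `outcome`, `age`, `management_level`, `abnormal_warning`,
#'   `management_time`; the true effect is attached as attribute
#'   `"true_ate"`.
#' @export
simulate_causal_episodes <- function(n, config = sim_config(),
                                     outcome = "SBP", seed = NULL) {
  set.seed(seed %||% config$seed)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 20), 95)
  level <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mgmt_time <- stats::runif(n, 0, config$horizon_days)
  age_z <- (age - config$age_mean) / config$age_sd
  time_z <- (mgmt_time - config$horizon_days / 2) / (config$horizon_days / 2)
  pc <- config$propensity_coefs
  warning_ <- stats::runif(n) < (0.15 + 0.15 * (level - 1))
  p <- stats::plogis(pc[["intercept"]] + pc[["age"]] * age_z +
                       pc[["level"]] * (level - 2) +
                       pc[["warning"]] * warning_ + pc[["mgmt_time"]] * time_z)
  treated <- stats::runif(n) < p
  oc <- config$outcome_coefs[[outcome]]
  base <- BASELINE_MEANS[[outcome]]
  y <- base + oc[["age"]] * age_z + oc[["level"]] * (level - 2) +
    oc[["warning"]] * warning_ + oc[["mgmt_time"]] * time_z +
    treated * config$true_ate[[outcome]] +
    stats::rnorm(n, 0, config$measurement_noise_sd[[outcome]])
  out <- data.frame(treatment = treated, outcome = y, age = age,
                    management_level = level, abnormal_warning = warning_,
                    management_time = mgmt_time, stringsAsFactors = FALSE)
  attr(out, "true_ate") <- unname(config$true_ate[[outcome]])
  class(out) <- c("causal_data", class(out))
  out
}
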