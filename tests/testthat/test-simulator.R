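test_that("simulation is seed-reproducible and validates its config", {
  cfg <- sim_config(n_patients = 30, horizon_days = 60, seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  expect_error(sim_config(disease_mix = c(HTN = 0.6, T2DM = 0.2,
                                          HM = 0.1, COPD = 0.2)), "sum to 1")
  expect_error(sim_config(horizon_days = 30), ">= 60")
  expect_error(sim_config(ar_coef = 1.2), "ar_coef")
})

test_that("disease mix matches the configured proportions", {
  cfg <- sim_config(n_patients = 3000, horizon_days = 60, seed = 12)
  # only the profile draw matters here; silence the heavy parts via a short
  # horizon and check counts within 3 binomial standard deviations
  co <- simulate_cohort(cfg)
  counts <- table(factor(disease_group(co$profiles),
                         levels = names(cfg$disease_mix)))
  for (g in names(cfg$disease_mix)) {
    expected <- cfg$n_patients * cfg$disease_mix[[g]]
    sd3 <- 3 * sqrt(expected * (1 - cfg$disease_mix[[g]]))
    expect_lt(abs(counts[[g]] - expected), sd3 + 1)
  }
  # demographics land near the configured moments
  expect_equal(mean(co$profiles$age), 58, tolerance = 0.03)
  expect_equal(mean(co$profiles$sex == "male"), 0.571, tolerance = 0.1)
})

test_that("record kinds follow the disease and the compliance model", {
  cfg <- sim_config(n_patients = 40, horizon_days = 60, seed = 13)
  co <- simulate_cohort(cfg)
  grp <- setNames(disease_group(co$profiles), co$profiles$patient_id)
  rg <- grp[co$records$patient_id]
  # COPD patients submit no BP or BG; single-disease patients no foreign kinds
  expect_identical(sum(co$records$kind %in% c("BP", "BG") & rg == "COPD"), 0L)
  expect_identical(sum(co$records$kind == "BG" & rg == "HTN"), 0L)
  expect_identical(sum(co$records$kind == "BP" & rg == "T2DM"), 0L)
  expect_identical(sum(co$records$kind == "PEF" & rg != "COPD"), 0L)

  # conservation: total counts equal the sum of per-patient counts
  per_patient <- table(co$records$patient_id)
  expect_identical(sum(per_patient), nrow(co$records))
  expect_identical(
    as.integer(table(factor(rg, levels = c("HTN", "T2DM", "HM", "COPD")))),
    as.integer(colSums(descriptive_summary(co$profiles,
                                           co$records)$record_counts)))

  # full compliance: one record of each scheduled kind per day
  cfg2 <- sim_config(n_patients = 3, horizon_days = 60, seed = 14,
                     compliance_model = c(mean = 1, sd = 0))
  co2 <- simulate_cohort(cfg2)
  htn_ids <- co2$profiles$patient_id[disease_group(co2$profiles) == "HTN"]
  for (pid in htn_ids) {
    bp <- co2$records[co2$records$patient_id == pid &
                        co2$records$kind == "BP", ]
    expect_identical(nrow(bp), 60L)
    expect_identical(length(unique(as.Date(bp$timestamp))), 60L)
  }
})

test_that("zero noise and no interventions give a flat trajectory", {
  cfg <- sim_config(n_patients = 5, horizon_days = 60, seed = 15,
                    measurement_noise_sd = c(SBP = 0, FBG = 0, PEF = 0),
                    propensity_coefs = c(intercept = -20, age = 0, level = 0,
                                         warning = 0, mgmt_time = 0),
                    compliance_model = c(mean = 1, sd = 0))
  co <- simulate_cohort(cfg)
  expect_identical(nrow(co$interventions), 0L)
  for (pid in co$profiles$patient_id[disease_group(co$profiles) %in%
                                       c("HTN", "HM")]) {
    sbp <- co$records$sbp[co$records$patient_id == pid &
                            co$records$kind == "BP"]
    base <- co$ground_truth$baselines$SBP[
      co$ground_truth$baselines$patient_id == pid]
    expect_equal(sd(sbp), 0, tolerance = 1e-9)
    expect_equal(sbp[1], round(pmax(base, 75), 1), tolerance = 0.06)
  }
})

test_that("provider log conserves requests and draws the configured delays", {
  reqs <- data.frame(patient_id = rep(sprintf("P%02d", 1:20), each = 5),
                     block_start = rep(seq(0, 120, by = 30), 20))
  cfg0 <- sim_config(n_patients = 20, horizon_days = 150, seed = 16,
                     delay = list(kind = "constant", value = 0))
  set.seed(1)
  log0 <- simulate_provider_log(reqs, cfg0)
  expect_identical(nrow(log0), nrow(reqs))
  expect_true(all(log0$completed_at == log0$requested_at))

  cfg5 <- sim_config(n_patients = 20, horizon_days = 150, seed = 16,
                     delay = list(kind = "uniform", min = 1, max = 5))
  set.seed(2)
  log5 <- simulate_provider_log(reqs, cfg5)
  delays <- as.numeric(log5$completed_at - log5$requested_at)
  expect_true(all(delays >= 1 & delays <= 5))
  se <- sd(delays) / sqrt(length(delays))
  expect_lt(abs(mean(delays) - 3), 3 * se + 1e-9)

  # a provider with 16 requests on one day completes 16 follow-ups
  burst <- data.frame(patient_id = "P01", block_start = rep(30, 16))
  set.seed(3)
  lb <- simulate_provider_log(burst, cfg0)
  expect_identical(nrow(lb), 16L)
  expect_identical(length(unique(lb$completed_at)), 1L)
})

test_that("null effect and no confounding give a null contrast; injected effect is recovered", {
  # null calibration: no effect, no confounding
  cfg0 <- sim_config(n_patients = 250, horizon_days = 120, seed = 17,
                     true_ate = c(SBP = 0, FBG = 0, PEF = 0),
                     propensity_coefs = c(intercept = -0.5, age = 0,
                                          level = 0, warning = 0,
                                          mgmt_time = 0))
  co0 <- simulate_cohort(cfg0)
  rows0 <- extract_causal_dataset(co0$records, co0$interventions,
                                  co0$profiles, levels = co0$levels,
                                  warnings = co0$warnings,
                                  outcome = "SBP", seed = 17)
  expect_lt(abs(estimate_ate_naive(rows0)$estimate), 1.0)

  # effect injection without confounding: the difference in means recovers
  # the ground truth within Monte-Carlo error (patient-level baselines
  # cluster the episodes, so the MC standard error is about 1 mmHg here)
  cfg1 <- sim_config(n_patients = 250, horizon_days = 120, seed = 18,
                     propensity_coefs = c(intercept = -0.5, age = 0,
                                          level = 0, warning = 0,
                                          mgmt_time = 0))
  co1 <- simulate_cohort(cfg1)
  rows1 <- extract_causal_dataset(co1$records, co1$interventions,
                                  co1$profiles, levels = co1$levels,
                                  warnings = co1$warnings,
                                  outcome = "SBP", seed = 18)
  expect_lt(abs(estimate_ate_naive(rows1)$estimate - (-5)), 2.5)
})
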