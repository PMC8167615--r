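# Windowed aggregates of a patient's records.  All windows are half-open
# [start, end): a record timestamped exactly at `as_of` belongs to the next
# window, not this one.

in_window <- function(ts, start, end) {
  d <- as.Date(ts)
  d >= as.Date(start) & d < as.Date(end)
}

patient_window <- function(records, patient_id, as_of, window_days = 7) {
  as_of <- as.Date(as_of)
  r <- records[records$patient_id == patient_id &
                 in_window(records$timestamp, as_of - window_days, as_of), ,
               drop = FALSE]
  r
}

#' Compute the fact values for one patient
#'
#' Builds the named fact list the rule evaluator consumes: profile fields,
#' trailing 7-day aggregates of the patient's self-monitoring records,
#' 12-month exacerbation counts, and the pre-computed absence flags.
#'
#' @param profile One profile row.
#' @param records Record table (all patients; filtered internally).
#' @param as_of Evaluation date.
#' @param compliance Optional latest compliance state for the patient.
#' @param open_warnings Optional data.frame of the patient's open warnings.
#' @return Named list of facts keyed by [fact_schema()] paths.
#' @export
patient_facts <- function(profile, records, as_of, compliance = NULL,
                          open_warnings = NULL) {
  as_of <- as.Date(as_of)
  dz <- patient_diseases(profile)
  grp <- disease_group(profile)
  w <- patient_window(records, profile$patient_id, as_of, 7)
  facts <- list(
    "profile.age" = profile$age,
    "profile.sex" = profile$sex,
    "profile.education" = profile$education,
    "profile.has_htn" = "HTN" %in% dz,
    "profile.has_t2dm" = "T2DM" %in% dz,
    "profile.has_copd" = "COPD" %in% dz,
    "profile.has_hm" = grp == "HM",
    "profile.smoking" = isTRUE(profile$smoking),
    "profile.obesity" = isTRUE(profile$obesity),
    "profile.organ_damage" = isTRUE(profile$organ_damage),
    "mgmt.days_enrolled" = as.numeric(as_of - profile$enrollment_date)
  )
  bp <- w[w$kind == "BP", , drop = FALSE]
  facts[["agg.bp_n_7d"]] <- nrow(bp)
  facts[["agg.no_bp_record_7d"]] <- nrow(bp) == 0
  if (nrow(bp)) {
    facts[["agg.sbp_mean_7d"]] <- mean(bp$sbp)
    facts[["agg.dbp_mean_7d"]] <- mean(bp$dbp)
  }
  bg <- w[w$kind == "BG", , drop = FALSE]
  facts[["agg.bg_n_7d"]] <- nrow(bg)
  facts[["agg.no_bg_record_7d"]] <- nrow(bg) == 0
  if (nrow(bg)) {
    fbg <- bg$bg_value[bg$bg_type == "FBG"]
    pbg <- bg$bg_value[bg$bg_type == "PBG"]
    if (length(fbg)) facts[["agg.fbg_mean_7d"]] <- mean(fbg)
    if (length(pbg)) facts[["agg.pbg_mean_7d"]] <- mean(pbg)
    facts[["agg.hypoglycemia_7d"]] <- any(bg$bg_value < 3.9)
  }
  pef <- w[w$kind == "PEF", , drop = FALSE]
  facts[["agg.pef_n_7d"]] <- nrow(pef)
  facts[["agg.no_pef_record_7d"]] <- nrow(pef) == 0
  if (nrow(pef)) {
    facts[["agg.pef_mean_7d"]] <- mean(pef$pef)
    if (!is.na(profile$pef_personal_best))
      facts[["agg.pef_pct_best"]] <-
        100 * mean(pef$pef) / profile$pef_personal_best
  }
  yr <- patient_window(records, profile$patient_id, as_of, 365)
  psych <- yr[yr$kind == "psychological" & !is.na(yr$scale) &
                yr$scale == "CAT", , drop = FALSE]
  if (nrow(psych))
    facts[["agg.cat_latest"]] <-
      psych$score[which.max(as.numeric(psych$timestamp))]
  dis <- yr[yr$kind == "discomfort" & !is.na(yr$detail), , drop = FALSE]
  facts[["agg.exacerbations_12m"]] <- sum(dis$detail == "acute_exacerbation")
  facts[["agg.hospitalizations_12m"]] <- sum(dis$detail == "hospitalization")
  if (!is.null(compliance)) {
    facts[["compliance.value"]] <- compliance$compliance
    facts[["compliance.low"]] <- isTRUE(compliance$flagged_low)
  }
  if (!is.null(open_warnings)) {
    facts[["warning.open_count"]] <- nrow(open_warnings)
    facts[["warning.any_urgent"]] <-
      nrow(open_warnings) > 0 && any(open_warnings$severity == "urgent")
  }
  facts
}
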