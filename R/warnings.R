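empty_warnings <- function() {
  data.frame(
    warning_id = character(0), patient_id = character(0), kind = character(0),
    severity = character(0), evidence = character(0),
    raised_at = as.POSIXct(character(0), tz = "UTC"), status = character(0),
    stringsAsFactors = FALSE
  )
}

warning_row <- function(patient_id, kind, severity, evidence, raised_at) {
  data.frame(
    warning_id = sprintf("W-%s-%s-%s", patient_id, kind,
                         format(as.POSIXct(raised_at, tz = "UTC"),
                                "%Y%m%d%H%M%S")),
    patient_id = patient_id, kind = kind, severity = severity,
    evidence = evidence, raised_at = as.POSIXct(raised_at, tz = "UTC"),
    status = "open", stringsAsFactors = FALSE
  )
}

#' Abnormal-condition warning detection
#'
#' Applies the single-value checks to each record and the weekly-aggregate
#' check to the trailing 7-day blood-pressure window.  Default thresholds
#' (all configurable): urgent single BP at SBP >= 180, DBP >= 110, SBP < 90
#' or DBP < 60 mmHg; hypoglycemia below 3.9 and severe hyperglycemia at or
#' above 16.7 mmol/L; a positive ketone flag is urgent; peak flow below 80%
#' of personal best is a notice and below 60% urgent; a CAT score of 10 or
#' more raises a scale warning; any reported acute exacerbation is urgent.
#' The weekly check fires when the 7-day mean BP is at or above target with
#' at least 3 readings.
#'
#' @param records Records to check (single uploaded record or a window);
#'   must belong to `profile`.
#' @param profile One profile row.
#' @param as_of Evaluation datetime; the weekly window is
#'   `[as_of - 7d, as_of)`.
#' @param config Engine configuration.
#' @param weekly Whether to run the weekly-aggregate check (the on-upload
#'   path checks single values only).
#' @return A data.frame of warnings (zero rows when nothing fires).
#' @export
detect_warnings <- function(records, profile, as_of,
                            config = default_config(), weekly = TRUE) {
  if (nrow(records) && !all(records$patient_id == profile$patient_id))
    stop("records do not belong to patient ", profile$patient_id)
  dz <- patient_diseases(profile)
  th <- config$warnings
  out <- empty_warnings()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok_kind <- switch(r$kind,
      BP = "HTN" %in% dz, BG = "T2DM" %in% dz,
      PEF = "COPD" %in% dz, psychological = "COPD" %in% dz,
      TRUE)
    if (!ok_kind)
      stop("record kind ", r$kind, " inconsistent with diseases of patient ",
           profile$patient_id)
    w <- NULL
    if (r$kind == "BP") {
      if (r$sbp >= th$bp_urgent[["sbp_high"]] ||
          r$dbp >= th$bp_urgent[["dbp_high"]] ||
          r$sbp < th$bp_urgent[["sbp_low"]] ||
          r$dbp < th$bp_urgent[["dbp_low"]])
        w <- warning_row(r$patient_id, "single_value", "urgent",
                         r$record_id, r$timestamp)
    } else if (r$kind == "BG") {
      if (r$bg_value < th$bg_hypo || r$bg_value >= th$bg_severe)
        w <- warning_row(r$patient_id, "single_value", "urgent",
                         r$record_id, r$timestamp)
      if (isTRUE(r$ketone))
        w <- rbind(w, warning_row(r$patient_id, "ketone", "urgent",
                                  r$record_id, r$timestamp))
    } else if (r$kind == "PEF" && !is.na(profile$pef_personal_best)) {
      pct <- 100 * r$pef / profile$pef_personal_best
      if (pct < th$pef_urgent_pct)
        w <- warning_row(r$patient_id, "single_value", "urgent",
                         r$record_id, r$timestamp)
      else if (pct < th$pef_notice_pct)
        w <- warning_row(r$patient_id, "single_value", "notice",
                         r$record_id, r$timestamp)
    } else if (r$kind == "psychological" && !is.na(r$scale) &&
                 r$scale == "CAT") {
      if (r$score >= th$cat_threshold)
        w <- warning_row(r$patient_id, "scale", "notice",
                         r$record_id, r$timestamp)
    } else if (r$kind == "discomfort" && !is.na(r$detail) &&
                 r$detail == "acute_exacerbation") {
      w <- warning_row(r$patient_id, "acute_exacerbation", "urgent",
                       r$record_id, r$timestamp)
    }
    if (!is.null(w)) out <- rbind(out, w)
  }
  if (weekly && "HTN" %in% dz) {
    bp <- patient_window(records, profile$patient_id, as_of, 7)
    bp <- bp[bp$kind == "BP", , drop = FALSE]
    if (nrow(bp) >= th$weekly_min_readings &&
        (mean(bp$sbp) >= profile$sbp_target ||
           mean(bp$dbp) >= profile$dbp_target))
      out <- rbind(out, warning_row(
        profile$patient_id, "weekly_aggregate", "notice",
        sprintf("7d mean %.1f/%.1f over %d readings",
                mean(bp$sbp), mean(bp$dbp), nrow(bp)),
        as.POSIXct(as.Date(as_of), tz = "UTC")))
  }
  rownames(out) <- NULL
  out
}

#' Daily compliance update
#'
#' Compliance is the fraction of scheduled self-monitoring items the patient
#' completed over the trailing window (default 7 days).  The schedule comes
#' from the patient's management plan; per-kind completions are capped at
#' the scheduled count so over-reporting one kind cannot mask another.
#' Compliance below the configured threshold (default 0.5) flags the patient
#' and emits an extra-follow-up compliance-management task.
#'
#' @param plan A `management_plan` with a non-empty monitoring schedule.
#' @param records Record table for the patient.
#' @param date Evaluation date; window is `[date - window, date)`.
#' @param config Engine configuration.
#' @return A list of class `compliance_state`: `patient_id`, `date`,
#'   `scheduled_tasks`, `completed_tasks`, `compliance`, `flagged_low`, and
#'   `task` (an extra-follow-up task, `NULL` unless flagged).
#' @export
update_compliance <- function(plan, records, date,
                              config = default_config()) {
  sched <- plan$self_plan$monitoring_schedule
  window <- config$compliance$window_days
  expected <- vapply(sched, function(per_week) max(1, round(per_week * window / 7)),
                     numeric(1))
  if (!length(expected) || sum(expected) == 0)
    stop("management plan has an empty monitoring schedule")
  pid <- plan$patient_id
  w <- patient_window(records, pid, date, window)
  completed <- vapply(names(sched), function(k)
    min(sum(w$kind == k), expected[[k]]), numeric(1))
  compliance <- sum(completed) / sum(expected)
  flagged <- compliance < config$compliance$low_threshold
  task <- NULL
  if (flagged)
    task <- list(task_kind = "ComplianceManagement", patient_id = pid,
                 generated_at = as.Date(date),
                 payload = list(action = "extra_followup",
                                compliance = compliance))
  structure(list(patient_id = pid, date = as.Date(date),
                 scheduled_tasks = sum(expected),
                 completed_tasks = sum(completed),
                 compliance = compliance, flagged_low = flagged,
                 task = task),
            class = "compliance_state")
}
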