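LIFESTYLE_SETS <- list(
  HTN = c("reduce_sodium", "control_weight", "no_smoking_drinking",
          "increase_exercise", "reduce_stress"),
  T2DM = c("control_weight", "balanced_diet", "reduce_sodium",
           "no_smoking_drinking", "moderate_exercise", "reduce_stress"),
  COPD = c("no_smoking", "regular_exercise", "rehabilitation_exercise")
)

# self-monitoring frequencies (times per week) per disease and level
monitoring_for <- function(disease, level) {
  switch(disease,
    HTN = c(BP = if (level == 1) 7 else 14, medication = 7),
    T2DM = c(BG = c(7, 14, 21)[level], medication = 7),
    COPD = c(PEF = 7, psychological = 0.25, medication = 7)
  )
}

#' Generate a single-disease management plan
#'
#' Converts a management level (and risk assessment) into the executable
#' plan: the doctor intervention plan (follow-up schedule plus reminders for
#' open warnings and low compliance) and the patient self-management plan
#' (self-monitoring schedule in times per week, medication guidance,
#' canonical lifestyle-prescription codes and education items).  COPD plans
#' carry no engine-generated medication items; medication guidance for COPD
#' is performed manually by care providers.
#'
#' @param profile One profile row.
#' @param level A `management_level` from [assign_level()].
#' @param risk Optional `risk_assessment`.
#' @param config Engine configuration.
#' @return A list of class `management_plan`.
#' @export
generate_plan <- function(profile, level, risk = NULL,
                          config = default_config()) {
  disease <- level$disease
  if (!disease %in% patient_diseases(profile))
    stop("level disease ", disease, " not among patient's diseases")
  fu <- schedule_followup(disease, level$level, level$effective_date, config)
  med <- switch(disease,
    HTN = list(list(item = "antihypertensive_review", engine_generated = TRUE)),
    T2DM = list(list(item = "hypoglycemic_or_insulin_review",
                     engine_generated = TRUE)),
    COPD = list()
  )
  structure(list(
    patient_id = profile$patient_id,
    doctor_plan = list(
      followup_interval_days = fu$interval_days,
      next_followup = fu$next_date,
      pending_warning_reminders = list(),
      low_compliance_reminders = list()
    ),
    self_plan = list(
      monitoring_schedule = as.list(monitoring_for(disease, level$level)),
      medication_items = med,
      lifestyle_items = sort(LIFESTYLE_SETS[[disease]]),
      education_items = list(paste0(tolower(disease), "_basics"))
    ),
    provenance = list(diseases = disease,
                      levels = stats::setNames(level$level, disease))
  ), class = "management_plan")
}

#' @export
print.management_plan <- function(x, ...) {
  cat("<management_plan>", x$patient_id, "\n",
      " diseases:", paste(x$provenance$diseases, collapse = "+"),
      " levels:", paste(x$provenance$levels, collapse = "/"), "\n",
      " follow-up every", x$doctor_plan$followup_interval_days, "days (next",
      format(x$doctor_plan$next_followup), ")\n",
      " monitoring:", paste(names(x$self_plan$monitoring_schedule),
                            unlist(x$self_plan$monitoring_schedule),
                            sep = "=", collapse = ", "), "per week\n",
      " lifestyle:", paste(x$self_plan$lifestyle_items, collapse = ", "), "\n")
  invisible(x)
}

# conflict-resolution table extracted from an MCC merge ruleset: for every
# LifestyleGuidance rule with a conflict_group parameter, when `keep` is
# present the `drop` items are removed (most-conservative wins)
mcc_conflict_rules <- function(ruleset = NULL) {
  if (is.null(ruleset)) ruleset <- load_ruleset(bundled_ruleset("hm"))
  out <- list()
  for (r in ruleset) {
    p <- r$action$parameters
    if (!is.null(p$conflict_group))
      out[[p$conflict_group]] <- list(keep = p$keep,
                                      drop = unlist(p$drop) %||% character(0))
  }
  out
}

#' Merge single-disease management plans for a multimorbid patient
#'
#' Merging follows the most-conservative rule: the follow-up interval is the
#' minimum over the component plans; the monitoring schedule is the per-kind
#' maximum frequency; lifestyle items are the set union with redundancies
#' collapsed and conflicts resolved by the MCC merge ruleset (for example
#' `moderate_exercise` supersedes `increase_exercise`).  A single-element
#' input is returned unchanged.  The only supported multimorbidity is
#' hypertension with type 2 diabetes.
#'
#' @param plans List of `management_plan` objects for one patient.
#' @param mcc_rules Conflict rules; defaults to the bundled HM merge ruleset.
#' @return A merged `management_plan`.
#' @export
merge_plans <- function(plans, mcc_rules = NULL) {
  stopifnot(length(plans) >= 1)
  if (length(plans) == 1) return(plans[[1]])
  pids <- unique(vapply(plans, `[[`, character(1), "patient_id"))
  if (length(pids) > 1) stop("plans belong to different patients")
  dz <- unlist(lapply(plans, function(p) p$provenance$diseases))
  if (!setequal(dz, c("HTN", "T2DM")))
    stop("unsupported multimorbidity: ", paste(sort(dz), collapse = "+"),
         " (only HTN+T2DM is supported)")
  if (is.null(mcc_rules)) mcc_rules <- mcc_conflict_rules()
  ord <- order(dz)               # canonical order => merge is commutative
  plans <- plans[ord]
  intervals <- vapply(plans, function(p)
    p$doctor_plan$followup_interval_days, numeric(1))
  nexts <- as.Date(vapply(plans, function(p)
    as.character(p$doctor_plan$next_followup), character(1)))
  sched <- list()
  for (p in plans)
    for (k in names(p$self_plan$monitoring_schedule))
      sched[[k]] <- max(sched[[k]] %||% 0, p$self_plan$monitoring_schedule[[k]])
  sched <- sched[sort(names(sched))]
  lifestyle <- sort(unique(unlist(lapply(plans, function(p)
    p$self_plan$lifestyle_items))))
  for (cr in mcc_rules)
    if (!is.null(cr$keep) && cr$keep %in% lifestyle)
      lifestyle <- setdiff(lifestyle, cr$drop)
  meds <- unlist(lapply(plans, function(p) p$self_plan$medication_items),
                 recursive = FALSE)
  meds <- meds[!duplicated(vapply(meds, `[[`, character(1), "item"))]
  edu <- unique(unlist(lapply(plans, function(p) p$self_plan$education_items)))
  levels <- do.call(c, lapply(plans, function(p) p$provenance$levels))
  structure(list(
    patient_id = pids,
    doctor_plan = list(
      followup_interval_days = as.integer(min(intervals)),
      next_followup = min(nexts),
      pending_warning_reminders = list(),
      low_compliance_reminders = list()
    ),
    self_plan = list(
      monitoring_schedule = sched,
      medication_items = meds,
      lifestyle_items = lifestyle,
      education_items = as.list(sort(edu))
    ),
    provenance = list(diseases = sort(unique(dz)), levels = levels)
  ), class = "management_plan")
}
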