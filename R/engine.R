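#' Initialize an engine state
#'
#' The engine state bundles everything the two trigger modes operate on:
#' enrolled profiles, the record store, per-patient fact bases (with fired
#' rule memory), current risk assessments, levels and plans, open warnings,
#' the compliance log and the event log.  State is a plain value; both
#' [on_record()] and [on_schedule()] return an updated copy.
#'
#' @param profiles Profile table (see [patient_profile()]).
#' @param config Engine configuration, [default_config()].
#' @param rulesets Named list of rulesets per disease group; defaults to the
#'   bundled ones.
#' @return An object of class `engine_state`.
#' @export
engine_init <- function(profiles, config = default_config(),
                        rulesets = NULL) {
  validate_profiles(profiles)
  validate_config(config)
  if (is.null(rulesets))
    rulesets <- list(
      HTN = load_ruleset(bundled_ruleset("htn")),
      T2DM = load_ruleset(bundled_ruleset("t2dm")),
      COPD = load_ruleset(bundled_ruleset("copd")),
      HM = load_ruleset(bundled_ruleset("hm"))
    )
  structure(list(
    config = config, rulesets = rulesets, profiles = profiles,
    records = empty_records(), warnings = empty_warnings(),
    plans = list(), risks = list(), levels = list(), fb = list(),
    next_followup = list(), compliance_log = empty_compliance_log(),
    last_date = as.Date(NA), events = list()
  ), class = "engine_state")
}

empty_compliance_log <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
             scheduled_tasks = numeric(0), completed_tasks = numeric(0),
             compliance = numeric(0), flagged_low = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.engine_state <- function(x, ...) {
  cat("<engine_state>", nrow(x$profiles), "patients,",
      nrow(x$records), "records,", length(x$events), "events, last day",
      format(x$last_date), "\n")
  invisible(x)
}

make_event <- function(type, date, patient_id, payload = list()) {
  list(type = type, date = as.character(as.Date(date)),
       patient_id = patient_id, payload = payload)
}

group_ruleset <- function(state, grp) {
  if (grp == "HM") {
    rs <- c(unclass(state$rulesets$HTN), unclass(state$rulesets$T2DM),
            unclass(state$rulesets$HM))
    ids <- vapply(rs, `[[`, character(1), "rule_id")
    ord <- order(-vapply(rs, `[[`, numeric(1), "priority"), ids)
    structure(rs[ord], class = "ruleset")
  } else state$rulesets[[grp]]
}

refresh_fact_base <- function(state, pid, facts, date) {
  fb <- state$fb[[pid]] %||% fact_base()
  fb$facts <- facts
  fb <- expire_tasks(fb, date)   # also re-derives task.*.exists facts
  fb
}

#' On-upload trigger mode
#'
#' Handles one uploaded self-monitoring record: validates and stores it,
#' runs the single-value warning checks for immediate feedback, then
#' evaluates the event-triggered rules of the patient's disease group to
#' fixpoint (for example raising an abnormal-condition intervention task on
#' an urgent warning).
#'
#' @param state An `engine_state`.
#' @param record A one-row record data.frame ([monitoring_record()]).
#' @return List with `state` (updated) and `events` (list of emitted
#'   events; also appended to `state$events`).
#' @export
on_record <- function(state, record) {
  stopifnot(inherits(state, "engine_state"), nrow(record) == 1)
  validate_records(record)
  pid <- record$patient_id
  prow <- state$profiles[state$profiles$patient_id == pid, , drop = FALSE]
  if (!nrow(prow)) stop("record for unenrolled patient: ", pid)
  if (record$record_id %in% state$records$record_id)
    stop("duplicate record id: ", record$record_id)
  events <- list()
  state$records <- rbind(state$records, record)
  new_w <- detect_warnings(record, prow, record$timestamp,
                           state$config, weekly = FALSE)
  if (nrow(new_w)) {
    state$warnings <- rbind(state$warnings, new_w)
    for (i in seq_len(nrow(new_w)))
      events <- c(events, list(make_event(
        "warning", record$timestamp, pid,
        list(kind = new_w$kind[i], severity = new_w$severity[i],
             evidence = new_w$evidence[i]))))
  }
  open_w <- state$warnings[state$warnings$patient_id == pid &
                             state$warnings$status == "open", , drop = FALSE]
  facts <- patient_facts(prow, state$records,
                         as.Date(record$timestamp) + 1,
                         open_warnings = open_w)
  facts[["event.kind"]] <- record$kind
  facts[["event.record_id"]] <- record$record_id
  fb <- refresh_fact_base(state, pid, facts, as.Date(record$timestamp))
  res <- evaluate_to_fixpoint(fb, group_ruleset(state, disease_group(prow)),
                              as.Date(record$timestamp))
  state$fb[[pid]] <- res$fact_base
  for (i in seq_len(nrow(res$fired)))
    events <- c(events, list(make_event(
      "task", record$timestamp, pid,
      c(list(task_kind = res$fired$task_kind[i],
             rule_id = res$fired$provenance[i]),
        res$fired$payload[[i]]))))
  state$events <- c(state$events, events)
  list(state = state, events = events)
}

#' Periodic trigger mode
#'
#' Advances the engine to `date`, processing every intermediate day exactly
#' once (calling this once for an interval is equivalent to one call per
#' day).  Each day, for each enrolled patient: compliance is updated (daily
#' frequency), facts are rebuilt, stale tasks expire, and the periodic rules
#' of the patient's disease group are evaluated to fixpoint.  Fired tasks
#' are materialized: risk assessments are computed, management levels
#' re-assigned (emitting a `level_change` event and regenerating the plan —
#' merged across diseases for multimorbid patients — when the level moves),
#' due follow-ups emit `followup_request` events, and guidance tasks emit
#' `guidance` events.
#'
#' @param state An `engine_state`.
#' @param date Target date; must not precede the last processed date.
#' @return List with `state` and `events`.
#' @export
on_schedule <- function(state, date) {
  stopifnot(inherits(state, "engine_state"))
  date <- as.Date(date)
  if (!is.na(state$last_date) && date < state$last_date)
    stop("date regression: engine already processed ", format(state$last_date))
  start <- if (is.na(state$last_date))
    min(min(state$profiles$enrollment_date), date)
  else state$last_date + 1
  days <- seq(start, date, by = "day")
  if (!is.na(state$last_date) && date == state$last_date)
    days <- as.Date(character(0))
  events <- list()
  for (d in as.list(days)) {
    active <- state$profiles[state$profiles$enrollment_date <= d, ,
                             drop = FALSE]
    for (j in seq_len(nrow(active))) {
      prow <- active[j, , drop = FALSE]
      st <- process_patient_day(state, prow, d)
      state <- st$state
      events <- c(events, st$events)
    }
    state$last_date <- d
  }
  state$events <- c(state$events, events)
  list(state = state, events = events)
}

process_patient_day <- function(state, prow, d) {
  pid <- prow$patient_id
  grp <- disease_group(prow)
  dz <- patient_diseases(prow)
  events <- list()

  if (is.null(state$plans[[pid]])) {
    boot <- bootstrap_plan(state, prow, d)
    state <- boot$state
    events <- c(events, boot$events)
  }

  cs <- update_compliance(state$plans[[pid]], state$records, d, state$config)
  state$compliance_log <- rbind(state$compliance_log, data.frame(
    patient_id = pid, date = cs$date, scheduled_tasks = cs$scheduled_tasks,
    completed_tasks = cs$completed_tasks, compliance = cs$compliance,
    flagged_low = cs$flagged_low, stringsAsFactors = FALSE))
  events <- c(events, list(make_event(
    "compliance_state", d, pid,
    list(compliance = cs$compliance, flagged_low = cs$flagged_low))))

  open_w <- state$warnings[state$warnings$patient_id == pid &
                             state$warnings$status == "open", , drop = FALSE]
  facts <- patient_facts(prow, state$records, d, compliance = cs,
                         open_warnings = open_w)
  fb <- refresh_fact_base(state, pid, facts, d)
  res <- evaluate_to_fixpoint(fb, group_ruleset(state, grp), d)
  state$fb[[pid]] <- res$fact_base

  fired <- res$fired
  for (i in seq_len(nrow(fired))) {
    kind <- fired$task_kind[i]
    payload <- fired$payload[[i]]
    disease <- payload$disease
    if (kind == "RiskAssessment" && !is.null(disease)) {
      risk <- tryCatch(
        assess_risk(prow, state$records, disease, d, state$config),
        error = function(e) NULL)
      if (!is.null(risk)) {
        state$risks[[pid]][[disease]] <- risk
        events <- c(events, list(make_event(
          "risk_assessment", d, pid,
          list(disease = disease, category = risk$category))))
      }
    } else if (kind == "HierarchicalManagement" && !is.null(disease)) {
      lvl <- assign_level(prow, state$risks[[pid]][[disease]],
                          state$records, disease, d, state$config)
      old <- state$levels[[pid]][[disease]]
      state$levels[[pid]][[disease]] <- lvl$level
      if (is.null(old) || old != lvl$level) {
        events <- c(events, list(make_event(
          "level_change", d, pid,
          list(disease = disease, from = old, to = lvl$level,
               provisional = lvl$provisional))))
        reb <- rebuild_plan(state, prow, d)
        state <- reb$state
        events <- c(events, list(make_event(
          "plan_updated", d, pid,
          list(followup_interval_days =
                 state$plans[[pid]]$doctor_plan$followup_interval_days))))
      }
    } else if (kind == "RegularFollowUp") {
      nf <- state$next_followup[[pid]]
      if (!is.null(nf) && d >= nf) {
        interval <- state$plans[[pid]]$doctor_plan$followup_interval_days
        events <- c(events, list(make_event(
          "followup_request", d, pid,
          list(interval_days = interval, rule_id = fired$provenance[i]))))
        state$next_followup[[pid]] <- d + interval
      }
    } else if (kind == "ComplianceManagement") {
      events <- c(events, list(make_event(
        "compliance_intervention", d, pid,
        list(action = "extra_followup", compliance = cs$compliance))))
    } else if (kind == "AbnormalConditionIntervention") {
      events <- c(events, list(make_event(
        "abnormal_intervention", d, pid, payload)))
    } else {
      events <- c(events, list(make_event(
        "guidance", d, pid,
        c(list(task_kind = kind, rule_id = fired$provenance[i]), payload))))
    }
  }
  list(state = state, events = events)
}

# initial management period: provisional stratification and plan generation
# on the first processed day for a patient
bootstrap_plan <- function(state, prow, d) {
  pid <- prow$patient_id
  events <- list()
  for (disease in patient_diseases(prow)) {
    risk <- tryCatch(
      assess_risk(prow, state$records, disease, d, state$config),
      error = function(e) NULL)
    if (!is.null(risk)) state$risks[[pid]][[disease]] <- risk
    lvl <- assign_level(prow, risk, state$records, disease, d, state$config)
    state$levels[[pid]][[disease]] <- lvl$level
  }
  reb <- rebuild_plan(state, prow, d)
  state <- reb$state
  events <- c(events, list(make_event(
    "plan_created", d, pid,
    list(diseases = patient_diseases(prow),
         levels = state$levels[[pid]],
         followup_interval_days =
           state$plans[[pid]]$doctor_plan$followup_interval_days))))
  list(state = state, events = events)
}

rebuild_plan <- function(state, prow, d) {
  pid <- prow$patient_id
  single <- lapply(patient_diseases(prow), function(disease) {
    lvl <- structure(list(
      disease = disease, level = state$levels[[pid]][[disease]],
      label = as.character(utils::as.roman(state$levels[[pid]][[disease]])),
      basis = list(), provisional = FALSE, effective_date = d
    ), class = "management_level")
    generate_plan(prow, lvl, state$risks[[pid]][[disease]], state$config)
  })
  plan <- if (length(single) > 1) merge_plans(single) else single[[1]]
  state$plans[[pid]] <- plan
  state$next_followup[[pid]] <- plan$doctor_plan$next_followup
  list(state = state)
}

#' Replay a record stream through the engine
#'
#' Runs the full engine over a profile table and a record stream: days are
#' processed in order, with each day's periodic sweep followed by that day's
#' record uploads (ordered by timestamp, then record id).  Identical inputs
#' and configuration yield identical event logs.
#'
#' @param profiles Profile table.
#' @param records Record table.
#' @param config Engine configuration.
#' @param until Last day to process; defaults to the day after the last
#'   record.
#' @return The final `engine_state`; its `events` element is the event log.
#' @export
engine_replay <- function(profiles, records, config = default_config(),
                          until = NULL) {
  validate_records(records)
  state <- engine_init(profiles, config)
  start <- min(profiles$enrollment_date)
  if (is.null(until))
    until <- if (nrow(records)) max(as.Date(records$timestamp)) + 1
             else start + 1
  records <- records[order(records$timestamp, records$record_id), ,
                     drop = FALSE]
  rec_day <- as.Date(records$timestamp)
  for (d in as.list(seq(as.Date(start), as.Date(until), by = "day"))) {
    state <- on_schedule(state, d)$state
    todays <- which(rec_day == d)
    for (i in todays)
      state <- on_record(state, records[i, , drop = FALSE])$state
  }
  state
}
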