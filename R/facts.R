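#' Published fact schema
#'
#' The machine-readable list of fact paths a rule condition may reference,
#' with types and units.  Facts are computed by the engine from the patient
#' profile, windowed aggregates of self-monitoring records, warning and
#' compliance state; `task.<kind>.exists` facts are derived from fired task
#' instances so that one task's generation can trigger another rule.
#' Absence tests are pre-computed boolean facts (for example
#' `agg.no_bp_record_7d`) because rule conditions are positive conjunctions.
#'
#' @return A data.frame with columns `fact_path`, `type`, `unit`.
#' @export
fact_schema <- function() {
  base <- rbind(
    data.frame(fact_path = c(
      "profile.age", "profile.sex", "profile.education",
      "profile.has_htn", "profile.has_t2dm", "profile.has_copd", "profile.has_hm",
      "profile.smoking", "profile.obesity", "profile.organ_damage",
      "mgmt.days_enrolled",
      "level.HTN", "level.T2DM", "level.COPD", "level.provisional",
      "agg.sbp_mean_7d", "agg.dbp_mean_7d", "agg.bp_n_7d",
      "agg.fbg_mean_7d", "agg.pbg_mean_7d", "agg.bg_n_7d",
      "agg.hypoglycemia_7d",
      "agg.pef_mean_7d", "agg.pef_pct_best", "agg.pef_n_7d",
      "agg.cat_latest", "agg.exacerbations_12m", "agg.hospitalizations_12m",
      "agg.no_bp_record_7d", "agg.no_bg_record_7d", "agg.no_pef_record_7d",
      "warning.open_count", "warning.any_urgent",
      "compliance.value", "compliance.low",
      "event.kind", "event.record_id"
    ), stringsAsFactors = FALSE),
    data.frame(fact_path = sprintf("task.%s.exists", TASK_KINDS),
               stringsAsFactors = FALSE)
  )
  types <- c(
    "profile.age" = "numeric", "profile.sex" = "enum",
    "profile.education" = "enum",
    "profile.has_htn" = "logical", "profile.has_t2dm" = "logical",
    "profile.has_copd" = "logical", "profile.has_hm" = "logical",
    "profile.smoking" = "logical", "profile.obesity" = "logical",
    "profile.organ_damage" = "logical",
    "mgmt.days_enrolled" = "numeric",
    "level.HTN" = "integer", "level.T2DM" = "integer", "level.COPD" = "integer",
    "level.provisional" = "logical",
    "agg.sbp_mean_7d" = "numeric", "agg.dbp_mean_7d" = "numeric",
    "agg.bp_n_7d" = "integer",
    "agg.fbg_mean_7d" = "numeric", "agg.pbg_mean_7d" = "numeric",
    "agg.bg_n_7d" = "integer", "agg.hypoglycemia_7d" = "logical",
    "agg.pef_mean_7d" = "numeric", "agg.pef_pct_best" = "numeric",
    "agg.pef_n_7d" = "integer",
    "agg.cat_latest" = "numeric", "agg.exacerbations_12m" = "integer",
    "agg.hospitalizations_12m" = "integer",
    "agg.no_bp_record_7d" = "logical", "agg.no_bg_record_7d" = "logical",
    "agg.no_pef_record_7d" = "logical",
    "warning.open_count" = "integer", "warning.any_urgent" = "logical",
    "compliance.value" = "numeric", "compliance.low" = "logical",
    "event.kind" = "enum", "event.record_id" = "string"
  )
  units <- c("profile.age" = "years", "mgmt.days_enrolled" = "days",
             "agg.sbp_mean_7d" = "mmHg", "agg.dbp_mean_7d" = "mmHg",
             "agg.fbg_mean_7d" = "mmol/L", "agg.pbg_mean_7d" = "mmol/L",
             "agg.pef_mean_7d" = "L/min", "agg.pef_pct_best" = "%",
             "compliance.value" = "fraction")
  base$type <- ifelse(base$fact_path %in% names(types),
                      types[base$fact_path], "logical")
  base$unit <- ifelse(base$fact_path %in% names(units),
                      units[base$fact_path], "")
  rownames(base) <- NULL
  base
}

#' Create a fact base
#'
#' A fact base holds the patient facts a ruleset is evaluated against plus
#' the task instances derived so far (with rule provenance).
#'
#' @param facts Named list mapping fact paths (see [fact_schema()]) to
#'   scalar values.
#' @return An object of class `fact_base`.
#' @export
fact_base <- function(facts = list()) {
  if (length(facts)) {
    bad <- setdiff(names(facts), fact_schema()$fact_path)
    if (length(bad)) stop("unknown fact path(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(names(facts)))
      stop("duplicate fact paths in fact base")
  }
  structure(
    list(facts = facts, tasks = empty_tasks(), fired = character(0)),
    class = "fact_base"
  )
}

empty_tasks <- function() {
  data.frame(
    task_kind = character(0), generated_at = as.Date(character(0)),
    valid_until = as.Date(character(0)), provenance = character(0),
    dedup_key = character(0), payload = I(list()),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fact_base <- function(x, ...) {
  cat("<fact_base>", length(x$facts), "facts,",
      nrow(x$tasks), "derived tasks\n")
  invisible(x)
}

COMPARATORS <- c("==", "!=", "<", "<=", ">", ">=", "in", "exists")

# Evaluate one predicate against the fact list.  Missing facts make any
# predicate false (positive-conjunction semantics, no negation-as-failure).
eval_predicate <- function(pred, facts) {
  v <- facts[[pred$fact]]
  if (pred$op == "exists") return(!is.null(v) && !all(is.na(v)))
  if (is.null(v) || all(is.na(v))) return(FALSE)
  switch(pred$op,
    "==" = isTRUE(v == pred$value),
    "!=" = isTRUE(v != pred$value),
    "<"  = isTRUE(v <  pred$value),
    "<=" = isTRUE(v <= pred$value),
    ">"  = isTRUE(v >  pred$value),
    ">=" = isTRUE(v >= pred$value),
    "in" = isTRUE(v %in% unlist(pred$value)),
    stop("unknown comparator: ", pred$op)
  )
}

eval_condition <- function(condition, facts) {
  all(vapply(condition, eval_predicate, logical(1), facts = facts))
}
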