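#' Load and validate a declarative ruleset
#'
#' Rules are YAML documents, one rule per list entry, expressing
#' condition -> action pathway knowledge: a trigger (periodic with a
#' frequency in days, or event with the record kinds that fire it), a
#' conjunction of positive predicates over the published [fact_schema()],
#' and an action naming one of the eight in-system task kinds.  Rules are
#' returned sorted by decreasing priority, ties broken by `rule_id`
#' (lexicographic) for reproducibility.
#'
#' @param path Path to a YAML rule file.
#' @return A list of validated rules, class `ruleset`.
#' @seealso [bundled_ruleset()] for the rulesets shipped with the package,
#'   [evaluate_to_fixpoint()] for the forward-chaining evaluator.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  rules <- lapply(raw, validate_rule)
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids))
    stop("duplicate rule_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(-vapply(rules, `[[`, numeric(1), "priority"), ids)
  structure(rules[ord], class = "ruleset")
}

#' Path to a bundled disease ruleset
#'
#' Four rulesets ship with the package: `"htn"`, `"t2dm"`, `"copd"` and the
#' multimorbidity merge set `"hm"`.
#'
#' @param name One of `"htn"`, `"t2dm"`, `"copd"`, `"hm"`.
#' @return File path usable with [load_ruleset()].
#' @export
bundled_ruleset <- function(name = c("htn", "t2dm", "copd", "hm")) {
  name <- match.arg(name)
  system.file("extdata", "rulesets", paste0(name, ".yaml"),
              package = "chronicare", mustWork = TRUE)
}

validate_rule <- function(r) {
  id <- r$rule_id
  fail <- function(...) stop("rule '", if (is.null(id)) "<missing id>" else id,
                             "': ", ..., call. = FALSE)
  if (is.null(id) || !nzchar(id)) stop("rule without rule_id", call. = FALSE)
  if (is.null(r$disease_scope) ||
      !r$disease_scope %in% c(DISEASES, "HM", "ALL"))
    fail("disease_scope must be one of HTN, T2DM, COPD, HM, ALL")
  tr <- r$trigger
  if (is.null(tr$type) || !tr$type %in% c("periodic", "event"))
    fail("trigger type must be 'periodic' or 'event'")
  if (tr$type == "periodic") {
    f <- tr$frequency_days
    if (is.null(f) || !is.numeric(f) || f < 1 || f != round(f))
      fail("periodic trigger needs a positive integer frequency_days")
  } else {
    if (is.null(tr$record_kinds) || !all(tr$record_kinds %in% RECORD_KINDS))
      fail("event trigger record_kinds must be a subset of record_kinds()")
  }
  schema <- fact_schema()$fact_path
  for (p in r$condition) {
    if (is.null(p$fact) || !p$fact %in% schema)
      fail("unknown fact_path '", p$fact, "'")
    if (is.null(p$op) || !p$op %in% COMPARATORS)
      fail("unknown comparator '", p$op, "'")
    if (p$op != "exists" && is.null(p$value))
      fail("predicate on '", p$fact, "' lacks a value")
  }
  tk <- r$action$task_kind
  if (identical(tk, "Diagnosis"))
    fail("Diagnosis is not an in-system task")
  if (is.null(tk) || !tk %in% TASK_KINDS)
    fail("unknown task_kind '", tk, "'")
  if (!is.null(r$valid_duration_days) &&
      (!is.numeric(r$valid_duration_days) || r$valid_duration_days < 1))
    fail("valid_duration_days must be a positive number of days")
  if (is.null(r$priority)) r$priority <- 0
  if (is.null(r$condition)) r$condition <- list()
  if (is.null(r$action$parameters)) r$action$parameters <- list()
  r
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset>", length(x), "rules\n")
  for (r in x)
    cat(sprintf("  %-16s %-5s %-8s -> %s\n", r$rule_id, r$disease_scope,
                r$trigger$type, r$action$task_kind))
  invisible(x)
}

rule_applicable <- function(rule, facts) {
  ev <- facts[["event.kind"]]
  if (rule$trigger$type == "event") {
    !is.null(ev) && ev %in% rule$trigger$record_kinds
  } else {
    # periodic rules fire in periodic sweeps, not on record upload
    is.null(ev)
  }
}

# Default dedup key: task kind + disease scope + scheduling-period index,
# so a periodic task fires once per period (and once per disease for
# multimorbid patients whose single-disease rulesets run together).
rule_dedup_key <- function(rule, facts, now) {
  kind <- paste(rule$action$task_kind, rule$disease_scope, sep = ":")
  if (rule$trigger$type == "periodic") {
    d <- facts[["mgmt.days_enrolled"]]
    if (is.null(d)) d <- 0
    sprintf("%s:p%d", kind, floor(d / rule$trigger$frequency_days))
  } else {
    rid <- facts[["event.record_id"]]
    sprintf("%s:e%s", kind, if (is.null(rid)) format(now) else rid)
  }
}

#' Evaluate a ruleset to fixpoint
#'
#' Forward-chaining evaluation: repeated passes fire every applicable rule
#' whose condition holds against the current facts, insert the fired task
#' instances into the fact base (setting the corresponding
#' `task.<kind>.exists` facts) before the next pass, and stop when a pass
#' fires nothing.  A `(rule_id, dedup_key)` pair fires at most once — for a
#' periodic rule the dedup key encodes the scheduling-period index, so the
#' task fires once per period — which bounds the number of passes and makes
#' the result independent of rule order within a priority tier.
#'
#' @param fb A [fact_base()].
#' @param ruleset A `ruleset` from [load_ruleset()].
#' @param now Evaluation date (`Date`).
#' @return List with elements `fact_base` (the updated fact base) and
#'   `fired` (data.frame of the task instances newly fired by this call).
#' @export
evaluate_to_fixpoint <- function(fb, ruleset, now) {
  stopifnot(inherits(fb, "fact_base"))
  now <- as.Date(now)
  # canonical order (priority desc, rule_id) is re-imposed here so the
  # fixpoint cannot depend on the order rules are handed in
  ids <- vapply(ruleset, `[[`, character(1), "rule_id")
  ruleset <- ruleset[order(-vapply(ruleset, `[[`, numeric(1), "priority"), ids)]
  new_tasks <- empty_tasks()
  guard <- max(10L * length(ruleset), 10L)
  pass <- 0L
  trace <- character(0)
  repeat {
    pass <- pass + 1L
    if (pass > guard)
      stop("fixpoint not reached after ", guard, " passes; firing cycle: ",
           paste(utils::tail(trace, 20), collapse = " -> "))
    fired_this_pass <- empty_tasks()
    for (rule in ruleset) {
      if (!rule_applicable(rule, fb$facts)) next
      if (!eval_condition(rule$condition, fb$facts)) next
      key <- rule_dedup_key(rule, fb$facts, now)
      full <- paste(rule$rule_id, key, sep = "|")
      if (full %in% fb$fired ||
          key %in% fb$tasks$dedup_key ||      # dedup_key unique per fact base
          key %in% fired_this_pass$dedup_key) next
      vu <- if (is.null(rule$valid_duration_days)) as.Date(NA)
            else now + rule$valid_duration_days
      inst <- data.frame(
        task_kind = rule$action$task_kind, generated_at = now,
        valid_until = vu, provenance = rule$rule_id, dedup_key = key,
        payload = I(list(rule$action$parameters)), stringsAsFactors = FALSE
      )
      fired_this_pass <- rbind(fired_this_pass, inst)
      trace <- c(trace, rule$rule_id)
    }
    if (!nrow(fired_this_pass)) break
    # simultaneous insertion: facts update only between passes, so the
    # fixpoint does not depend on rule order within a pass
    fb$tasks <- rbind(fb$tasks, fired_this_pass)
    fb$fired <- c(fb$fired,
                  paste(fired_this_pass$provenance, fired_this_pass$dedup_key,
                        sep = "|"))
    for (k in unique(fired_this_pass$task_kind))
      fb$facts[[sprintf("task.%s.exists", k)]] <- TRUE
    new_tasks <- rbind(new_tasks, fired_this_pass)
  }
  list(fact_base = fb, fired = new_tasks)
}

#' Remove expired task instances from a fact base
#'
#' Tasks carry an optional valid duration; tasks whose `valid_until` has
#' passed are dropped and the derived `task.<kind>.exists` facts are
#' recomputed.  Removal is idempotent.
#'
#' @param fb A [fact_base()].
#' @param now Current date.
#' @return The pruned `fact_base`.
#' @export
expire_tasks <- function(fb, now) {
  stopifnot(inherits(fb, "fact_base"))
  now <- as.Date(now)
  keep <- is.na(fb$tasks$valid_until) | fb$tasks$valid_until >= now
  fb$tasks <- fb$tasks[keep, , drop = FALSE]
  for (k in TASK_KINDS) {
    path <- sprintf("task.%s.exists", k)
    if (k %in% fb$tasks$task_kind) fb$facts[[path]] <- TRUE
    else fb$facts[[path]] <- NULL
  }
  fb
}
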