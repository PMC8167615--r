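# Fixtures are built in code: profiles, record streams, ad-hoc rules, and an
# independent reference evaluator used as the oracle for the rule engine.

empty_records_fixture <- function() chronicare:::empty_records()

htn_profile <- function(id = "p1", ...) {
  patient_profile(id, age = 60, sex = "male", diseases = "HTN",
                  enrollment_date = "2020-01-01", ...)
}

t2dm_profile <- function(id = "p2", ...) {
  patient_profile(id, age = 55, sex = "female", diseases = "T2DM",
                  enrollment_date = "2020-01-01", ...)
}

copd_profile <- function(id = "p3", ...) {
  patient_profile(id, age = 65, sex = "male", diseases = "COPD",
                  enrollment_date = "2020-01-01", pef_personal_best = 450, ...)
}

hm_profile <- function(id = "p4", ...) {
  patient_profile(id, age = 62, sex = "female", diseases = c("HTN", "T2DM"),
                  enrollment_date = "2020-01-01", ...)
}

# n daily BP records ending the day before `as_of`
bp_series <- function(pid, sbp, dbp, n = 5, as_of = "2020-02-01") {
  days <- as.Date(as_of) - seq_len(n)
  do.call(rbind, lapply(seq_len(n), function(i)
    monitoring_record(pid, paste(days[i], "08:00:00"), "BP",
                      record_id = sprintf("%s-bp-%02d", pid, i),
                      sbp = sbp, dbp = dbp, heart_rate = 70)))
}

bg_series <- function(pid, fbg = NULL, pbg = NULL, n = 3,
                      as_of = "2020-02-01") {
  days <- as.Date(as_of) - seq_len(n)
  rows <- list()
  for (i in seq_len(n)) {
    if (!is.null(fbg))
      rows[[length(rows) + 1]] <- monitoring_record(
        pid, paste(days[i], "07:00:00"), "BG",
        record_id = sprintf("%s-fbg-%02d", pid, i),
        bg_type = "FBG", bg_value = fbg, ketone = FALSE)
    if (!is.null(pbg))
      rows[[length(rows) + 1]] <- monitoring_record(
        pid, paste(days[i], "13:00:00"), "BG",
        record_id = sprintf("%s-pbg-%02d", pid, i),
        bg_type = "PBG", bg_value = pbg, ketone = FALSE)
  }
  do.call(rbind, rows)
}

# build a rule as load_ruleset would return it
make_rule <- function(rule_id, task_kind, condition = list(),
                      scope = "ALL", type = "periodic", frequency = 30,
                      record_kinds = "BP", priority = 0,
                      valid_duration_days = NULL, parameters = list()) {
  trigger <- if (type == "periodic")
    list(type = "periodic", frequency_days = frequency)
  else list(type = "event", record_kinds = record_kinds)
  list(rule_id = rule_id, disease_scope = scope, trigger = trigger,
       condition = condition, priority = priority,
       valid_duration_days = valid_duration_days,
       action = list(task_kind = task_kind, parameters = parameters))
}

as_ruleset <- function(rules) structure(rules, class = "ruleset")

pred <- function(fact, op = "==", value = TRUE)
  list(fact = fact, op = op, value = value)

# Independent reference evaluator: repeatedly scans all rules against the
# facts (task-existence facts recomputed from the accumulated task set) with
# a visited dedup-key set, until no rule adds a task.  Deliberately naive.
oracle_fixpoint <- function(facts, rules, days_enrolled = 0) {
  eval_pred <- function(p, f) {
    v <- f[[p$fact]]
    if (p$op == "exists") return(!is.null(v))
    if (is.null(v)) return(FALSE)
    switch(p$op, "==" = isTRUE(v == p$value), "!=" = isTRUE(v != p$value),
           "<" = isTRUE(v < p$value), "<=" = isTRUE(v <= p$value),
           ">" = isTRUE(v > p$value), ">=" = isTRUE(v >= p$value),
           "in" = isTRUE(v %in% unlist(p$value)))
  }
  keys <- character(0)
  repeat {
    added <- FALSE
    for (r in rules) {
      if (r$trigger$type != "periodic") next
      if (!all(vapply(r$condition, eval_pred, logical(1), f = facts))) next
      key <- sprintf("%s:%s:p%d", r$action$task_kind, r$disease_scope,
                     floor(days_enrolled / r$trigger$frequency_days))
      if (key %in% keys) next
      keys <- c(keys, key)
      facts[[sprintf("task.%s.exists", r$action$task_kind)]] <- TRUE
      added <- TRUE
    }
    if (!added) break
  }
  sort(keys)
}

# random ruleset generator for the property suite
random_ruleset <- function(n_rules, rng_facts = BOOL_FACTS) {
  rules <- lapply(seq_len(n_rules), function(i) {
    kind <- sample(task_kinds(), 1)
    n_cond <- sample(0:2, 1)
    cond <- lapply(sample(c(rng_facts,
                            sprintf("task.%s.exists", task_kinds())), n_cond),
                   function(f) pred(f, "==", TRUE))
    make_rule(sprintf("R%03d", i), kind, condition = cond,
              scope = sample(c("HTN", "T2DM", "COPD", "HM", "ALL"), 1),
              frequency = sample(c(1, 7, 30), 1),
              priority = sample(1:3, 1))
  })
  as_ruleset(rules)
}

BOOL_FACTS <- c("profile.has_htn", "profile.has_t2dm", "profile.has_copd",
                "profile.has_hm", "compliance.low", "warning.any_urgent",
                "agg.no_bp_record_7d")

random_facts <- function() {
  f <- lapply(BOOL_FACTS, function(x) sample(c(TRUE, FALSE), 1))
  names(f) <- BOOL_FACTS
  f <- f[unlist(f)]                    # keep only true facts (positive logic)
  f[["mgmt.days_enrolled"]] <- sample(0:120, 1)
  f
}

fired_keys <- function(res) sort(res$fired$dedup_key)
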