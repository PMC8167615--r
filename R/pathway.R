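#' Disease-specific risk assessment
#'
#' Evaluates the risk factors that refine a patient's treatment plan.
#' For hypertension: cardiovascular risk-factor count (age above the
#' sex-specific cutoff, smoking, obesity, diabetes comorbidity), target-organ
#' damage and comorbidity flags.  For type 2 diabetes: whether blood
#' pressure, blood glucose and blood lipids are controlled.  For COPD:
#' peak-flow percent of personal best, CAT score, and 12-month exacerbation
#' and hospitalization counts, combined into the standard 2x2
#' symptom-burden-by-exacerbation-risk grid (categories I-IV).
#'
#' @param profile One profile row.
#' @param records Record table.
#' @param disease One of `"HTN"`, `"T2DM"`, `"COPD"`; must be a disease the
#'   patient is managed for.
#' @param as_of Assessment date.
#' @param config Engine configuration, see [default_config()].
#' @return A list of class `risk_assessment` with elements `disease`,
#'   `factors`, `category`, `assessed_at`.
#' @export
assess_risk <- function(profile, records, disease, as_of,
                        config = default_config()) {
  dz <- patient_diseases(profile)
  if (!disease %in% dz)
    stop("patient ", profile$patient_id, " is not managed for ", disease)
  as_of <- as.Date(as_of)
  facts <- patient_facts(profile, records, as_of)
  out <- switch(disease,
    HTN = {
      cutoff <- config$risk_factors$age_cutoff[[profile$sex]]
      factors <- list(
        age_risk = profile$age > cutoff,
        smoking = isTRUE(profile$smoking),
        obesity = isTRUE(profile$obesity),
        diabetes_comorbidity = "T2DM" %in% dz,
        organ_damage = isTRUE(profile$organ_damage)
      )
      n <- sum(unlist(factors[c("age_risk", "smoking", "obesity",
                                "diabetes_comorbidity")]))
      factors$risk_factor_count <- n
      category <- if (isTRUE(factors$organ_damage) || n >= 3) "high"
                  else if (n >= 1) "moderate" else "low"
      list(factors = factors, category = category)
    },
    T2DM = {
      bp_ok <- if (!is.null(facts[["agg.sbp_mean_7d"]]))
        facts[["agg.sbp_mean_7d"]] < profile$sbp_target &&
          facts[["agg.dbp_mean_7d"]] < profile$dbp_target else TRUE
      fbg <- facts[["agg.fbg_mean_7d"]]
      pbg <- facts[["agg.pbg_mean_7d"]]
      bg_ok <- (is.null(fbg) || fbg < profile$fbg_target) &&
        (is.null(pbg) || pbg < profile$pbg_target)
      factors <- list(bp_controlled = bp_ok, bg_controlled = bg_ok,
                      lipid_controlled = isTRUE(profile$lipid_controlled))
      n <- sum(unlist(factors))
      category <- c("uncontrolled", "partially_controlled",
                    "partially_controlled", "all_controlled")[n + 1]
      list(factors = factors, category = category)
    },
    COPD = {
      cat_score <- facts[["agg.cat_latest"]]
      pef_pct <- facts[["agg.pef_pct_best"]]
      if (is.null(cat_score) && is.null(pef_pct))
        stop("insufficient data: COPD risk assessment needs PEF or CAT records")
      high_symptom <- (!is.null(cat_score) &&
                         cat_score >= config$warnings$cat_threshold) ||
        (!is.null(pef_pct) && pef_pct < config$targets$pef_pct_best)
      high_risk <- facts[["agg.exacerbations_12m"]] >= 2 ||
        facts[["agg.hospitalizations_12m"]] >= 1
      factors <- list(
        pef_percent_best = if (is.null(pef_pct)) NA_real_ else pef_pct,
        cat_score = if (is.null(cat_score)) NA_real_ else cat_score,
        exacerbations_12m = facts[["agg.exacerbations_12m"]],
        hospitalizations_12m = facts[["agg.hospitalizations_12m"]],
        high_symptom = high_symptom, high_risk = high_risk
      )
      # 2x2 grid ordered by intensity: I low/low, II high-symptom,
      # III high-risk, IV both
      category <- c("I", "II", "III", "IV")[1 + high_symptom + 2 * high_risk]
      list(factors = factors, category = category)
    },
    stop("unknown disease: ", disease)
  )
  structure(list(disease = disease, factors = out$factors,
                 category = out$category, assessed_at = as_of),
            class = "risk_assessment")
}

#' Hierarchical management level assignment
#'
#' Assigns the patient's management level from the trailing 7-day window of
#' self-monitoring records.  Hypertension has 2 levels (I if the window mean
#' BP meets the target, else II); type 2 diabetes 3 levels (I both FBG and
#' PBG at target, II exactly one, III neither or any hypoglycemia in the
#' window); COPD 4 levels taken directly from the risk-assessment category.
#' With fewer than the configured minimum readings (default 3) the
#' most-intensive level is assigned provisionally, mirroring the initial
#' management period before classification.
#'
#' @inheritParams assess_risk
#' @param risk A `risk_assessment` (required for COPD).
#' @return A list of class `management_level` with elements `disease`,
#'   `level` (integer), `label` (roman numeral), `basis`, `provisional`,
#'   `effective_date`.
#' @export
assign_level <- function(profile, risk = NULL, records, disease, as_of,
                         config = default_config()) {
  dz <- patient_diseases(profile)
  if (!disease %in% dz)
    stop("patient ", profile$patient_id, " is not managed for ", disease)
  as_of <- as.Date(as_of)
  facts <- patient_facts(profile, records, as_of)
  min_n <- config$stratification$min_readings
  provisional <- FALSE
  basis <- list()
  level <- switch(disease,
    HTN = {
      n <- facts[["agg.bp_n_7d"]]
      basis <- list(bp_n = n, sbp_mean = facts[["agg.sbp_mean_7d"]],
                    dbp_mean = facts[["agg.dbp_mean_7d"]])
      if (n < min_n) { provisional <- TRUE; 2L }
      else if (facts[["agg.sbp_mean_7d"]] < profile$sbp_target &&
                 facts[["agg.dbp_mean_7d"]] < profile$dbp_target) 1L else 2L
    },
    T2DM = {
      n <- facts[["agg.bg_n_7d"]]
      basis <- list(bg_n = n, fbg_mean = facts[["agg.fbg_mean_7d"]],
                    pbg_mean = facts[["agg.pbg_mean_7d"]])
      if (n < min_n) { provisional <- TRUE; 3L }
      else if (isTRUE(facts[["agg.hypoglycemia_7d"]])) 3L
      else {
        fbg_ok <- is.null(facts[["agg.fbg_mean_7d"]]) ||
          facts[["agg.fbg_mean_7d"]] < profile$fbg_target
        pbg_ok <- is.null(facts[["agg.pbg_mean_7d"]]) ||
          facts[["agg.pbg_mean_7d"]] < profile$pbg_target
        3L - fbg_ok - pbg_ok
      }
    },
    COPD = {
      if (is.null(risk)) {
        risk <- tryCatch(assess_risk(profile, records, "COPD", as_of, config),
                         error = function(e) NULL)
      }
      if (is.null(risk)) { provisional <- TRUE; basis <- list(); 4L }
      else {
        basis <- risk$factors
        match(risk$category, c("I", "II", "III", "IV"))
      }
    },
    stop("unknown disease: ", disease)
  )
  structure(list(disease = disease, level = as.integer(level),
                 label = as.character(utils::as.roman(level)), basis = basis,
                 provisional = provisional, effective_date = as_of),
            class = "management_level")
}

#' Regular follow-up scheduling
#'
#' Maps a (disease, level) pair to the follow-up interval: hypertension
#' level I every 90 days and level II every 14 days by default (configurable
#' within 14-28 days); type 2 diabetes levels I/II/III every 90/30/14 days;
#' COPD every 14 days at every level.
#'
#' @param disease `"HTN"`, `"T2DM"` or `"COPD"`.
#' @param level Integer level (1-based) or roman-numeral label.
#' @param reference_date Date the interval is counted from.
#' @param config Engine configuration.
#' @return List with `interval_days` and `next_date`.
#' @export
schedule_followup <- function(disease, level, reference_date,
                              config = default_config()) {
  if (is.character(level)) level <- match(level, c("I", "II", "III", "IV"))
  tab <- config$followup[[disease]]
  if (is.null(tab) || is.na(level) || level < 1 || level > length(tab))
    stop("no follow-up interval for (", disease, ", level ", level, ")")
  interval <- tab[[level]]
  list(interval_days = as.integer(interval),
       next_date = as.Date(reference_date) + interval)
}
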