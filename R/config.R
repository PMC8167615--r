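#' Default engine configuration
#'
#' Returns the full set of tunable engine parameters: monitoring targets,
#' warning thresholds, follow-up intervals, compliance settings and
#' task-update frequencies.  All values can be overridden via
#' [read_config()] or by editing the returned list.  Units: pressures in
#' mmHg, glucose in mmol/L, peak expiratory flow in L/min, intervals and
#' windows in days.
#'
#' @return A named nested list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$targets$bp
default_config <- function() {
  list(
    targets = list(
      bp  = c(sbp = 140, dbp = 90),    # attainment means mean BP strictly below both
      bg  = c(fbg = 7.0, pbg = 10.0),
      pef_pct_best = 80                # below this fraction of personal best -> notice
    ),
    warnings = list(
      bp_urgent  = c(sbp_high = 180, dbp_high = 110, sbp_low = 90, dbp_low = 60),
      bg_hypo    = 3.9,
      bg_severe  = 16.7,
      pef_notice_pct = 80,
      pef_urgent_pct = 60,
      cat_threshold  = 10,
      weekly_min_readings = 3
    ),
    followup = list(
      # days between regular follow-ups per (disease, level)
      HTN  = c(90, 14),                # level II configurable in [14, 28]
      T2DM = c(90, 30, 14),
      COPD = c(14, 14, 14, 14)
    ),
    compliance = list(window_days = 7, low_threshold = 0.5),
    frequencies = list(                 # task-update frequencies, days
      compliance = 1,
      stratification = 7,
      risk_assessment = 180
    ),
    stratification = list(min_readings = 3),
    risk_factors = list(
      # HTN cardiovascular risk-factor definitions
      age_cutoff = c(male = 55, female = 65)
    )
  )
}

#' Read an engine configuration file
#'
#' Reads a YAML configuration file and merges it over [default_config()];
#' keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  h2 <- cfg$followup$HTN[2]
  if (h2 < 14 || h2 > 28)
    stop("HTN level II follow-up interval must lie in [14, 28] days, got ", h2)
  if (cfg$compliance$low_threshold < 0 || cfg$compliance$low_threshold > 1)
    stop("compliance low threshold must be a fraction in [0, 1]")
  if (cfg$compliance$window_days < 1) stop("compliance window must be >= 1 day")
  invisible(cfg)
}

# diseases managed by the engine; HM = hypertension with type 2 diabetes
DISEASES <- c("HTN", "T2DM", "COPD")

# the 8 in-system pathway task kinds (diagnosis is out of system scope)
TASK_KINDS <- c(
  "RiskAssessment", "HierarchicalManagement", "RegularFollowUp",
  "AbnormalConditionIntervention", "MedicationGuidance",
  "LifestyleGuidance", "HealthEducation", "ComplianceManagement"
)

RECORD_KINDS <- c("BP", "BG", "PEF", "diet", "exercise", "psychological",
                  "medication", "discomfort")

#' In-system pathway task kinds
#'
#' The eight management tasks the engine generates (diagnosis happens in
#' hospital, before enrollment, and is not an engine task).
#'
#' @return Character vector of length 8.
#' @export
task_kinds <- function() TASK_KINDS

#' Self-monitoring record kinds
#'
#' @return Character vector of the supported record kinds.
#' @export
record_kinds <- function() RECORD_KINDS
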