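#' Construct a patient profile
#'
#' One row per patient.  `diseases` is the non-empty subset of
#' HTN / T2DM / COPD the patient is managed for; the only supported
#' multimorbidity is hypertension with type 2 diabetes (labelled HM), and
#' COPD is managed alone.
#'
#' @param patient_id Unique identifier.
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param diseases Character vector, subset of `c("HTN", "T2DM", "COPD")`.
#' @param enrollment_date Date of enrollment in the management program.
#' @param education Education level.
#' @param sbp_target,dbp_target Blood-pressure targets, mmHg.
#' @param fbg_target,pbg_target Fasting/postprandial glucose targets, mmol/L.
#' @param pef_personal_best Personal-best peak expiratory flow, L/min
#'   (COPD only).
#' @param smoking,obesity,organ_damage,lipid_controlled Risk-factor flags.
#' @return A one-row data.frame of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, age, sex, diseases, enrollment_date,
                            education = "unknown",
                            sbp_target = 140, dbp_target = 90,
                            fbg_target = 7.0, pbg_target = 10.0,
                            pef_personal_best = NA_real_,
                            smoking = FALSE, obesity = FALSE,
                            organ_damage = FALSE, lipid_controlled = TRUE) {
  p <- data.frame(
    patient_id = as.character(patient_id), age = as.numeric(age),
    sex = sex, education = education,
    diseases = paste(sort(unique(diseases)), collapse = ";"),
    enrollment_date = as.Date(enrollment_date),
    sbp_target = sbp_target, dbp_target = dbp_target,
    fbg_target = fbg_target, pbg_target = pbg_target,
    pef_personal_best = as.numeric(pef_personal_best),
    smoking = smoking, obesity = obesity, organ_damage = organ_damage,
    lipid_controlled = lipid_controlled,
    stringsAsFactors = FALSE
  )
  validate_profiles(p)
  class(p) <- c("patient_profile", class(p))
  p
}

PROFILE_COLUMNS <- c("patient_id", "age", "sex", "education", "diseases",
                     "enrollment_date", "sbp_target", "dbp_target",
                     "fbg_target", "pbg_target", "pef_personal_best",
                     "smoking", "obesity", "organ_damage", "lipid_controlled")

validate_profiles <- function(p) {
  stopifnot(is.data.frame(p))
  missing <- setdiff(PROFILE_COLUMNS, names(p))
  if (length(missing))
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(p$patient_id))
    stop("duplicate patient_id in profiles")
  if (any(p$age <= 0)) stop("age must be positive")
  if (!all(p$sex %in% c("male", "female"))) stop("sex must be male or female")
  dz <- strsplit(p$diseases, ";", fixed = TRUE)
  for (i in seq_along(dz)) {
    d <- dz[[i]]
    if (!length(d) || !all(d %in% DISEASES))
      stop("patient ", p$patient_id[i], ": diseases must be a non-empty subset of ",
           paste(DISEASES, collapse = "/"))
    if (length(d) > 1 && !setequal(d, c("HTN", "T2DM")))
      stop("patient ", p$patient_id[i],
           ": HTN+T2DM is the only supported multimorbidity")
  }
  invisible(p)
}

#' Disease group of a patient
#'
#' Collapses the disease set to the four managed pathways:
#' HTN, T2DM, COPD, or HM (hypertension with type 2 diabetes).
#'
#' @param profile A profile row or profile table.
#' @return Character vector of group labels.
#' @export
disease_group <- function(profile) {
  vapply(strsplit(profile$diseases, ";", fixed = TRUE), function(d) {
    if (setequal(d, c("HTN", "T2DM"))) "HM" else d[1]
  }, character(1))
}

patient_diseases <- function(profile_row) {
  strsplit(profile_row$diseases, ";", fixed = TRUE)[[1]]
}

RECORD_COLUMNS <- c("record_id", "patient_id", "timestamp", "kind",
                    "sbp", "dbp", "heart_rate", "bg_type", "bg_value",
                    "ketone", "pef", "scale", "score", "detail")

#' Construct a self-monitoring record
#'
#' @param patient_id Patient identifier.
#' @param timestamp ISO-8601 datetime (or `POSIXct`).
#' @param kind One of [record_kinds()].
#' @param record_id Unique record identifier (generated if missing).
#' @param ... Kind-specific values: `sbp`, `dbp`, `heart_rate` (BP);
#'   `bg_type` ("FBG"/"PBG"), `bg_value`, `ketone` (BG); `pef` (PEF);
#'   `scale` ("CAT"/"other"), `score` (psychological); `detail`
#'   (free text, e.g. `"acute_exacerbation"` on a discomfort record).
#' @return A one-row data.frame with the canonical record columns.
#' @export
monitoring_record <- function(patient_id, timestamp, kind,
                              record_id = NULL, ...) {
  v <- list(...)
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (is.null(record_id))
    record_id <- sprintf("%s-%s-%s", patient_id, kind,
                         format(ts, "%Y%m%d%H%M%S"))
  r <- data.frame(
    record_id = record_id, patient_id = as.character(patient_id),
    timestamp = ts, kind = kind,
    sbp = v$sbp %||% NA_real_, dbp = v$dbp %||% NA_real_,
    heart_rate = v$heart_rate %||% NA_real_,
    bg_type = v$bg_type %||% NA_character_,
    bg_value = v$bg_value %||% NA_real_,
    ketone = v$ketone %||% NA,
    pef = v$pef %||% NA_real_,
    scale = v$scale %||% NA_character_, score = v$score %||% NA_real_,
    detail = v$detail %||% NA_character_,
    stringsAsFactors = FALSE
  )
  validate_records(r)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_records <- function() {
  data.frame(
    record_id = character(0), patient_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"), kind = character(0),
    sbp = numeric(0), dbp = numeric(0), heart_rate = numeric(0),
    bg_type = character(0), bg_value = numeric(0), ketone = logical(0),
    pef = numeric(0), scale = character(0), score = numeric(0),
    detail = character(0), stringsAsFactors = FALSE
  )
}

# Returns a character vector of row-level problems ("" when clean); used by
# both the constructors (which stop) and the file readers (which report
# line numbers).
record_problems <- function(r) {
  msg <- character(nrow(r))
  bad <- !r$kind %in% RECORD_KINDS
  msg[bad] <- paste0("unknown record kind '", r$kind[bad], "'")
  i <- r$kind == "BP" & msg == ""
  bp_bad <- i & (is.na(r$sbp) | is.na(r$dbp) | r$dbp <= 0 | r$sbp <= r$dbp)
  msg[bp_bad] <- "BP record requires sbp > dbp > 0"
  i <- r$kind == "BG" & msg == ""
  bg_bad <- i & (is.na(r$bg_value) | r$bg_value <= 0 |
                   is.na(r$bg_type) | !r$bg_type %in% c("FBG", "PBG"))
  msg[bg_bad] <- "BG record requires bg_type in FBG/PBG and bg_value > 0"
  i <- r$kind == "PEF" & msg == ""
  pef_bad <- i & (is.na(r$pef) | r$pef <= 0)
  msg[pef_bad] <- "PEF record requires pef > 0"
  i <- r$kind == "psychological" & msg == "" &
    !is.na(r$scale) & r$scale == "CAT"
  cat_bad <- i & (is.na(r$score) | r$score < 0 | r$score > 40)
  msg[cat_bad] <- "CAT score must lie in [0, 40]"
  msg
}

validate_records <- function(r) {
  pr <- record_problems(r)
  if (any(pr != ""))
    stop("invalid record(s): ",
         paste(sprintf("row %d: %s", which(pr != ""), pr[pr != ""]),
               collapse = "; "))
  invisible(r)
}
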