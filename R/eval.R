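#' Descriptive summary of a cohort
#'
#' Counts self-monitoring records by kind and disease group and summarizes
#' demographics, mirroring the standard usage tables of a telehealth
#' deployment report.
#'
#' @param profiles Profile table.
#' @param records Record table (every `patient_id` must appear in
#'   `profiles`).
#' @return List with `record_counts` (kind x disease-group matrix of
#'   counts), `record_percent` (column percentages), and `demographics`.
#' @export
descriptive_summary <- function(profiles, records) {
  if (nrow(records) && !all(records$patient_id %in% profiles$patient_id))
    stop("records reference unknown patients")
  grp <- stats::setNames(disease_group(profiles), profiles$patient_id)
  groups <- c("HTN", "T2DM", "HM", "COPD")
  counts <- matrix(0L, nrow = length(RECORD_KINDS), ncol = length(groups),
                   dimnames = list(RECORD_KINDS, groups))
  if (nrow(records)) {
    tab <- table(factor(records$kind, levels = RECORD_KINDS),
                 factor(grp[records$patient_id], levels = groups))
    counts[] <- as.integer(tab)
  }
  pct <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
  demo <- list(
    n_patients = nrow(profiles),
    age_mean = mean(profiles$age), age_sd = stats::sd(profiles$age),
    male_fraction = mean(profiles$sex == "male"),
    disease_mix = table(factor(grp, levels = groups)) / nrow(profiles)
  )
  list(record_counts = counts, record_percent = pct, demographics = demo)
}

#' Paired Student t test from differences
#'
#' The closed form: `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom, two-sided p value from the t distribution.
#'
#' @param differences Numeric vector of paired differences (length >= 2,
#'   nonzero variance).
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (n < 2) stop("paired t test needs at least 2 differences")
  s <- stats::sd(d)
  if (s == 0) stop("degenerate variance: all differences identical")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), n = n)
}

#' Windowed before/after outcome comparison
#'
#' For each patient, the "before" mean is taken over the records in the
#' first two weeks after enrollment, `[enrollment, enrollment + 14d)`, and
#' the "after" mean over the two weeks following the given span,
#' `[enrollment + span, enrollment + span + 14d)`; both windows are
#' half-open.  Patients lacking records in either window are excluded, and
#' a paired two-sided t test is applied to the per-patient means.
#'
#' @param records Record table.
#' @param profiles Profile table (supplies enrollment dates).
#' @param outcome `"SBP"`, `"FBG"` or `"PEF"`.
#' @param span_days Time span, days (>= 14).
#' @return A list of class `span_comparison`: `span_days`, `n_patients`,
#'   `mean_before`, `mean_after`, `mean_diff`, `t_statistic`, `p_value`.
#' @export
before_after <- function(records, profiles, outcome, span_days) {
  if (span_days < 14) stop("span_days must be >= 14")
  val <- outcome_values(records, outcome)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    pid <- profiles$patient_id[i]
    e <- profiles$enrollment_date[i]
    r <- val[val$patient_id == pid, , drop = FALSE]
    b <- r$value[in_window(r$timestamp, e, e + 14)]
    a <- r$value[in_window(r$timestamp, e + span_days, e + span_days + 14)]
    if (!length(b) || !length(a)) return(NULL)
    c(before = mean(b), after = mean(a))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) < 2)
    stop("insufficient data: fewer than 2 patients with records in both windows")
  tt <- paired_t(out[, "after"] - out[, "before"])
  structure(list(span_days = span_days, n_patients = nrow(out),
                 mean_before = mean(out[, "before"]),
                 mean_after = mean(out[, "after"]),
                 mean_diff = tt$mean_diff, t_statistic = tt$t,
                 p_value = tt$p_value),
            class = "span_comparison")
}

#' @export
print.span_comparison <- function(x, ...) {
  cat(sprintf(
    "<span_comparison> %d days: n=%d, before %.2f, after %.2f (diff %+.2f), t=%.3f, p=%.4g\n",
    x$span_days, x$n_patients, x$mean_before, x$mean_after, x$mean_diff,
    x$t_statistic, x$p_value))
  invisible(x)
}

# outcome extraction: one value column per supported physiological index
outcome_values <- function(records, outcome) {
  r <- switch(outcome,
    SBP = {
      x <- records[records$kind == "BP", , drop = FALSE]
      data.frame(patient_id = x$patient_id, timestamp = x$timestamp,
                 value = x$sbp, stringsAsFactors = FALSE)
    },
    FBG = {
      x <- records[records$kind == "BG" & !is.na(records$bg_type) &
                     records$bg_type == "FBG", , drop = FALSE]
      data.frame(patient_id = x$patient_id, timestamp = x$timestamp,
                 value = x$bg_value, stringsAsFactors = FALSE)
    },
    PEF = {
      x <- records[records$kind == "PEF", , drop = FALSE]
      data.frame(patient_id = x$patient_id, timestamp = x$timestamp,
                 value = x$pef, stringsAsFactors = FALSE)
    },
    stop("unsupported outcome: ", outcome)
  )
  r
}

#' Care-provider work-efficiency metrics
#'
#' Per provider: the distribution of follow-up counts per active day (an
#' active day is one with at least one follow-up) and the monthly
#' distribution of response days — the delay between the engine generating a
#' follow-up request and the provider completing it — summarized as median,
#' quartiles and 1.5-IQR outliers.
#'
#' @param interventions Intervention table with `provider_id`,
#'   `patient_id`, `kind`, `requested_at`, `completed_at`.
#' @return A list of class `efficiency_report`, one entry per provider with
#'   `followups_per_day` (histogram table), `mean_per_active_day`,
#'   `n_followups`, and `monthly_response` (per-month median, quartiles,
#'   outliers).
#' @export
efficiency_report <- function(interventions) {
  fu <- interventions[interventions$kind == "regular_followup", , drop = FALSE]
  if (any(as.Date(fu$completed_at) < as.Date(fu$requested_at)))
    stop("completed_at precedes requested_at")
  out <- lapply(split(fu, fu$provider_id), function(g) {
    per_day <- table(as.character(as.Date(g$completed_at)))
    hist <- table(as.integer(per_day))
    resp <- as.numeric(as.Date(g$completed_at) - as.Date(g$requested_at))
    month <- format(as.Date(g$requested_at), "%Y-%m")
    monthly <- lapply(split(resp, month), function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      list(median = q[2], q1 = q[1], q3 = q[3],
           outliers = v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr])
    })
    list(followups_per_day = hist,
         mean_per_active_day = mean(as.integer(per_day)),
         n_followups = nrow(g), n_active_days = length(per_day),
         mean_response_days = mean(resp),
         monthly_response = monthly)
  })
  structure(out, class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  for (p in names(x))
    cat(sprintf("%s: %d follow-ups over %d active days (mean %.1f/day), mean response %.1f days\n",
                p, x[[p]]$n_followups, x[[p]]$n_active_days,
                x[[p]]$mean_per_active_day, x[[p]]$mean_response_days))
  invisible(x)
}
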