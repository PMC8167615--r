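#' Extract the causal-episode dataset
#'
#' Builds the (treatment, outcome, confounders) rows the propensity-score
#' estimators consume.  Each completed intervention yields one treated
#' episode whose outcome is the mean of the patient's outcome records in the
#' 30 days after the intervention, `(t, t + 30d]`.  Control episodes are
#' 14-day intervention-free windows — at most one per eligible patient per
#' 30-day block, chosen seed-controlled — whose mean outcome is the control
#' outcome.  Confounders are evaluated at the episode's initial time point:
#' age, the latest management level, whether any abnormal warning was
#' reported during the episode window, and the time since enrollment.
#' Episodes with no outcome records are dropped; the number dropped is
#' attached as attribute `"n_dropped"`.
#'
#' @param records Record table.
#' @param interventions Intervention table (`patient_id`, `requested_at`,
#'   `completed_at`).
#' @param profiles Profile table.
#' @param levels Optional data.frame `patient_id`, `date`, `level` of level
#'   history; when absent all episodes get level 1.
#' @param warnings Optional warning table (`patient_id`, `raised_at`).
#' @param outcome `"SBP"`, `"FBG"` or `"PEF"`.
#' @param seed Seed controlling control-window placement.
#' @return A `causal_data` data.frame (see [simulate_causal_episodes()]).
#' @export
extract_causal_dataset <- function(records, interventions, profiles,
                                   levels = NULL, warnings = NULL,
                                   outcome = "SBP", seed = 1L) {
  set.seed(seed)
  val <- outcome_values(records, outcome)
  val$day <- as.Date(val$timestamp)
  rows <- list()
  n_dropped <- 0L
  warn_days <- if (!is.null(warnings) && nrow(warnings))
    split(as.Date(warnings$raised_at), warnings$patient_id) else list()
  level_at <- function(pid, day) {
    if (is.null(levels)) return(1L)
    h <- levels[levels$patient_id == pid & as.Date(levels$date) <= day, ,
                drop = FALSE]
    if (!nrow(h)) 1L else h$level[which.max(as.Date(h$date))]
  }
  any_warning <- function(pid, start, end) {
    w <- warn_days[[pid]]
    !is.null(w) && any(w >= start & w < end)
  }
  for (i in seq_len(nrow(profiles))) {
    pid <- profiles$patient_id[i]
    enroll <- profiles$enrollment_date[i]
    v <- val[val$patient_id == pid, , drop = FALSE]
    iv <- interventions[interventions$patient_id == pid, , drop = FALSE]
    iv_days <- sort(as.Date(iv$completed_at))
    # treated episodes: one per intervention, outcome over (t, t + 30]
    for (t0 in as.list(iv_days)) {
      y <- v$value[v$day > t0 & v$day <= t0 + 30]
      if (!length(y)) { n_dropped <- n_dropped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        treatment = TRUE, outcome = mean(y), age = profiles$age[i],
        management_level = level_at(pid, t0),
        abnormal_warning = any_warning(pid, t0, t0 + 30),
        management_time = as.numeric(t0 - enroll),
        stringsAsFactors = FALSE)
    }
    # control episodes: one intervention-free 14-day window per 30-day block
    if (!nrow(v)) next
    last_day <- max(v$day)
    blocks <- seq(enroll, last_day, by = "30 days")
    for (b0 in as.list(blocks)) {
      start <- b0 + sample.int(16, 1) - 1L   # window fits inside the block
      end <- start + 14
      if (length(iv_days) &&
          any(iv_days >= start - 14 & iv_days < end)) next
      y <- v$value[v$day >= start & v$day < end]
      if (!length(y)) { n_dropped <- n_dropped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        treatment = FALSE, outcome = mean(y), age = profiles$age[i],
        management_level = level_at(pid, start),
        abnormal_warning = any_warning(pid, start, end),
        management_time = as.numeric(start - enroll),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = logical(0), outcome = numeric(0), age = numeric(0),
               management_level = integer(0), abnormal_warning = logical(0),
               management_time = numeric(0))
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("causal_data", class(out))
  out
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Fit the propensity model
#'
#' Main-effects logistic regression of treatment on the four confounders:
#' standardized age, ordinal management level, abnormal-warning indicator,
#' and standardized management time.
#'
#' @param rows A `causal_data` data.frame.
#' @return Numeric vector of propensity scores in (0, 1), with the fitted
#'   `glm` attached as attribute `"model"`.
#' @export
fit_propensity <- function(rows) {
  if (length(unique(rows$treatment)) < 2)
    stop("both treatment classes must be present to fit a propensity model")
  d <- data.frame(
    t = rows$treatment,
    age_z = standardize(rows$age),
    level = as.numeric(rows$management_level),
    warning = as.numeric(rows$abnormal_warning),
    time_z = standardize(rows$management_time)
  )
  fit <- suppressWarnings(
    stats::glm(t ~ age_z + level + warning + time_z, data = d,
               family = stats::binomial()))
  scores <- as.numeric(stats::fitted(fit))
  # perfect separation: every treated row fitted at 1 and every control at 0
  eps <- 1e-8
  if (all(scores[d$t] > 1 - eps) && all(scores[!d$t] < eps))
    stop("perfect separation: propensity scores degenerate at 0/1; ",
         "check confounder coding", call. = FALSE)
  scores <- pmin(pmax(scores, eps), 1 - eps)
  attr(scores, "model") <- fit
  scores
}

ate_estimate <- function(method, estimate, n_treated, n_control,
                         diagnostics = list()) {
  structure(list(method = method, estimate = estimate,
                 n_treated = n_treated, n_control = n_control,
                 diagnostics = diagnostics),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("<ate_estimate> %s: %.3f (treated %d, control %d)\n",
              x$method, x$estimate, x$n_treated, x$n_control))
  invisible(x)
}

#' Naive difference in means
#'
#' The unadjusted contrast `mean(Y | treated) - mean(Y | control)`; under
#' confounding this is biased and serves as the reference the
#' propensity-score estimators are compared against.
#'
#' @param rows A `causal_data` data.frame.
#' @return An `ate_estimate`.
#' @export
estimate_ate_naive <- function(rows) {
  if (length(unique(rows$treatment)) < 2)
    stop("both treatment classes must be present")
  ate_estimate("naive",
               mean(rows$outcome[rows$treatment]) -
                 mean(rows$outcome[!rows$treatment]),
               sum(rows$treatment), sum(!rows$treatment))
}

#' Average treatment effect by propensity-score matching
#'
#' 1:1 nearest-neighbor matching on the propensity score, with replacement;
#' the estimate is the mean over treated episodes of the treated-minus-
#' matched-control outcome difference.  Ties are broken by seed-controlled
#' randomization.  An optional caliper (in score units) raises a positivity
#' error when some treated unit has no control within it.
#'
#' @param rows A `causal_data` data.frame.
#' @param scores Propensity scores from [fit_propensity()] (refit when
#'   omitted).
#' @param seed Seed for tie-breaking.
#' @param caliper Optional maximum score distance (default off).
#' @return An `ate_estimate` with overlap diagnostics.
#' @export
estimate_ate_psm <- function(rows, scores = NULL, seed = 1L, caliper = NULL) {
  if (is.null(scores)) scores <- fit_propensity(rows)
  set.seed(seed)
  ti <- which(rows$treatment)
  ci <- which(!rows$treatment)
  if (!length(ti) || !length(ci))
    stop("both treatment classes must be present")
  cs <- scores[ci]
  ord <- order(cs, stats::runif(length(cs)))  # randomize equal scores
  cs_sorted <- cs[ord]
  ci_sorted <- ci[ord]
  pos <- findInterval(scores[ti], cs_sorted)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(cs_sorted))
  d_lo <- abs(scores[ti] - cs_sorted[lo])
  d_hi <- abs(scores[ti] - cs_sorted[hi])
  take_lo <- d_lo <= d_hi
  match_idx <- ifelse(take_lo, ci_sorted[lo], ci_sorted[hi])
  dist <- pmin(d_lo, d_hi)
  if (!is.null(caliper) && any(dist > caliper))
    stop("positivity violation: ", sum(dist > caliper),
         " treated episode(s) have no control within the caliper")
  est <- mean(rows$outcome[ti] - rows$outcome[match_idx])
  ate_estimate("PSM", est, length(ti), length(unique(match_idx)),
               diagnostics = list(
                 mean_match_distance = mean(dist),
                 score_range_treated = range(scores[ti]),
                 score_range_control = range(cs)))
}

#' Average treatment effect by propensity-score stratification
#'
#' Episodes are cut into equal-frequency strata of the propensity score;
#' strata missing either class are dropped (reported in diagnostics) and the
#' estimate is the stratum-effect average weighted by each stratum's share
#' of the retained sample.
#'
#' @inheritParams estimate_ate_psm
#' @param n_strata Number of strata (>= 2, default 5).
#' @return An `ate_estimate`.
#' @export
estimate_ate_pss <- function(rows, scores = NULL, n_strata = 5) {
  if (n_strata < 2) stop("n_strata must be >= 2")
  if (is.null(scores)) scores <- fit_propensity(rows)
  if (length(unique(rows$treatment)) < 2)
    stop("both treatment classes must be present")
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(scores, breaks = br, include.lowest = TRUE)
  eff <- n <- numeric(0)
  dropped <- 0L
  for (s in levels(stratum)) {
    i <- which(stratum == s)
    t <- rows$treatment[i]
    if (!any(t) || all(t)) { dropped <- dropped + 1L; next }
    eff <- c(eff, mean(rows$outcome[i][t]) - mean(rows$outcome[i][!t]))
    n <- c(n, length(i))
  }
  if (!length(eff)) stop("all strata lack a treatment class; cannot estimate")
  ate_estimate("PSS", sum(eff * n / sum(n)),
               sum(rows$treatment), sum(!rows$treatment),
               diagnostics = list(n_strata = length(levels(stratum)),
                                  strata_dropped = dropped,
                                  strata_n = n))
}

#' Refutation checks for a propensity-score estimate
#'
#' Robustness checks on an estimated effect: `placebo_treatment` permutes
#' the treatment labels (a valid pipeline should then find an effect near
#' zero); `random_common_cause` adds an independent noise covariate to the
#' propensity model (the estimate should barely move); `subset` re-estimates
#' on random 80% subsets (the estimate should be stable).
#'
#' @param rows A `causal_data` data.frame.
#' @param estimator `"PSM"` or `"PSS"`.
#' @param method Refuter to run.
#' @param reps Number of repetitions (>= 2).
#' @param seed Seed.
#' @param tolerance Pass threshold: for `placebo_treatment`, the absolute
#'   mean refuted estimate; for the other two, the absolute shift from the
#'   original estimate.
#' @param subset_fraction Fraction retained by the `subset` refuter.
#' @return List of class `refutation`: `method`, `original`, `refuted`
#'   (mean over reps), `shift`, `passed`, `reps`.
#' @export
refute <- function(rows, estimator = c("PSM", "PSS"),
                   method = c("placebo_treatment", "random_common_cause",
                              "subset"),
                   reps = 10, seed = 1L, tolerance = 0.5,
                   subset_fraction = 0.8) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  if (reps < 2) stop("reps must be >= 2")
  est_fun <- function(r, sc, sd_) switch(estimator,
    PSM = estimate_ate_psm(r, sc, seed = sd_)$estimate,
    PSS = estimate_ate_pss(r, sc)$estimate)
  set.seed(seed)
  original <- est_fun(rows, fit_propensity(rows), seed)
  vals <- vapply(seq_len(reps), function(k) {
    switch(method,
      placebo_treatment = {
        r <- rows
        r$treatment <- sample(r$treatment)
        est_fun(r, fit_propensity(r), seed + k)
      },
      random_common_cause = {
        d <- data.frame(t = rows$treatment,
                        age_z = standardize(rows$age),
                        level = as.numeric(rows$management_level),
                        warning = as.numeric(rows$abnormal_warning),
                        time_z = standardize(rows$management_time),
                        noise = stats::rnorm(nrow(rows)))
        fit <- suppressWarnings(
          stats::glm(t ~ age_z + level + warning + time_z + noise,
                     data = d, family = stats::binomial()))
        est_fun(rows, as.numeric(stats::fitted(fit)), seed + k)
      },
      subset = {
        i <- sample(nrow(rows), floor(subset_fraction * nrow(rows)))
        r <- rows[i, , drop = FALSE]
        est_fun(r, fit_propensity(r), seed + k)
      })
  }, numeric(1))
  refuted <- mean(vals)
  shift <- if (method == "placebo_treatment") abs(refuted)
           else abs(refuted - original)
  structure(list(method = method, estimator = estimator,
                 original = original, refuted = refuted, shift = shift,
                 passed = shift <= tolerance, reps = reps,
                 tolerance = tolerance),
            class = "refutation")
}

#' @export
print.refutation <- function(x, ...) {
  cat(sprintf("<refutation> %s on %s: original %.3f, refuted %.3f (shift %.3f) -> %s\n",
              x$method, x$estimator, x$original, x$refuted, x$shift,
              if (x$passed) "pass" else "FAIL"))
  invisible(x)
}
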