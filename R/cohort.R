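# Cohort-level clinical analysis: responder classification, score-cutoff
# stratification, response-rate and contingency tables, product-limit
# survival, log-rank comparisons, and response-duration summaries.

#' RECIST responder classification
#'
#' Complete or partial response (CR/PR) is a responder; stable or
#' progressive disease (SD/PD) is a non-responder.
#'
#' @param best_response character vector of RECIST 1.1 best-response codes.
#' @return character vector `"responder"` / `"non_responder"`.
#' @export
classify_response <- function(best_response) {
  br <- toupper(trimws(best_response))
  bad <- !(br %in% c("CR", "PR", "SD", "PD"))
  if (any(bad)) {
    stop("invalid_recist_code: ", paste(unique(best_response[bad]), collapse = ", "))
  }
  ifelse(br %in% c("CR", "PR"), "responder", "non_responder")
}

#' Stratify a cohort at a score cutoff
#'
#' Partitions patients into a high stratum (score strictly above the
#' cutoff) and a low stratum (at or below); patients missing the score go
#' to an `excluded` bucket, never silently dropped.
#'
#' @param cohort data.frame of patient records.
#' @param score_name column holding the score, e.g. `"pd1_score"`.
#' @param cutoff stratification cutoff, default 4.
#' @return list with data.frames `above`, `at_or_below`, `excluded`.
#' @export
stratify_by_score <- function(cohort, score_name, cutoff = 4) {
  if (!score_name %in% names(cohort)) {
    stop("missing score column: ", score_name)
  }
  s <- cohort[[score_name]]
  list(above = cohort[!is.na(s) & s > cutoff, , drop = FALSE],
       at_or_below = cohort[!is.na(s) & s <= cutoff, , drop = FALSE],
       excluded = cohort[is.na(s), , drop = FALSE])
}

#' Response rates per stratum
#'
#' @param strata named list of disjoint patient data.frames, each with a
#'   `best_response` column.
#' @return data.frame: stratum, responders, total, percent (rounded to the
#'   nearest integer; `NA` for an empty stratum).
#' @export
response_rate_table <- function(strata) {
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    total <- nrow(d)
    resp <- if (total) sum(classify_response(d$best_response) == "responder") else 0L
    data.frame(stratum = nm, responders = resp, total = total,
               percent = if (total) round(100 * resp / total) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Standard product-limit estimator; at tied times events precede
#' censorings. Thin wrapper shaping [survival::survfit()] output into a
#' plain table.
#'
#' @param times follow-up times (months), nonnegative.
#' @param events logical/0-1 event indicators (TRUE = event observed).
#' @return object of class `survival_curve`: list with `times`, `survival`,
#'   `at_risk`, `n_events`, `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty_cohort")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_events = fit$n.event,
                 n = length(times)),
            class = "survival_curve")
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a `survival_curve` (right-continuous).
#' @param curve a `survival_curve`.
#' @param t time(s) at which to evaluate.
#' @return estimated S(t).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$times <= tt)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Unweighted log-rank chi-squared statistic (1 df) with the p-value from
#' the upper chi-squared tail.
#'
#' @param times_a,events_a,times_b,events_b follow-up times and event flags
#'   for the two groups.
#' @return list with `statistic` and `p_value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) stop("empty_group")
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  if (sum(event) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Compare a variable between responders and non-responders
#'
#' Continuous variables get a Wilcoxon rank-sum test (exact when both
#' groups have at most 10 observations and no ties, normal approximation
#' with tie correction otherwise). Categorical variables get a Pearson
#' chi-squared test without continuity correction, falling back to Fisher's
#' exact test when a 2x2 table has any expected cell below 5.
#'
#' @param responders,non_responders vectors of the variable in each group.
#' @param type `"continuous"` or `"categorical"`.
#' @return list: `test_used`, `statistic`, `p_value`, and `table` for
#'   categorical comparisons.
#' @export
compare_groups <- function(responders, non_responders,
                           type = c("continuous", "categorical")) {
  type <- match.arg(type)
  responders <- responders[!is.na(responders)]
  non_responders <- non_responders[!is.na(non_responders)]
  if (length(responders) == 0 && length(non_responders) == 0) stop("no_data")
  if (type == "continuous") {
    exact <- length(responders) <= 10 && length(non_responders) <= 10 &&
      !anyDuplicated(c(responders, non_responders))
    wt <- suppressWarnings(
      stats::wilcox.test(responders, non_responders,
                         exact = exact, correct = FALSE)
    )
    return(list(test_used = "wilcoxon_rank_sum",
                statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  values <- c(responders, non_responders)
  group <- rep(c("responder", "non_responder"),
               c(length(responders), length(non_responders)))
  tab <- table(group, values)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(test_used = "fisher_exact", statistic = NA_real_,
                p_value = ft$p.value, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test_used = "chi_squared", statistic = unname(ct$statistic),
       p_value = ct$p.value, table = tab)
}

#' Per-stratum response-duration summary
#'
#' Duration of response is (response end, or last follow-up for ongoing
#' responses) minus response start, computed for responders only; strata
#' means are compared with a Wilcoxon rank-sum test. Responders missing a
#' response start are excluded with a warning.
#'
#' @param cohort patient data.frame (columns `best_response`,
#'   `response_start_months`, `response_end_months`, `ongoing`,
#'   `os_months`).
#' @param stratifier logical/character vector (length nrow(cohort)) naming
#'   each patient's stratum.
#' @return list: `summary` data.frame (stratum, n, mean_duration),
#'   `durations` per patient, and `p_value` comparing the two strata.
#' @export
duration_summary <- function(cohort, stratifier) {
  stopifnot(length(stratifier) == nrow(cohort))
  resp <- classify_response(cohort$best_response) == "responder"
  d <- cohort[resp, , drop = FALSE]
  strat <- as.character(stratifier)[resp]
  missing_start <- is.na(d$response_start_months)
  if (any(missing_start)) {
    warning(sum(missing_start), " responder(s) missing response_start_months; excluded")
    strat <- strat[!missing_start]
    d <- d[!missing_start, , drop = FALSE]
  }
  end <- ifelse(!is.na(d$ongoing) & d$ongoing, d$os_months,
                d$response_end_months)
  end[is.na(end)] <- d$os_months[is.na(end)]  # last follow-up fallback
  dur <- end - d$response_start_months
  summ <- stats::aggregate(dur, by = list(stratum = strat),
                           FUN = function(x) c(n = length(x), mean = mean(x)))
  summary_df <- data.frame(stratum = summ$stratum,
                           n = summ$x[, "n"], mean_duration = summ$x[, "mean"])
  p <- NA_real_
  lv <- unique(strat)
  if (length(lv) == 2 && all(table(strat) >= 1)) {
    p <- compare_groups(dur[strat == lv[1]], dur[strat == lv[2]],
                        type = "continuous")$p_value
  }
  list(summary = summary_df,
       durations = data.frame(patient_id = d$patient_id, stratum = strat,
                              duration_months = dur),
       p_value = p)
}

#' Swimmer-plot data table
#'
#' One row per patient with treatment/response timeline markers, sorted by
#' stratum then by follow-up duration; plotting is left to downstream tools.
#'
#' @param cohort patient data.frame.
#' @param stratum optional per-patient stratum labels.
#' @return data.frame: patient_id, stratum, response class, follow-up,
#'   response start/end, ongoing flag.
#' @export
swimmer_table <- function(cohort, stratum = NULL) {
  if (nrow(cohort) == 0) {
    return(data.frame(patient_id = character(0), stratum = character(0),
                      response = character(0), followup_months = numeric(0),
                      response_start_months = numeric(0),
                      response_end_months = numeric(0), ongoing = logical(0)))
  }
  if (is.null(stratum)) stratum <- rep("all", nrow(cohort))
  out <- data.frame(
    patient_id = cohort$patient_id,
    stratum = as.character(stratum),
    response = classify_response(cohort$best_response),
    followup_months = cohort$os_months,
    response_start_months = cohort$response_start_months,
    response_end_months = ifelse(!is.na(cohort$ongoing) & cohort$ongoing,
                                 NA_real_, cohort$response_end_months),
    ongoing = !is.na(cohort$ongoing) & cohort$ongoing,
    stringsAsFactors = FALSE
  )
  out[order(out$stratum, -out$followup_months), , drop = FALSE]
}
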