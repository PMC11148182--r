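# CSV schemas and the top-level pipeline: plates -> scores -> cohort
# analysis -> predictive evaluation, with a machine-readable config echo so
# any run is reproducible from its outputs.

.plate_cols <- c("plate_id", "sample_id", "condition", "signal",
                 "coverage_mm2", "replicate_index")
.cohort_cols <- c("patient_id", "best_response", "os_months", "os_event",
                  "pfs_months", "pfs_event", "line_of_treatment",
                  "cps_value", "pd1_score", "pdl1_score", "pdl2_score",
                  "response_start_months", "response_end_months", "ongoing")

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

.as_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop("non-numeric value in column '", col, "' at row ", bad[1])
  }
  out
}

.as_bool <- function(x, col, required = TRUE) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "t", "yes")] <- TRUE
  out[lx %in% c("0", "false", "f", "no")] <- FALSE
  bad <- which(is.na(out) & !(lx %in% c("", "na")))
  if (length(bad)) stop("non-boolean value in column '", col, "' at row ", bad[1])
  if (required && anyNA(out)) {
    stop("missing value in column '", col, "' at row ", which(is.na(out))[1])
  }
  out
}

#' Read a plate CSV of raw wells
#'
#' One row per well; required columns `plate_id, sample_id, condition,
#' signal, coverage_mm2, replicate_index`. Condition labels are matched
#' case-insensitively against the enumeration; unknown columns are kept.
#'
#' @param path CSV path (UTF-8, header required).
#' @return typed data.frame of wells.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .plate_cols, "plate CSV")
  df$condition <- normalize_condition(df$condition)
  df$signal <- .as_num(df$signal, "signal")
  if (anyNA(df$signal)) {
    stop("missing signal at row ", which(is.na(df$signal))[1])
  }
  if (any(df$signal < 0)) stop("signal must be nonnegative")
  df$coverage_mm2 <- .as_num(df$coverage_mm2, "coverage_mm2")
  samp <- !(df$condition %in% c("POSITIVE_CONTROL", "BLANK"))
  if (any(samp & (is.na(df$coverage_mm2) | df$coverage_mm2 <= 0))) {
    stop("sample wells need positive coverage_mm2 (row ",
         which(samp & (is.na(df$coverage_mm2) | df$coverage_mm2 <= 0))[1], ")")
  }
  df$replicate_index <- as.integer(df$replicate_index)
  df
}

#' Read a cohort CSV of patient records
#'
#' Required columns per the cohort schema; booleans accept 0/1/true/false;
#' `cps_value` and the response-timeline columns may be blank.
#'
#' @param path CSV path.
#' @return typed data.frame of patient records.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .cohort_cols, "cohort CSV")
  classify_response(df$best_response)  # validates codes
  for (col in c("os_months", "pfs_months", "cps_value", "pd1_score",
                "pdl1_score", "pdl2_score", "response_start_months",
                "response_end_months")) {
    df[[col]] <- .as_num(df[[col]], col)
  }
  df$os_event <- .as_bool(df$os_event, "os_event")
  df$pfs_event <- .as_bool(df$pfs_event, "pfs_event")
  df$ongoing <- .as_bool(df$ongoing, "ongoing", required = FALSE)
  df$line_of_treatment <- as.integer(df$line_of_treatment)
  if (any(df$os_months < 0 | df$pfs_months < 0, na.rm = TRUE)) {
    stop("survival times must be nonnegative")
  }
  df
}

#' Write a cohort CSV
#' @param cohort patient data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[, .cohort_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a plate CSV
#' @param wells well data.frame.
#' @param path output path.
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells[, .plate_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Scores plates (if given), merges scores into the cohort, stratifies at
#' the score cutoff, computes response-rate tables, survival comparisons,
#' the response-duration summary, the swimmer table, and the predictive
#' cohort-sampling curve; writes all tables plus a JSON summary and a
#' config echo under `out_dir`.
#'
#' @param cohort patient data.frame (see [read_cohort_csv()]).
#' @param wells optional well data.frame; when given, plate-derived scores
#'   replace the cohort's score columns.
#' @param out_dir output directory, created if needed; `NULL` skips file
#'   output.
#' @param score_name score used for stratification, default `"pd1_score"`.
#' @param cutoff stratification cutoff, default 4.
#' @param cps_threshold CPS positivity threshold, default 1.
#' @param sizes,repeats cohort-sampling protocol parameters.
#' @param seed master seed for all randomness.
#' @param pc_reference see [plate_normalization()].
#' @return (invisibly) list with scores, stratified response-rate tables,
#'   survival results, duration summary, swimmer table, sampling curve, and
#'   the JSON-ready summary.
#' @export
run_pipeline <- function(cohort, wells = NULL, out_dir = NULL,
                         score_name = "pd1_score", cutoff = 4,
                         cps_threshold = 1, sizes = 15:29, repeats = 100,
                         seed = 1, pc_reference = NULL) {
  scores <- NULL
  if (!is.null(wells)) {
    scores <- score_plates(wells, pc_reference = pc_reference)
    message("scored ", nrow(scores), " samples from ", nrow(wells), " wells")
    keep <- setdiff(names(cohort), c("pd1_score", "pdl1_score", "pdl2_score"))
    cohort <- merge(cohort[, keep],
                    scores[, c("sample_id", "pd1_score", "pdl1_score",
                               "pdl2_score")],
                    by.x = "patient_id", by.y = "sample_id", all.x = TRUE)
  }
  cohort$responder <- classify_response(cohort$best_response) == "responder"

  strata <- stratify_by_score(cohort, score_name, cutoff)
  score_rates <- response_rate_table(
    stats::setNames(strata[c("above", "at_or_below")],
                    c(paste0(score_name, ">", cutoff),
                      paste0(score_name, "<=", cutoff))))

  cps_rates <- NULL; cps_logrank <- NULL
  has_cps <- !is.na(cohort$cps_value)
  if (any(has_cps)) {
    cps_pos <- has_cps & classify_cps(cohort$cps_value, cps_threshold) == "positive"
    cps_neg <- has_cps & !cps_pos
    cps_rates <- response_rate_table(list(
      "cps_positive" = cohort[cps_pos, , drop = FALSE],
      "cps_negative" = cohort[cps_neg, , drop = FALSE]))
    cc <- cohort[has_cps, , drop = FALSE]
    cps_logrank <- logrank_test(
      cc$os_months[cc$responder], cc$os_event[cc$responder],
      cc$os_months[!cc$responder], cc$os_event[!cc$responder])
  } else {
    message("no CPS values present; CPS-stratified tables not computed")
  }

  hi <- strata$above; lo <- strata$at_or_below
  os_logrank <- logrank_test(hi$os_months, hi$os_event,
                             lo$os_months, lo$os_event)
  pfs_logrank <- logrank_test(hi$pfs_months, hi$pfs_event,
                              lo$pfs_months, lo$pfs_event)
  km_high <- km_estimate(hi$os_months, hi$os_event)
  km_low <- km_estimate(lo$os_months, lo$os_event)

  in_strata <- rbind(hi, lo)
  strat_label <- rep(c("above", "at_or_below"), c(nrow(hi), nrow(lo)))
  duration <- duration_summary(in_strata, strat_label)
  swimmer <- swimmer_table(in_strata, strat_label)

  curve <- cohort_sampling_curve(cohort[stats::complete.cases(
    cohort[, c("pd1_score", "pdl1_score", "pdl2_score")]), , drop = FALSE],
    sizes = sizes, repeats = repeats, seed = seed)

  summary <- list(
    config = list(score_name = score_name, cutoff = cutoff,
                  cps_threshold = cps_threshold, sizes = range(sizes),
                  repeats = repeats, seed = seed,
                  n_patients = nrow(cohort)),
    response_rates_by_score = score_rates,
    response_rates_by_cps = cps_rates,
    os_logrank = os_logrank, pfs_logrank = pfs_logrank,
    cps_os_logrank = cps_logrank,
    duration = duration$summary, duration_p = duration$p_value,
    predictive_min_auc = min(curve$summary$min_auc),
    predictive_mean_auc = mean(curve$summary$mean_auc)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(scores)) {
      utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(score_rates,
                     file.path(out_dir, "response_rates_by_score.csv"),
                     row.names = FALSE)
    if (!is.null(cps_rates)) {
      utils::write.csv(cps_rates,
                       file.path(out_dir, "response_rates_by_cps.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(swimmer, file.path(out_dir, "swimmer.csv"),
                     row.names = FALSE)
    utils::write.csv(curve$per_repeat,
                     file.path(out_dir, "predictive_auc.csv"),
                     row.names = FALSE)
    utils::write.csv(curve$summary,
                     file.path(out_dir, "predictive_auc_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  invisible(c(summary, list(strata = strata, swimmer = swimmer,
                            sampling_curve = curve, km_high = km_high,
                            km_low = km_low, scores = scores)))
}
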