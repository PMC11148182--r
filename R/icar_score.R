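# Core functionality-score arithmetic: delta response, plate normalization,
# and the per-ligand score  delta / log2(coverage) * pc_ratio.

#' Recognised blocking conditions
#' @export
BLOCKING_CONDITIONS <- c("NO_AB", "BLOCK_PD1", "BLOCK_PDL1", "BLOCK_PDL2",
                         "POSITIVE_CONTROL", "BLANK")

.block_conditions <- c("BLOCK_PD1", "BLOCK_PDL1", "BLOCK_PDL2")
.score_names <- c(BLOCK_PD1 = "pd1_score", BLOCK_PDL1 = "pdl1_score",
                  BLOCK_PDL2 = "pdl2_score")

#' Normalise a blocking-condition label
#'
#' Case-insensitive match against the condition enumeration; anything else
#' is rejected.
#' @param x character vector of labels.
#' @return vector of canonical labels.
#' @export
normalize_condition <- function(x) {
  up <- toupper(trimws(x))
  bad <- !(up %in% BLOCKING_CONDITIONS)
  if (any(bad)) {
    stop("invalid_condition: ", paste(unique(x[bad]), collapse = ", "))
  }
  up
}

#' Blocking-induced drop in reporter signal
#'
#' The delta response for one sample/condition is the mean unblocked
#' (no-antibody) reporter signal minus the mean signal under the blocking
#' antibody. A negative delta (blocking *raised* the signal) is retained,
#' not clamped, and flagged `"negative_delta"`.
#'
#' @param unblocked_wells,blocked_wells data.frames of wells (see
#'   [read_plate_csv()] for the schema); unblocked wells must have condition
#'   `NO_AB`, and both sets must share one `sample_id` and `plate_id`.
#' @return list with `delta`, per-set replicate `sd`s, and `qc` flags.
#' @export
compute_delta_response <- function(unblocked_wells, blocked_wells) {
  if (nrow(unblocked_wells) == 0 || nrow(blocked_wells) == 0) {
    stop("missing_condition: empty well set")
  }
  ids <- unique(c(unblocked_wells$sample_id, blocked_wells$sample_id))
  plates <- unique(c(unblocked_wells$plate_id, blocked_wells$plate_id))
  if (length(ids) != 1 || length(plates) != 1) {
    stop("sample_mismatch: wells span multiple sample_ids or plate_ids")
  }
  if (any(unblocked_wells$condition != "NO_AB")) {
    stop("missing_condition: unblocked wells must have condition NO_AB")
  }
  delta <- mean(unblocked_wells$signal) - mean(blocked_wells$signal)
  qc <- character(0)
  if (delta < 0) qc <- "negative_delta"
  list(delta = delta,
       sd_unblocked = stats::sd(unblocked_wells$signal),
       sd_blocked = stats::sd(blocked_wells$signal),
       qc = qc)
}

#' Functionality score from delta response, coverage and plate normalization
#'
#' The score is the blocking-induced signal drop per log2 mm^2 of tissue,
#' harmonised across plates by the positive-control ratio:
#' `delta / log2(coverage_mm2) * pc_ratio`.
#'
#' @param delta delta response (may be negative).
#' @param coverage_mm2 tissue surface coverage in mm^2; must exceed 1 so the
#'   log2 divisor stays positive.
#' @param pc_ratio positive-control ratio for this plate (> 0).
#' @return the score (real, possibly negative).
#' @export
compute_icar_score <- function(delta, coverage_mm2, pc_ratio) {
  if (any(coverage_mm2 <= 1)) {
    stop("coverage_too_small: coverage_mm2 must exceed 1 mm^2")
  }
  if (any(pc_ratio <= 0)) stop("pc_ratio must be positive")
  delta / log2(coverage_mm2) * pc_ratio
}

#' Per-plate positive-control normalization
#'
#' The plate's PC ratio is a configured cross-experiment reference signal
#' divided by the plate's own mean positive-control signal; multiplying a
#' plate's scores by it puts all plates on the reference scale.
#'
#' @param wells well table containing `POSITIVE_CONTROL` rows.
#' @param pc_reference reference positive-control signal. Default `NULL`
#'   uses the grand mean of all positive-control wells in `wells` (so a
#'   single-run analysis is normalised to its own average plate).
#' @return data.frame with one row per plate: `plate_id`, `pc_response`,
#'   `pc_reference`, `pc_ratio`.
#' @export
plate_normalization <- function(wells, pc_reference = NULL) {
  pc <- wells[wells$condition == "POSITIVE_CONTROL", , drop = FALSE]
  if (nrow(pc) == 0) stop("missing_condition: no POSITIVE_CONTROL wells")
  per_plate <- stats::aggregate(signal ~ plate_id, data = pc, FUN = mean)
  names(per_plate)[2] <- "pc_response"
  if (any(per_plate$pc_response <= 0)) {
    stop("positive-control signal must be positive")
  }
  if (is.null(pc_reference)) pc_reference <- mean(pc$signal)
  per_plate$pc_reference <- pc_reference
  per_plate$pc_ratio <- pc_reference / per_plate$pc_response
  per_plate
}

#' Score one patient sample from its wells
#'
#' Computes the PD-1, PD-L1 and PD-L2 functionality scores for a single
#' sample on a single plate: one delta response per blocking condition
#' against the shared no-antibody wells, each divided by log2 of the
#' sample's mean coverage and scaled by the plate's PC ratio. A missing
#' blocking condition yields an `NA` score and a `missing_<condition>` flag.
#'
#' @param wells wells of one `sample_id` on one `plate_id` (conditions
#'   `NO_AB` and any of the three blocking conditions).
#' @param norm the plate's normalization row from [plate_normalization()],
#'   or a single pc_ratio value.
#' @return one-row data.frame: `sample_id`, `pd1_score`, `pdl1_score`,
#'   `pdl2_score`, `qc_flags` (semicolon-joined).
#' @export
score_patient <- function(wells, norm) {
  pc_ratio <- if (is.data.frame(norm)) {
    stopifnot(nrow(norm) == 1)
    norm$pc_ratio
  } else as.numeric(norm)
  wells <- wells[!(wells$condition %in% c("POSITIVE_CONTROL", "BLANK")), ,
                 drop = FALSE]
  sid <- unique(wells$sample_id)
  if (length(sid) != 1) stop("sample_mismatch: expected a single sample_id")
  unb <- wells[wells$condition == "NO_AB", , drop = FALSE]
  if (nrow(unb) == 0) stop("missing_condition: no NO_AB wells")
  coverage <- mean(wells$coverage_mm2)

  scores <- stats::setNames(rep(NA_real_, 3), unname(.score_names))
  flags <- character(0)
  for (cond in .block_conditions) {
    blk <- wells[wells$condition == cond, , drop = FALSE]
    if (nrow(blk) == 0) {
      flags <- c(flags, paste0("missing_", cond))
      next
    }
    dr <- compute_delta_response(unb, blk)
    flags <- c(flags, dr$qc)
    scores[[.score_names[[cond]]]] <-
      compute_icar_score(dr$delta, coverage, pc_ratio)
  }
  data.frame(sample_id = sid,
             pd1_score = scores[["pd1_score"]],
             pdl1_score = scores[["pdl1_score"]],
             pdl2_score = scores[["pdl2_score"]],
             qc_flags = paste(unique(flags), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Score every sample on every plate
#'
#' Applies blank subtraction (when `BLANK` wells exist), computes per-plate
#' PC ratios, and scores each sample with [score_patient()].
#'
#' @param wells full well table (all plates).
#' @param pc_reference see [plate_normalization()].
#' @param blank_subtract subtract each plate's mean blank signal from all of
#'   its wells before scoring (default TRUE when blanks are present).
#' @return data.frame of per-sample scores.
#' @export
score_plates <- function(wells, pc_reference = NULL, blank_subtract = TRUE) {
  wells$condition <- normalize_condition(wells$condition)
  if (blank_subtract && any(wells$condition == "BLANK")) {
    bl <- wells[wells$condition == "BLANK", , drop = FALSE]
    bmean <- stats::aggregate(signal ~ plate_id, data = bl, FUN = mean)
    names(bmean)[2] <- ".blank"
    wells <- merge(wells, bmean, by = "plate_id", all.x = TRUE)
    adj <- !is.na(wells$.blank) & wells$condition != "BLANK"
    wells$signal[adj] <- pmax(wells$signal[adj] - wells$.blank[adj], 0)
    wells$.blank <- NULL
  }
  norm <- plate_normalization(wells, pc_reference = pc_reference)
  samp <- wells[!(wells$condition %in% c("POSITIVE_CONTROL", "BLANK")), ,
                drop = FALSE]
  keys <- unique(samp[, c("plate_id", "sample_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    w <- samp[samp$plate_id == keys$plate_id[i] &
                samp$sample_id == keys$sample_id[i], , drop = FALSE]
    score_patient(w, norm[norm$plate_id == keys$plate_id[i], , drop = FALSE])
  })
  do.call(rbind, out)
}
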