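# Combined Positive Score (CPS) for PD-L1 immunohistochemistry.

#' Combined Positive Score from cell counts
#'
#' CPS = 100 x (PD-L1-positive tumor cells + PD-L1-positive immune cells)
#' / total viable tumor cells. Positive immune cells are lymphocytes plus
#' macrophages within the tumor area.
#'
#' @param pdl1_positive_tumor_cells,pdl1_positive_immune_cells nonnegative
#'   integer counts.
#' @param total_viable_tumor_cells positive integer count.
#' @return the CPS value (nonnegative real; can exceed 100 because immune
#'   cells enter the numerator only).
#' @export
compute_cps <- function(pdl1_positive_tumor_cells,
                        pdl1_positive_immune_cells,
                        total_viable_tumor_cells) {
  if (any(total_viable_tumor_cells < 1)) {
    stop("total_viable_tumor_cells must be >= 1")
  }
  if (any(pdl1_positive_tumor_cells < 0) ||
      any(pdl1_positive_immune_cells < 0)) {
    stop("counts must be nonnegative")
  }
  if (any(pdl1_positive_tumor_cells > total_viable_tumor_cells)) {
    stop("count_inconsistency: positive tumor cells exceed total viable tumor cells")
  }
  100 * (pdl1_positive_tumor_cells + pdl1_positive_immune_cells) /
    total_viable_tumor_cells
}

#' CPS positivity call
#'
#' A CPS at or above the threshold (conventionally 1) is positive.
#'
#' @param cps_value nonnegative CPS value(s); `NA` propagates.
#' @param threshold positivity threshold, default 1.
#' @param inclusive is the boundary itself positive? Default TRUE
#'   (CPS >= 1 signifies positivity).
#' @return character vector `"positive"` / `"negative"`.
#' @export
classify_cps <- function(cps_value, threshold = 1, inclusive = TRUE) {
  pos <- if (inclusive) cps_value >= threshold else cps_value > threshold
  ifelse(pos, "positive", "negative")
}

#' Band CPS values into the conventional reporting categories
#'
#' Partitions nonnegative CPS values into `<1%`, `1-20%` and `>20%`.
#'
#' @param cps_value nonnegative CPS value(s).
#' @return factor with levels `<1%`, `1-20%`, `>20%`.
#' @export
band_cps <- function(cps_value) {
  cut(cps_value, breaks = c(-Inf, 1, 20, Inf), right = FALSE,
      labels = c("<1%", "1-20%", ">20%")) ->
    b
  # right = FALSE puts exactly 20 into ">20%"; the convention is 1-20 inclusive
  b[!is.na(cps_value) & cps_value == 20] <- "1-20%"
  b
}
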