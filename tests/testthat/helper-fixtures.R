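# Fixture builders shared across test files.

# One sample's wells on one plate, one well per condition unless signals
# are vectors (then one well per replicate).
make_wells <- function(sample_id = "S1", plate_id = "PLATE01",
                       no_ab = 100, pd1 = 40, pdl1 = 70, pdl2 = 90,
                       coverage = 4) {
  conds <- list(NO_AB = no_ab, BLOCK_PD1 = pd1, BLOCK_PDL1 = pdl1,
                BLOCK_PDL2 = pdl2)
  conds <- conds[!vapply(conds, is.null, logical(1))]
  do.call(rbind, lapply(names(conds), function(cn) {
    sig <- conds[[cn]]
    data.frame(plate_id = plate_id, sample_id = sample_id, condition = cn,
               signal = sig, coverage_mm2 = coverage,
               replicate_index = seq_along(sig), stringsAsFactors = FALSE)
  }))
}

pc_wells <- function(plate_id = "PLATE01", signal = 1000, n = 2) {
  data.frame(plate_id = plate_id, sample_id = "PC",
             condition = "POSITIVE_CONTROL", signal = rep(signal, n),
             coverage_mm2 = NA_real_, replicate_index = seq_len(n),
             stringsAsFactors = FALSE)
}

# Minimal valid patient record(s); fields overridable per patient.
make_cohort <- function(n = 4, best_response = c("PR", "CR", "SD", "PD"),
                        os_months = 10, os_event = TRUE,
                        pfs_months = 5, pfs_event = TRUE,
                        pd1_score = 5, pdl1_score = 3, pdl2_score = 2,
                        cps_value = 10, line_of_treatment = 1,
                        response_start_months = NA_real_,
                        response_end_months = NA_real_, ongoing = FALSE) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             best_response = rep_len(best_response, n),
             os_months = rep_len(os_months, n),
             os_event = rep_len(os_event, n),
             pfs_months = rep_len(pfs_months, n),
             pfs_event = rep_len(pfs_event, n),
             line_of_treatment = rep_len(line_of_treatment, n),
             cps_value = rep_len(cps_value, n),
             pd1_score = rep_len(pd1_score, n),
             pdl1_score = rep_len(pdl1_score, n),
             pdl2_score = rep_len(pdl2_score, n),
             response_start_months = rep_len(response_start_months, n),
             response_end_months = rep_len(response_end_months, n),
             ongoing = rep_len(ongoing, n),
             stringsAsFactors = FALSE)
}

# Independent product-limit oracle: direct evaluation of the definition,
# never via the survival package.
hand_km <- function(times, events, at) {
  ts <- sort(unique(times[events]))
  s <- 1
  for (tt in ts[ts <= at]) {
    n_risk <- sum(times >= tt)
    d <- sum(times == tt & events)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Independent log-rank oracle: observed-minus-expected over event times.
hand_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(times[events]))) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp1)
    d <- sum(times == tt & events)
    d1 <- sum(times == tt & events & grp1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}
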