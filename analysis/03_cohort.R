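#!/usr/bin/env Rscript
# Stage 3: clinical evaluation — responder classification, stratification
# at the score cutoff of 4 and by CPS positivity, response-rate tables,
# overall-survival log-rank comparisons, response-duration summary, and the
# swimmer table. Writes the per-stratum tables under results/.

library(icar)

cohort <- read_cohort_csv("results/cohort.csv")
scores <- read.csv("results/scores.csv")
cohort <- merge(cohort[, setdiff(names(cohort),
                                 c("pd1_score", "pdl1_score", "pdl2_score"))],
                scores[, c("sample_id", "pd1_score", "pdl1_score",
                           "pdl2_score")],
                by.x = "patient_id", by.y = "sample_id")

strat <- stratify_by_score(cohort, "pd1_score", cutoff = 4)
rr <- response_rate_table(list("pd1>4" = strat$above,
                               "pd1<=4" = strat$at_or_below))
write.csv(rr, "results/response_rates_by_score.csv", row.names = FALSE)
cat("response rates by PD-1 score stratum:\n")
print(rr, row.names = FALSE)

has_cps <- !is.na(cohort$cps_value)
pos <- has_cps & classify_cps(cohort$cps_value) == "positive"
rr_cps <- response_rate_table(list(
  cps_positive = cohort[pos, ], cps_negative = cohort[has_cps & !pos, ]))
write.csv(rr_cps, "results/response_rates_by_cps.csv", row.names = FALSE)
cat("\nresponse rates by CPS status (", sum(has_cps), "evaluable ):\n")
print(rr_cps, row.names = FALSE)

lr <- logrank_test(strat$above$os_months, strat$above$os_event,
                   strat$at_or_below$os_months, strat$at_or_below$os_event)
cat(sprintf("\nOS log-rank, pd1>4 vs <=4: chi2 = %.2f, p = %.4f\n",
            lr$statistic, lr$p_value))

resp <- classify_response(cohort$best_response) == "responder"
lr_cps <- logrank_test(cohort$os_months[has_cps & resp],
                       cohort$os_event[has_cps & resp],
                       cohort$os_months[has_cps & !resp],
                       cohort$os_event[has_cps & !resp])
cat(sprintf("OS log-rank, responders vs non-responders (CPS-evaluable): p = %.4f\n",
            lr_cps$p_value))

in_strata <- rbind(strat$above, strat$at_or_below)
lab <- rep(c("pd1>4", "pd1<=4"),
           c(nrow(strat$above), nrow(strat$at_or_below)))
dur <- duration_summary(in_strata, lab)
write.csv(dur$summary, "results/duration_summary.csv", row.names = FALSE)
cat("\nmean response duration by stratum (months):\n")
print(dur$summary, row.names = FALSE)
cat(sprintf("rank-sum p = %.4f\n", dur$p_value))

sw <- swimmer_table(in_strata, lab)
write.csv(sw, "results/swimmer.csv", row.names = FALSE)
cat(sprintf("\nswimmer table: %d rows, %d ongoing responses\n",
            nrow(sw), sum(sw$ongoing)))
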