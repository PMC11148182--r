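#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — a 29-patient cohort with
# the default (study-condition) preset, plus the raw 96-well plate
# measurements realizing each patient's latent functionality scores.
# Writes plates.csv, cohort.csv and truth.csv under results/.

library(icar)

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
g <- generate_cohort(cfg)
pl <- generate_plates(g$truth, cfg)

write_cohort_csv(g$cohort, "results/cohort.csv")
write_plate_csv(pl$wells, "results/plates.csv")
write.csv(g$truth, "results/truth.csv", row.names = FALSE)
write.csv(pl$plate_truth, "results/plate_truth.csv", row.names = FALSE)
writeLines(as.character(pl$pc_reference), "results/pc_reference.txt")

n_resp <- sum(classify_response(g$cohort$best_response) == "responder")
cat(sprintf("cohort: %d patients, %d responders (%.0f%%)\n",
            nrow(g$cohort), n_resp, 100 * n_resp / nrow(g$cohort)))
cat(sprintf("plates: %d wells on %d plates, %.0f%% well noise\n",
            nrow(pl$wells), nrow(pl$plate_truth), 100 * cfg$well_noise_sd))
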