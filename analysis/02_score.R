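#!/usr/bin/env Rscript
# Stage 2: score the raw plates into per-patient PD-1 / PD-L1 / PD-L2
# functionality scores, and check recovery against the generator's latent
# truth. Writes scores.csv.

library(icar)

wells <- read_plate_csv("results/plates.csv")
pc_reference <- as.numeric(readLines("results/pc_reference.txt"))
scores <- score_plates(wells, pc_reference = pc_reference)
write.csv(scores, "results/scores.csv", row.names = FALSE)

truth <- read.csv("results/truth.csv")
m <- merge(scores, truth, by.x = "sample_id", by.y = "patient_id")
cat(sprintf("scored %d patients from %d wells\n", nrow(scores), nrow(wells)))
for (lig in c("pd1", "pdl1", "pdl2")) {
  r <- cor(m[[paste0(lig, "_score")]], m[[paste0(lig, "_latent")]])
  cat(sprintf("  %-5s score vs latent: r = %.3f\n", lig, r))
}
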