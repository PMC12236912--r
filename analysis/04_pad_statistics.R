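#!/usr/bin/env Rscript
# Stage 4: descriptive PAD statistics from the persisted predictions.
#
# Re-derives, from results/replica/pad_table.csv alone, the per-group
# accuracy and PAD summaries (by diagnosis, by site, and by the four
# diagnosis x age-25 cells), the true-age correlations, and the pairwise
# Levene variance tests - the study's Tables 3-5 layouts.

library(brainpad)

pad <- read.csv("results/replica/pad_table.csv")
class(pad) <- c("pad_table", "data.frame")
dir.create("results/pad", showWarnings = FALSE)

by_dx <- group_metrics(pad, "diagnosis")
by_cell <- group_metrics(pad, interaction(pad$diagnosis, pad$age_partition,
                                          sep = " "))
by_site_dx <- group_metrics(pad, interaction(pad$site, pad$diagnosis,
                                             sep = " "))
write.csv(by_dx, "results/pad/metrics_by_diagnosis.csv", row.names = FALSE)
write.csv(by_cell, "results/pad/metrics_by_cell.csv", row.names = FALSE)
write.csv(by_site_dx, "results/pad/metrics_by_site.csv", row.names = FALSE)

cat("PAD by diagnosis:\n"); print(by_dx)
cat("\nPAD by diagnosis x age partition:\n"); print(by_cell)

cors <- correlations(pad)
write.csv(cors, "results/pad/correlations.csv", row.names = FALSE)
cat("\ncorrelations:\n"); print(cors)

lev <- pairwise_variance_tests(pad)
write.csv(lev, "results/pad/levene_tests.csv", row.names = FALSE)
cat("\npairwise Levene tests (6 pairs + overall):\n"); print(lev)
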