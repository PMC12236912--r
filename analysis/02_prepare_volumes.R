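#!/usr/bin/env Rscript
# Stage 2: volume preparation - load/render, center-crop, QC, stack.
#
# Phantoms are rendered at 28 x 32 x 28 voxels and center-cropped to the
# 24 x 28 x 24 grid the CNN consumes (mirroring the 91x109x91 -> 75x88x78
# crop of the full-size pipeline, whose margins are printed below). QC
# flags non-finite voxels and empty channels; the stacked batch follows
# the (batch, channel, X, Y, Z) layout.

library(brainpad)

seed <- 1L
cfg <- replica_config(seed = seed)
dir.create("results", showWarnings = FALSE)

# the full-size crop this stage mirrors
src <- c(91, 109, 91); tgt <- c(75, 88, 78)
lo <- (src - tgt) %/% 2
cat(sprintf("full-size crop %s -> %s: low margins (%s), high margins (%s)\n",
            paste(src, collapse = "x"), paste(tgt, collapse = "x"),
            paste(lo, collapse = ", "),
            paste(src - tgt - lo, collapse = ", ")))

coh <- brainpad:::simulate_stage(cfg, "test")
sub <- coh[1:24, ]
class(sub) <- class(coh)
attr(sub, "spec") <- attr(coh, "spec")
attr(sub, "site_offsets") <- attr(coh, "site_offsets")

prep <- prepare_cohort(sub, cfg$phantom, cfg$target_dims, cfg$control_noise_sd)
cat(sprintf("prepared batch: %s (%d subjects passed QC of %d)\n",
            paste(dim(prep$batch$data), collapse = " x "),
            sum(prep$qc), length(prep$qc)))

qc_tab <- data.frame(subject_id = names(prep$qc), qc_pass = unname(prep$qc))
write.csv(qc_tab, "results/prep_qc.csv", row.names = FALSE)

# the binary array cache round-trips exactly
cache <- file.path("scratch", "batch_cache.rds")
dir.create("scratch", showWarnings = FALSE)
save_batch_cache(prep$batch, cache)
stopifnot(identical(load_batch_cache(cache), prep$batch))
cat("array cache round-trip verified:", cache, "\n")
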