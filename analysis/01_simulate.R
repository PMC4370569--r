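#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs every later stage consumes.
# A two-chromosome toy genome with subtelomeric end-domains, tRNA and LTR
# features (LTRs biased to the subtelomere borders), a ChIP-like log2-ratio
# track with a +1 log2 effect over subtelomeres and tRNA genes, a paired
# occupancy table with a 0.5-fold decrease at LTRs, and spot tables for
# four strains with decreasing peripheral anchoring.

suppressMessages(library(nucorg))

seed <- 42
out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- make_genome_and_features(
  c(chrA = 200000, chrB = 200000),
  feature_plan = data.frame(
    class = c("tRNA", "LTR", "LTR"),
    n = c(60L, 10L, 12L),
    length = c(300L, 350L, 350L),
    placement = c("uniform", "uniform", "subtelomere_border")
  ),
  subtelomere_length = 15000, seed = seed, out_dir = out)
cat("genome:", paste(GenomeInfoDb::seqnames(g$layout), collapse = ", "),
    "|", length(g$features), "features\n")
print(table(g$features$feature_class))

sim <- simulate_probe_signal(g$layout, g$features,
                             target_classes = c("subtelomere", "tRNA"),
                             effect = 1, probe_step = 60, seed = seed + 1)
write_bedgraph(sim$condition, file.path(out, "chip.bedgraph"))
write_bedgraph(sim$control, file.path(out, "control.bedgraph"))
write_bedgraph(sim$ratio, file.path(out, "ratio.bedgraph"))
cat("probe tracks:", length(sim$ratio), "probes,",
    sum(sim$mask), "over target classes\n")

occ <- simulate_occupancy(g$features, class_label = "LTR",
                          mu = 100, dispersion = 10, fold = 0.5,
                          seed = seed + 2)
write.table(occ, file.path(out, "occupancy_LTR.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("occupancy table:", nrow(occ), "LTR features, simulated fold 0.5\n")

# peripheral anchoring: wt strong, single mutants intermediate, double weak
presets <- list(
  wt = c(0.75, 0.15, 0.10),
  fft3d = c(0.70, 0.18, 0.12),
  bqt4d = c(0.55, 0.25, 0.20),
  bqt4d_fft3d = c(0.40, 0.28, 0.32)
)
spots <- do.call(rbind, lapply(seq_along(presets), function(i) {
  simulate_spots(150, names(presets)[i], presets[[i]], seed = seed + 10 + i)
}))
write.table(spots[, c("cell_id", "strain", "radius_um", "distance_um")],
            file.path(out, "spots.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("spot table:", nrow(spots), "cells over", length(presets), "strains\n")
cat("fixtures written to", out, "\n")
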