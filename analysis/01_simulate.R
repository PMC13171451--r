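#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Two objects are produced under results/analysis/:
#   * a 2 Mb softmasked random genome (40.3% lowercase repeat content) with
#     its repeat/non-repeat mask in BED4, plus a matching 2 Mb initiation
#     signal track on the same coordinates (for the repeat-partition step);
#   * a 10 Mb initiation signal track from the default generator model (for
#     the distance-distribution step) together with its ground truth.
# All signal values are on the log10(pseudo-reads + 1) scale.

suppressMessages(library(noisefloor))
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L

message("generating 2 Mb softmasked genome (repeat fraction 0.403) ...")
genome <- gen_masked_sequence(2e6, repeat_fraction = 0.403, seed = seed,
                              name = "synth")
write_fasta(genome, file.path(out, "genome.fa"))
mask <- case_mask_intervals(genome)
write_bed(mask, file.path(out, "mask.bed"))
frac <- sum(mask$end[mask$class == "repeat"] -
              mask$start[mask$class == "repeat"]) / 2e6
message(sprintf("  realized repeat fraction: %.3f over %d mask intervals",
                frac, nrow(mask)))

message("generating 2 Mb initiation track on the genome coordinates ...")
small <- gen_tss_track(track_model(length = 2e6, seed = seed))
write_bedgraph(small$track, file.path(out, "signal_2mb.bedgraph"))
message(sprintf("  %d TSSs in %d truth clusters",
                nrow(small$truth$tss), nrow(small$truth$clusters)))

message("generating 10 Mb softmask (for the repeat-partition step) ...")
genome10 <- gen_masked_sequence(1e7, repeat_fraction = 0.403,
                                seed = seed + 2L, name = "synth")
write_bed(case_mask_intervals(genome10), file.path(out, "mask_10mb.bed"))

message("generating 10 Mb initiation track for distance analyses ...")
big <- gen_tss_track(track_model(length = 1e7, seed = seed + 1L))
write_bedgraph(big$track, file.path(out, "signal_10mb.bedgraph"))
write.table(big$truth$tss, file.path(out, "truth_tss_10mb.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(big$truth$clusters, file.path(out, "truth_clusters_10mb.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d TSSs in %d truth clusters; P(gap <= 25 bp) = %.4f",
                nrow(big$truth$tss), nrow(big$truth$clusters),
                expected_short_gap_fraction(track_model(length = 1e7))))
message("done; inputs written under ", out)
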