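#!/usr/bin/env Rscript
# Step 2: build the randomized genome variants.
#
# From the synthetic softmasked genome of step 1, produce the full panel of
# randomizations used for noise-floor estimation: whole-sequence reversal,
# global and 100 bp sliding-window (step 50) mono- and dinucleotide
# shuffles, and repeat-only / non-repeat-only reversal and mononucleotide
# shuffling. Each output is checked for the invariant its construction
# guarantees (composition, dinucleotide multiset, or untouched mask).

suppressMessages(library(noisefloor))
out <- "results/analysis"
genome <- read_fasta(file.path(out, "genome.fa"))
seed <- 20260922L

mono <- function(s) table(strsplit(s, "")[[1]])
dinu <- function(s) {
  n <- nchar(s)
  sort(table(substring(s, 1:(n - 1), 2:n)))
}

variants <- list()
message("reversing ...")
variants$reversed <- reverse_sequence(genome)

message("global mononucleotide shuffle ...")
variants$shuffle_mono_global <-
  shuffle_klet_global(genome, shuffle_spec(k = 1, seed = seed))
message("global dinucleotide shuffle ...")
variants$shuffle_di_global <-
  shuffle_klet_global(genome, shuffle_spec(k = 2, seed = seed))
message("windowed (100/50) mononucleotide shuffle ...")
variants$shuffle_mono_local <- shuffle_klet_windowed(
  genome, shuffle_spec(k = 1, scope = "windowed", window = 100, step = 50,
                       seed = seed))
message("windowed (100/50) dinucleotide shuffle ...")
variants$shuffle_di_local <- shuffle_klet_windowed(
  genome, shuffle_spec(k = 2, scope = "windowed", window = 100, step = 50,
                       seed = seed))
message("repeat-only and non-repeat-only randomization ...")
variants$repeats_reversed <-
  randomize_mask_class(genome, "repeat", "reverse")
variants$nonrepeats_reversed <-
  randomize_mask_class(genome, "non_repeat", "reverse")
variants$repeats_shuffled <-
  randomize_mask_class(genome, "repeat", "shuffle",
                       shuffle_spec(k = 1, seed = seed))
variants$nonrepeats_shuffled <-
  randomize_mask_class(genome, "non_repeat", "shuffle",
                       shuffle_spec(k = 1, seed = seed))

# invariant checks
stopifnot(identical(mono(variants$reversed[[1]]), mono(genome[[1]])))
stopifnot(identical(mono(variants$shuffle_mono_global[[1]]),
                    mono(genome[[1]])))
stopifnot(identical(dinu(variants$shuffle_di_global[[1]]),
                    dinu(genome[[1]])))
stopifnot(identical(mono(variants$shuffle_mono_local[[1]]),
                    mono(genome[[1]])))
for (v in c("repeats_reversed", "nonrepeats_reversed",
            "repeats_shuffled", "nonrepeats_shuffled")) {
  stopifnot(identical(case_mask_intervals(variants[[v]]),
                      case_mask_intervals(genome)))
}
message("all construction invariants hold")

for (nm in names(variants)) {
  v <- variants[[nm]]
  names(v) <- paste0(names(genome), "_", nm)
  write_fasta(v, file.path(out, paste0("genome_", nm, ".fa")))
}
message("wrote ", length(variants), " randomized variants under ", out)
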