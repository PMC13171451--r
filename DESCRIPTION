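Package: noisefloor
Title: Background Transcription Initiation Analysis via Genome Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the background ("noise floor") level of
    transcription initiation in large genomes. Provides case-preserving
    softmasked FASTA handling, genome randomization operators (sequence
    reversal, exact mono- and dinucleotide k-let shuffles both globally and
    in sliding windows, and repeat/non-repeat restricted randomization),
    conversion of log10(s+1)-scale transcription-initiation prediction
    tracks into integer pseudo-read counts, transcription start site (TSS)
    calling, max-gap TSS clustering with the standard cluster summary
    statistics, inter-cluster distance distributions with mode counting,
    threshold sweeps, repeat/non-repeat TSS partitioning, and a synthetic
    track generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
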