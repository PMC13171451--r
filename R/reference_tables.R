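# Published genome-scale reference statistics for the human T2T assembly.
#
# These tables record the headline numbers of a genome-wide survey of
# predicted and experimentally assayed transcription initiation in the human
# telomere-to-telomere (CHM13v2.0) assembly and its randomized variants
# (reversed, mono-/dinucleotide shuffled locally and globally, and with only
# the repeat or non-repeat regions randomized). Reproducing those runs needs
# the full assembly and a deep-learning predictor; the printed counts are
# instead used here as worked-example inputs for the metric definitions:
# the derived columns (mean TSSs per cluster, class percentages) must be
# recoverable from the counts by this package's own arithmetic.

#' Reference genome-scale TSS cluster statistics
#'
#' One row per dataset: TSS and cluster counts plus the published summary
#' columns (mean cluster width in bp, mean TSSs per cluster, mean inter-TSS
#' and inter-cluster distances in bp), all at a calling threshold of one
#' (pseudo-)read and a 25 bp cluster merge distance.
#'
#' @return A data.frame with 12 rows.
#' @export
reference_tss_metrics <- function() {
  data.frame(
    dataset = c("experimental GRO-cap", "T2T forward", "T2T reversed",
                "local dinucleotide shuffled", "global dinucleotide shuffled",
                "local mononucleotide shuffled",
                "global mononucleotide shuffled",
                "reversed repeats", "reversed non-repeats",
                "repeats globally shuffled", "non-repeats globally shuffled",
                "forward holdout chromosomes"),
    n_tss = c(2218983, 2258412, 522771, 444570, 17272, 8498, 101,
              1490275, 600400, 963766, 1415927, 218958),
    n_clusters = c(741856, 287993, 47125, 67639, 6338, 2332, 52,
                   267250, 80708, 129563, 182790, 31144),
    mean_cluster_width = c(11.8, 26.5, 44.5, 25.6, 11.8, 14.5, 5.3,
                           20.8, 26.0, 25.7, 26.4, 24.2),
    mean_tss_per_cluster = c(2.99, 7.84, 11.09, 6.57, 2.73, 3.64, 1.94,
                             5.58, 7.44, 7.44, 7.75, 7.03),
    mean_inter_tss_distance = c(1358, 1377, 5924, 6978, 175000, 306682,
                                5721320, 2087, 5170, 3225, 2194, 1969),
    mean_inter_cluster_distance = c(4051, 10772, 65703, 45853, 478038,
                                    1125994, 13731162, 11616, 38447, 23971,
                                    16974, 13823),
    stringsAsFactors = FALSE
  )
}

#' Reference repeat/non-repeat TSS partition
#'
#' One row per dataset: TSS counts inside repeat and non-repeat regions, the
#' published class percentages, and the published length-normalised
#' densities (TSS per kb of class sequence; `NA` where printed only as an
#' upper bound below 0.001). Shuffles are global mononucleotide shuffles of
#' the named regions.
#'
#' @return A data.frame with 5 rows.
#' @export
reference_repeat_partition <- function() {
  data.frame(
    dataset = c("experimental GRO-cap", "forward", "repeat regions shuffled",
                "non-repeat regions shuffled", "whole genome shuffled"),
    n_repeat_tss = c(216778, 147285, 255512, 27759, 73),
    n_nonrepeat_tss = c(2000498, 2111127, 708254, 332784, 28),
    pct_repeat = c(9.8, 6.5, 26.5, 7.7, 72.3),
    pct_nonrepeat = c(90.2, 93.5, 73.5, 92.3, 27.7),
    total_tss = c(2217276, 2258412, 963766, 360543, 101),
    density_repeat = c(0.208, 0.117, 0.204, 0.022, NA),
    density_nonrepeat = c(1.105, 1.134, 0.380, 0.179, NA),
    stringsAsFactors = FALSE
  )
}
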