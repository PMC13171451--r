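---
title: "Estimating the transcription-initiation noise floor from randomized genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the transcription-initiation noise floor from randomized genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisefloor)
```

## The problem

Large genomes are pervasively transcribed, yet only a small fraction of
their sequence belongs to characterized functional elements. One way to ask
whether pervasive transcription is more than background noise is to compare
transcription initiation in the native genome with initiation in
*randomized* versions of the same sequence: a reversed genome, or genomes
shuffled so that mono- or dinucleotide composition is preserved at a global
or local scale. If a base-resolution initiation signal (a prediction track
or a cap-analysis assay such as GRO-cap/CAGE) shows far fewer transcription
start sites (TSSs) on randomized sequence than on native sequence, most
native initiation cannot be explained by chance occurrence of
initiation-competent motifs.

`noisefloor` implements the computational machinery of such an analysis:

1. **genome randomization operators** — reversal, exact k-let shuffles, and
   softmask-class-restricted randomization;
2. **signal handling** — bedGraph ingestion, conversion of log10-scale
   prediction tracks to integer pseudo-reads, TSS calling, window stitching;
3. **cluster metrics** — max-gap TSS clustering and the six summary
   statistics used to compare datasets;
4. **distance analyses** — inter-cluster distance histograms on a log axis,
   deterministic mode counting, threshold sweeps;
5. **repeat partitioning** — TSS counts, percentages and per-kb densities in
   repeat vs non-repeat sequence;
6. **a synthetic generator** with exact ground truth, so the entire chain is
   testable without a trained predictor or a reference genome download.

## Sequence randomization

`reverse_sequence()` reverses character order without complementation. This
destroys encoded information while preserving composition (and mapping each
dinucleotide XY to YX).

`shuffle_klet_global()` with `k = 1` is a uniform permutation of the
residues. With `k = 2` it preserves the *exact multiset of overlapping
dinucleotides* using the Euler-path construction on the de Bruijn
multigraph: vertices are residues, edges are the observed dinucleotides; a
random last-edge assignment is rejection-tested for connectivity to the
terminal vertex, remaining out-edges are randomly ordered, and the Eulerian
walk spells the shuffled sequence. The construction fixes the first and
last residues; when the edge graph admits a single arrangement the input is
returned unchanged (it *is* the unique arrangement). Exactness is what
makes the operator testable: a brute-force k-let counter verifies every
output in the test suite.

`shuffle_klet_windowed()` applies the same operator inside sliding windows
(default 100 bp, step 50 bp), left to right, each window acting on the
current — possibly already re-shuffled — content. With a step smaller than
the window, overlapping halves are re-shuffled sequentially; this
"in-place sliding" reading is a design decision, since window-shuffling
tools do not document their overlap semantics precisely. Total
mononucleotide composition is exactly preserved either way.

`randomize_mask_class()` restricts randomization to maximal runs of one
softmask class (lowercase = repeat). Runs are independently reversed or
shuffled and reinserted at their original coordinates; all other bytes are
untouched, so the mask pattern of the output is identical to the input.

Case handling in the whole-sequence shuffles is deliberate: characters
carry their case with them, scrambling the mask along with the sequence.
Downstream repeat analyses therefore use the *original* mask coordinates
from BED, not the case of a shuffled FASTA.

All operators are bitwise-reproducible from a single integer seed. Substream
seeds for records, windows and runs are derived with `derive_seed()`, an
affine map modulo 2^31 − 1; the whole-sequence shuffle runs in window
substream 1, which makes a single-window windowed shuffle bitwise-identical
to the global one.

## From signal to TSSs

Prediction tracks encode read counts as log10(s + 1). `to_pseudo_reads()`
inverts this: x = 10^v − 1, values below one pseudo-read become zero,
values of one or more are rounded half away from zero. Two boundary choices
are fixed here: a transformed value of exactly 1 maps to 1 (continuity with
the exact round trip `to_pseudo_reads(log10(s+1)) == s`), and rounding is
half away from zero rather than banker's, so fixtures are stable.
`call_tss()` then reports every position whose count meets the calling
threshold (default 1).

Strands are processed independently end to end. When a predictor emits
several assay tracks per strand, `aggregate_tracks()` reduces them
elementwise by `max` or `sum`; the reduction is configuration, since no
single convention exists for collapsing multi-assay output.

## Cluster metrics

`cluster_tss()` merges TSSs whose *adjacent* positional difference is at
most `max_gap` (default 25 bp) — single linkage, implemented with
`IRanges::reduce()`. The alternative "any two TSSs within 25 bp"
complete-linkage reading was rejected: it disagrees with the standard
interval-merge semantics of genomic-ranges tooling, and single linkage is
the convention the reference statistics follow. Cluster width is the
inclusive span `end − start + 1` (a singleton has width 1). Inter-cluster
distance is the gap `start(next) − end(previous)`; start-to-start spacing
is a defensible alternative, but "distance to the next cluster" reads most
naturally as separation. Inter-TSS distances are adjacent position
differences pooled within sequence/strand.

`compute_metrics()` reports the six statistics at full precision;
`format_metrics()` rounds for report tables (widths to 1 decimal, TSSs per
cluster to 2, distances to whole bases, all half-up).

`distance_histogram()` bins distances into 100 log10-spaced bins over
[1, 10^8] bp, left-closed right-open (top edge closed). `count_modes()`
smooths the counts with a 5-bin moving average and counts local maxima
whose topographic prominence is at least 5% of the maximum smoothed bin —
a deterministic operationalization of "how many modes does this
distribution have" that needs no kernel bandwidth selection on the raw
distances.

## The synthetic generator

`gen_tss_track()` generates the statistical structure the analysis assumes,
with complete ground truth:

* **inter-cluster gaps** from a three-component lognormal mixture, medians
  50 / 300 / 15,000 bp (sdlog 0.35 / 0.30 / 0.50), weights
  0.25 / 0.25 / 0.50. The three medians mirror the short/medium/long modes
  reported for inter-cluster distances in real initiation data; the weights
  were chosen once so the implied mean gap (~8.6 kb) is of the same order
  as the genome-wide mean inter-cluster distance (~10.8 kb) in the
  reference table. The component *family* is a modeling choice — only peak
  locations, not distribution families, are constrained by observation.
* **TSSs per cluster**: 1 + Poisson(6.8), mean 7.8, echoing the forward
  genome reference value.
* **intra-cluster spacing**: 1 + geometric (mean 3.5 bp), truncated at
  25 bp so a truth cluster is never split by the default merge; total span
  capped at 100 bp, the typical upper scale of initiation clusters.
* **magnitudes**: a per-*cluster* discretized Pareto strength (tail exponent
  1.3, mean ~4.3 pseudo-reads per TSS) shared by all members, with mild
  per-TSS lognormal jitter (sd 0.1). Drawing strength at cluster level is
  the structural assumption that initiation strength is a property of a
  site: raising the calling threshold then removes whole weak clusters
  rather than eroding cluster shape, which reproduces the observed
  robustness of cluster width and TSSs-per-cluster to threshold sweeps. A
  larger jitter (0.25 was tried first) erodes boundary clusters partially
  and destroys that robustness, so 0.1 is part of the model definition.
* Emitted values are log10(count + 1), so the signal chain must invert the
  encoding *exactly*; the truth tables make the comparison exact, and
  `expected_short_gap_fraction()` reports the probability (~0.7% under
  defaults) that a sampled gap is ≤ 25 bp and two truth clusters merge.

`gen_masked_sequence()` draws i.i.d. uniform residues and assigns case by
an alternating-run renewal process with geometric run lengths; the mean
repeat run is 300 bp (the scale of the most abundant human interspersed
repeats) and the stationary lowercase fraction equals the requested repeat
fraction (default 0.403, the repeat content of the complete human
assembly). Over 1 Mb the realized fraction concentrates within about
±0.02 of the target (renewal-process sd ≈ 0.008).

What the generator does *not* emulate: any sequence dependence of the
signal (there is no sequence-to-signal model), chromosome-scale
heterogeneity of initiation density, correlated strand structure, or
repeat-family composition. Tests passing on synthetic tracks therefore
validate the *computational chain* — randomization exactness, encoding
inversion, clustering, counting — not the biological claims one would make
on real data.

## Problem sizes and numerics

The packaged analyses and tests run at reduced scale chosen to exercise
every code path with comfortable statistical power: 2 Mb genomes for the
randomization panel, a 10 Mb track (~1,100 clusters, ~8,500 TSSs) for
distance and partition analyses, and string spaces up to length 10 for
shuffle exactness (exhaustive to length 5, sampled above). Clustering,
calling and conversion are vectorised and run genome-scale if supplied;
the Euler shuffle walks its edge list in R and processes a few megabases
per minute, which is adequate for the windowed variants and for
chromosome-window inputs.

Degenerate inputs are defined, not errors: empty TSS sets give zero-count
metric rows with missing distances; sequences shorter than k are rejected
by the global shuffle but skipped (unchanged) as windows or mask runs; an
empty bedGraph is an all-zero track for the declared sequences; a sequence
too short for a single cluster yields an empty track with empty truth.

## Known limitations

* The dinucleotide shuffle fixes terminal residues (a property of the
  Euler construction, asserted in tests); shuffles that relax this exist
  but are not implemented.
* Mode counting depends on the fixed smoothing bandwidth and prominence
  floor; they are defaults of the operationalization, not estimates.
* No statistical tests compare distance distributions between datasets;
  the package computes descriptive statistics only.
* Coordinate lifting between assemblies is out of scope: masks and TSS
  calls must share a coordinate system, enforced by sequence-name
  matching.
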