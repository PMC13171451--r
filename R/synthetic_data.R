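# Synthetic softmasked genomes and TSS signal tracks with known ground
# truth, so every pipeline stage is testable without a trained predictor or
# a genome download.
#
# The track generator emulates the clustered, heavy-tailed structure of
# base-resolution initiation data: clusters of nearby TSSs (typically up to
# ~100 bp wide) separated by gaps drawn from a three-component lognormal
# mixture with short (~50 bp), medium (~300 bp) and long (~15,000 bp) modes,
# and per-cluster initiation strengths with a Pareto tail. Emitted values are
# log10(count + 1), so the signal chain must invert them exactly.

#' Parameters for the synthetic TSS track generator
#'
#' Defaults describe the study conditions the generator emulates: a trimodal
#' inter-cluster gap distribution with modes near 50 / 300 / 15,000 bp, a
#' mean of ~7.8 TSSs per cluster, cluster widths capped at 100 bp, and
#' heavy-tailed pseudo-read magnitudes with mean ~4.3 reads per TSS.
#' Magnitude is drawn per CLUSTER (one strength shared, with mild per-TSS
#' jitter): initiation strength is a property of a site, which is what makes
#' cluster-shape statistics robust under read-threshold sweeps.
#'
#' @param length Sequence length in bp.
#' @param gap_weights Mixture weights (sum to 1).
#' @param gap_meanlog Lognormal location (natural log) per component,
#'   strictly increasing; defaults `log(c(50, 300, 15000))`.
#' @param gap_sdlog Lognormal scale per component.
#' @param tss_per_cluster_mean Mean TSSs per cluster; counts are
#'   `1 + Poisson(mean - 1)`.
#' @param member_gap_mean Mean of the intra-cluster adjacent-TSS spacing
#'   (1 + geometric, truncated at 25 bp so a truth cluster is never split by
#'   the 25 bp merge).
#' @param width_cap Maximum cluster span in bp.
#' @param magnitude_alpha Pareto tail exponent of the per-cluster strength.
#' @param magnitude_jitter_sd Lognormal sd of the per-TSS jitter around the
#'   cluster strength.
#' @param seed RNG seed; all draws run in substreams of it.
#' @return A list of class `track_model`.
#' @export
track_model <- function(length = 1e7,
                        gap_weights = c(0.25, 0.25, 0.5),
                        gap_meanlog = log(c(50, 300, 15000)),
                        gap_sdlog = c(0.35, 0.30, 0.50),
                        tss_per_cluster_mean = 7.8,
                        member_gap_mean = 3.5,
                        width_cap = 100L,
                        magnitude_alpha = 1.3,
                        magnitude_jitter_sd = 0.1,
                        seed = 1L) {
  stopifnot(length >= 0,
            abs(sum(gap_weights) - 1) < 1e-9,
            length(gap_weights) == length(gap_meanlog),
            length(gap_meanlog) == length(gap_sdlog),
            !is.unsorted(gap_meanlog, strictly = TRUE),
            all(gap_sdlog > 0),
            tss_per_cluster_mean >= 1,
            member_gap_mean >= 1,
            width_cap >= 1,
            magnitude_alpha > 1)
  structure(list(length = length, gap_weights = gap_weights,
                 gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
                 tss_per_cluster_mean = tss_per_cluster_mean,
                 member_gap_mean = member_gap_mean,
                 width_cap = as.integer(width_cap),
                 magnitude_alpha = magnitude_alpha,
                 magnitude_jitter_sd = magnitude_jitter_sd,
                 seed = as.integer(seed)),
            class = "track_model")
}

#' Probability that a sampled inter-cluster gap is at most `max_gap`
#'
#' Gaps this short cause adjacent truth clusters to be merged by the
#' clustering stage; the model reports the probability so tests can account
#' for expected mis-merges exactly.
#'
#' @param model A [track_model()].
#' @param max_gap Merge distance in bases.
#' @return Probability in `[0, 1]`.
#' @export
expected_short_gap_fraction <- function(model, max_gap = 25L) {
  stopifnot(inherits(model, "track_model"))
  # gaps are rounded lognormal draws floored at 1; P(round(X) <= g) ~ P(X <= g + 0.5)
  sum(model$gap_weights *
        plnorm(max_gap + 0.5, model$gap_meanlog, model$gap_sdlog))
}

#' Generate a softmasked random genome sequence
#'
#' Residues are i.i.d. uniform over {A,C,G,T}; case is assigned by an
#' alternating-run renewal process with geometric run lengths whose
#' stationary lowercase fraction equals `repeat_fraction`. The default mean
#' repeat run length of 300 bp is the scale of the most abundant human
#' interspersed repeats.
#'
#' @param length Sequence length in bp.
#' @param repeat_fraction Target lowercase (repeat) fraction.
#' @param mean_run_length Mean length of a lowercase run, bp.
#' @param seed RNG seed.
#' @param name Sequence name.
#' @return Named character vector of length one.
#' @export
gen_masked_sequence <- function(length, repeat_fraction = 0.403,
                                mean_run_length = 300, seed = 1L,
                                name = "synth") {
  stopifnot(length >= 0, repeat_fraction >= 0, repeat_fraction <= 1,
            mean_run_length >= 1)
  if (length == 0) return(stats::setNames("", name))
  codes <- withr::with_seed(derive_seed(seed, 1L), {
    base <- sample(c(65L, 67L, 71L, 84L), length, replace = TRUE)  # A C G T
    if (repeat_fraction > 0 && repeat_fraction < 1) {
      mr <- mean_run_length
      mn <- mr * (1 - repeat_fraction) / repeat_fraction
      lower <- logical(length)
      pos <- 0L
      is_rep <- runif(1) < repeat_fraction
      while (pos < length) {
        m <- if (is_rep) mr else mn
        run <- 1L + rgeom(1L, 1 / m)      # mean 1/p = m
        idx <- (pos + 1L):min(pos + run, length)
        lower[idx] <- is_rep
        pos <- pos + run
        is_rep <- !is_rep
      }
      base[lower] <- base[lower] + 32L
    } else if (repeat_fraction == 1) {
      base <- base + 32L
    }
    base
  })
  stats::setNames(intToUtf8(codes), name)
}

#' Generate a synthetic TSS signal track with ground truth
#'
#' Clusters are placed left to right: each inter-cluster gap is drawn from
#' the lognormal mixture, each cluster is populated with
#' `1 + Poisson(mean - 1)` TSSs at truncated-geometric spacings (span capped
#' at `width_cap`), a per-cluster Pareto strength sets the integer magnitude
#' of every member (with mild lognormal jitter), and the emitted per-base
#' values are `log10(count + 1)`.
#'
#' @param model A [track_model()].
#' @param name,strand Track identifiers.
#' @return A list with `track` (a `signal_track`) and `truth`, a list with
#'   `clusters` (`cluster`, `start`, `end`, `n_tss`, `strength`), `tss`
#'   (`cluster`, `pos`, `count`) and `gaps` (`gap`, `component`; one row per
#'   gap between consecutive recorded clusters).
#' @export
gen_tss_track <- function(model = track_model(), name = "synth",
                          strand = "+") {
  stopifnot(inherits(model, "track_model"))
  L <- model$length
  res <- withr::with_seed(derive_seed(model$seed, 2L), {
    cl_start <- integer(0); cl_end <- integer(0); cl_n <- integer(0)
    cl_strength <- numeric(0)
    tss_cl <- integer(0); tss_pos <- integer(0); tss_cnt <- numeric(0)
    gap_val <- numeric(0); gap_comp <- integer(0)
    cur <- 0
    ci <- 0L
    repeat {
      z <- sample.int(length(model$gap_weights), 1L,
                      prob = model$gap_weights)
      g <- max(1, round(rlnorm(1, model$gap_meanlog[z], model$gap_sdlog[z])))
      start <- cur + g
      k <- 1L + rpois(1L, model$tss_per_cluster_mean - 1)
      # adjacent spacings: 1 + geometric, truncated so no intra-cluster gap
      # exceeds the merge distance and the span stays under the cap
      if (k > 1L) {
        repeat {
          mg <- 1L + pmin(rgeom(k - 1L, 1 / model$member_gap_mean), 24L)
          if (1L + sum(mg) <= model$width_cap) break
        }
        pos <- start + c(0L, cumsum(mg))
      } else {
        pos <- start
      }
      if (pos[k] >= L) break
      strength <- floor(runif(1)^(-1 / model$magnitude_alpha) + 0.5)
      cnt <- pmax(1, floor(strength *
                             exp(rnorm(k, 0, model$magnitude_jitter_sd)) + 0.5))
      ci <- ci + 1L
      cl_start <- c(cl_start, start); cl_end <- c(cl_end, pos[k])
      cl_n <- c(cl_n, k); cl_strength <- c(cl_strength, strength)
      tss_cl <- c(tss_cl, rep(ci, k)); tss_pos <- c(tss_pos, pos)
      tss_cnt <- c(tss_cnt, cnt)
      if (ci > 1L) { gap_val <- c(gap_val, g); gap_comp <- c(gap_comp, z) }
      cur <- pos[k]
    }
    list(cl = data.frame(cluster = seq_len(ci), start = cl_start,
                         end = cl_end, n_tss = cl_n,
                         strength = cl_strength),
         tss = data.frame(cluster = tss_cl, pos = tss_pos, count = tss_cnt),
         gaps = data.frame(gap = gap_val, component = gap_comp))
  })
  values <- numeric(L)
  if (nrow(res$tss) > 0) values[res$tss$pos + 1L] <- log10(res$tss$count + 1)
  list(track = signal_track(name, strand, values),
       truth = list(clusters = res$cl, tss = res$tss, gaps = res$gaps))
}

#' Write the small worked-example fixtures
#'
#' Deterministic (no RNG): a four-TSS BED used throughout the documentation,
#' a toy bedGraph whose pseudo-read conversion reproduces that TSS set, and
#' a toy softmasked FASTA. Running twice produces identical bytes.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
gen_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tss = file.path(out_dir, "worked_tss.bed"),
    bedgraph = file.path(out_dir, "worked_signal.bedgraph"),
    fasta = file.path(out_dir, "toy_masked.fasta")
  )
  # the worked TSS set {100, 110, 140, 200} with counts {2, 1, 1, 5}
  pos <- c(100L, 110L, 140L, 200L)
  cnt <- c(2L, 1L, 1L, 5L)
  writeLines(sprintf("s\t%d\t%d\t%d", pos, pos + 1L, cnt), paths[["tss"]])
  vals <- sprintf("%.17g", log10(cnt + 1))
  writeLines(sprintf("s\t%d\t%d\t%s", pos, pos + 1L, vals),
             paths[["bedgraph"]])
  writeLines(c(">s", "ACGtttGA"), paths[["fasta"]])
  invisible(paths)
}
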