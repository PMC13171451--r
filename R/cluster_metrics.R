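# Max-gap TSS clustering, cluster summary statistics, inter-cluster distance
# distributions, mode counting, and threshold sweeps.
#
# Clustering is single linkage: consecutive TSSs whose positional difference
# is <= max_gap belong to one cluster (the merge is IRanges::reduce on unit
# ranges). Cluster width is the inclusive span end - start + 1, so a
# singleton has width 1. Inter-cluster distance is the gap start(next) -
# end(previous); distances never cross a sequence or strand boundary.

.group_key <- function(df) paste(df$name, df$strand, sep = "\r")

.empty_clusters <- function() {
  data.frame(name = character(), strand = character(), start = integer(),
             end = integer(), n_tss = integer(), width = integer(),
             stringsAsFactors = FALSE)
}

#' Cluster TSS positions with a maximum-gap merge
#'
#' Consecutive TSSs separated by at most `max_gap` bases are merged into one
#' cluster; cluster start/end are the min/max member positions. Every TSS
#' belongs to exactly one cluster.
#'
#' @param tss Data.frame with columns `name`, `strand`, `pos` (strictly
#'   increasing within each sequence/strand), as from [call_tss()].
#' @param max_gap Maximum merge distance in bases (default 25).
#' @return Data.frame with columns `name`, `strand`, `start`, `end` (0-based,
#'   inclusive), `n_tss`, `width` (`end - start + 1`).
#' @export
cluster_tss <- function(tss, max_gap = 25L) {
  stopifnot(max_gap >= 0)
  if (nrow(tss) == 0) return(.empty_clusters())
  key <- .group_key(tss)
  parts <- split(tss, factor(key, levels = unique(key)))
  out <- lapply(parts, function(g) {
    if (is.unsorted(g$pos, strictly = TRUE)) {
      stop("TSS positions must be strictly increasing within a ",
           "sequence/strand", call. = FALSE)
    }
    ir <- IRanges::IRanges(start = g$pos + 1L, width = 1L)
    # reduce merges ranges separated by a gap < min.gapwidth; unit ranges at
    # positions p1 < p2 have gap p2 - p1 - 1, so min.gapwidth = max_gap
    # merges exactly when p2 - p1 <= max_gap
    red <- IRanges::reduce(ir, min.gapwidth = max_gap)
    data.frame(
      name = rep(g$name[1], length(red)),
      strand = rep(g$strand[1], length(red)),
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red) - 1L,
      n_tss = IRanges::countOverlaps(red, ir),
      width = IRanges::width(red),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}

#' Gaps between adjacent TSS clusters
#'
#' One distance per adjacent cluster pair within each sequence/strand,
#' defined as `start(next) - end(previous)`; pairs never span sequences or
#' strands.
#'
#' @param clusters Data.frame as from [cluster_tss()].
#' @return Numeric vector of distances in bp (possibly empty).
#' @export
inter_cluster_distances <- function(clusters) {
  if (nrow(clusters) == 0) return(numeric())
  key <- .group_key(clusters)
  parts <- split(clusters, factor(key, levels = unique(key)))
  unlist(lapply(parts, function(g) {
    n <- nrow(g)
    if (n < 2) return(numeric())
    g$start[-1] - g$end[-n]
  }), use.names = FALSE)
}

.inter_tss_distances <- function(tss) {
  if (nrow(tss) == 0) return(numeric())
  key <- .group_key(tss)
  parts <- split(tss, factor(key, levels = unique(key)))
  unlist(lapply(parts, function(g) diff(g$pos)), use.names = FALSE)
}

#' Compute the six cluster summary statistics for one dataset/threshold
#'
#' Columns: number of TSSs; number of clusters; mean cluster width (bp); mean
#' TSSs per cluster (`n_tss / n_clusters`); mean inter-TSS distance (adjacent
#' TSS position differences, pooled over sequences/strands); mean
#' inter-cluster distance (gap between adjacent cluster spans, pooled).
#' Distances are reported as `NA` when fewer than two TSSs (or clusters)
#' exist. Full precision is retained; see [format_metrics()] for report
#' rounding.
#'
#' @param tss Data.frame of TSS calls.
#' @param clusters Clusters built from `tss` via [cluster_tss()].
#' @param label Dataset label for the output row.
#' @param threshold Calling threshold used, recorded in the row.
#' @return One-row data.frame (a metrics row).
#' @export
compute_metrics <- function(tss, clusters, label = "", threshold = NA) {
  n_tss <- nrow(tss)
  n_cl <- nrow(clusters)
  if (sum(clusters$n_tss) != n_tss) {
    stop("clusters were not built from this TSS set: member counts do not ",
         "sum to the number of TSSs", call. = FALSE)
  }
  d_tss <- .inter_tss_distances(tss)
  d_cl <- inter_cluster_distances(clusters)
  data.frame(
    dataset = label,
    threshold = threshold,
    n_tss = n_tss,
    n_clusters = n_cl,
    mean_cluster_width = if (n_cl > 0) mean(clusters$width) else NA_real_,
    mean_tss_per_cluster = if (n_cl > 0) n_tss / n_cl else NA_real_,
    mean_inter_tss_distance = if (length(d_tss) > 0) mean(d_tss) else NA_real_,
    mean_inter_cluster_distance = if (length(d_cl) > 0) mean(d_cl) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Round a metrics table to report precision
#'
#' Widths to 1 decimal place, TSSs per cluster to 2, distances to whole
#' bases; rounding is half away from zero so printed tables are stable.
#'
#' @param rows Data.frame of metrics rows from [compute_metrics()].
#' @return The table with rounded summary columns.
#' @export
format_metrics <- function(rows) {
  rows$mean_cluster_width <- round_half_up(rows$mean_cluster_width, 1)
  rows$mean_tss_per_cluster <- round_half_up(rows$mean_tss_per_cluster, 2)
  rows$mean_inter_tss_distance <- round_half_up(rows$mean_inter_tss_distance, 0)
  rows$mean_inter_cluster_distance <-
    round_half_up(rows$mean_inter_cluster_distance, 0)
  rows
}

#' Histogram of inter-cluster distances on a log axis
#'
#' Counts over log10-spaced bins, left-closed right-open (the top edge is
#' closed so the range is covered exactly). Counts always sum to the number
#' of distances.
#'
#' @param distances Numeric vector of distances, all >= 1 and within `range`.
#' @param n_bins Number of bins.
#' @param range Two-element numeric range in bp.
#' @return A list of class `distance_histogram` with fields `edges`
#'   (length `n_bins + 1`), `counts`, `total`.
#' @export
distance_histogram <- function(distances, n_bins = 100L, range = c(1, 1e8)) {
  stopifnot(n_bins >= 1, length(range) == 2, range[1] > 0, range[2] > range[1])
  if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
  if (length(distances) > 0 &&
      (min(distances) < range[1] || max(distances) > range[2])) {
    stop("distance outside histogram range", call. = FALSE)
  }
  edges <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_bins + 1)
  bin <- findInterval(distances, edges, rightmost.closed = TRUE)
  structure(list(edges = edges, counts = tabulate(bin, n_bins),
                 total = length(distances)),
            class = "distance_histogram")
}

.smooth_counts <- function(counts, bandwidth) {
  n <- length(counts)
  h <- (bandwidth - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(counts[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Locate peaks of a smoothed distance histogram
#'
#' The histogram is smoothed with a fixed-width moving average in log space,
#' then local maxima (plateau-aware) are ranked by topographic prominence:
#' the drop from the peak to the highest saddle separating it from higher
#' terrain. Peaks with prominence below `min_prominence_frac` of the maximum
#' smoothed count are discarded. Deterministic.
#'
#' @param hist A `distance_histogram`.
#' @param smooth_bandwidth Moving-average width in bins (forced odd).
#' @param min_prominence_frac Prominence floor as a fraction of the maximum
#'   smoothed bin.
#' @return Data.frame with columns `bin`, `center` (geometric bin center,
#'   bp), `height`, `prominence`, one row per retained peak.
#' @export
find_histogram_peaks <- function(hist, smooth_bandwidth = 5L,
                                 min_prominence_frac = 0.05) {
  stopifnot(inherits(hist, "distance_histogram"))
  empty <- data.frame(bin = integer(), center = numeric(),
                      height = numeric(), prominence = numeric())
  if (hist$total == 0) return(empty)
  bw <- max(1L, smooth_bandwidth)
  if (bw %% 2L == 0L) bw <- bw + 1L
  s <- .smooth_counts(hist$counts, bw)
  runs <- rle(s)
  re <- cumsum(runs$lengths)
  rs <- re - runs$lengths + 1L
  nr <- length(runs$values)
  peaks <- integer(0)
  for (j in seq_len(nr)) {
    v <- runs$values[j]
    if (v <= 0) next
    left_ok <- j == 1L || runs$values[j - 1L] < v
    right_ok <- j == nr || runs$values[j + 1L] < v
    if (left_ok && right_ok) {
      peaks <- c(peaks, rs[j] + (re[j] - rs[j]) %/% 2L)  # plateau midpoint
    }
  }
  if (length(peaks) == 0) return(empty)
  n <- length(s)
  prom <- vapply(peaks, function(b) {
    h <- s[b]
    key <- -Inf
    sides <- list(if (b > 1L) (b - 1L):1L else integer(0),
                  if (b < n) (b + 1L):n else integer(0))
    for (side in sides) {
      if (length(side) == 0) next
      run_min <- Inf
      found_higher <- FALSE
      for (i in side) {
        if (s[i] > h) { found_higher <- TRUE; break }
        run_min <- min(run_min, s[i])
      }
      if (found_higher) key <- max(key, run_min)
    }
    if (!is.finite(key)) key <- 0  # global maximum: prominence is its height
    h - key
  }, numeric(1))
  keep <- prom >= min_prominence_frac * max(s)
  centers <- sqrt(hist$edges[peaks] * hist$edges[peaks + 1L])
  out <- data.frame(bin = peaks[keep], center = centers[keep],
                    height = s[peaks][keep], prominence = prom[keep])
  out[order(out$bin), , drop = FALSE]
}

#' Count modes of an inter-cluster distance distribution
#'
#' Operationalizes modality of the (log-scale) distance distribution as the
#' number of prominent peaks of the smoothed histogram; see
#' [find_histogram_peaks()].
#'
#' @inheritParams find_histogram_peaks
#' @return Integer number of modes (0 for an empty histogram).
#' @export
count_modes <- function(hist, smooth_bandwidth = 5L,
                        min_prominence_frac = 0.05) {
  nrow(find_histogram_peaks(hist, smooth_bandwidth, min_prominence_frac))
}

#' Recompute cluster metrics across a ladder of calling thresholds
#'
#' For each threshold the pipeline `call_tss` -> `cluster_tss` ->
#' `compute_metrics` is rerun from the same pseudo-read track(s). The number
#' of called TSSs is non-increasing in the threshold.
#'
#' @param tracks A `pseudo_read_track` or a list of them (e.g. both strands).
#' @param thresholds Ascending integer thresholds, all >= 1.
#' @param max_gap Cluster merge distance in bases.
#' @param label Dataset label for the rows.
#' @return Data.frame with one metrics row per threshold.
#' @export
threshold_sweep <- function(tracks, thresholds, max_gap = 25L, label = "") {
  if (inherits(tracks, "pseudo_read_track")) tracks <- list(tracks)
  stopifnot(all(thresholds >= 1), !is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    tss <- do.call(rbind, lapply(tracks, call_tss, threshold = th))
    cl <- cluster_tss(tss, max_gap)
    compute_metrics(tss, cl, label = label, threshold = th)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
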