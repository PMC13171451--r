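# Per-base transcription-initiation signal: bedGraph ingestion, pseudo-read
# conversion, TSS calling, and stitching of window-level tracks back into
# chromosome coordinates.
#
# Signal values are on the log10(s + 1) scale (s = read count), the encoding
# emitted by base-resolution initiation predictors; the pseudo-read transform
# inverts it exactly for integer s.

#' Construct a per-base signal track
#'
#' @param name Sequence identifier.
#' @param strand `"+"` or `"-"`; strands are processed independently
#'   end-to-end.
#' @param values Non-negative numeric vector, one value per base, on the
#'   log10(s+1) scale.
#' @return A list of class `signal_track`.
#' @export
signal_track <- function(name, strand = "+", values = numeric()) {
  stopifnot(is.character(name), length(name) == 1L,
            strand %in% c("+", "-"), is.numeric(values))
  if (any(values < 0)) stop("signal values must be >= 0", call. = FALSE)
  structure(list(name = name, strand = strand, values = as.numeric(values)),
            class = "signal_track")
}

#' Read a bedGraph file into per-base signal tracks
#'
#' Records are 0-based half-open and must be sorted and non-overlapping
#' within each sequence. Intervals are expanded to per-base values; uncovered
#' positions are 0.
#'
#' @param path Path to a bedGraph file.
#' @param seq_lengths Optional named vector of sequence lengths; sequences in
#'   `names(seq_lengths)` with no records yield all-zero tracks. When absent,
#'   each track's length is the largest end coordinate seen for it.
#' @param strand Strand label to attach to every track (bedGraph itself is
#'   unstranded; stranded assays ship one file per strand).
#' @return A list of `signal_track` objects.
#' @export
read_bedgraph <- function(path, seq_lengths = NULL, strand = "+") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  empty <- file.size(path) == 0 ||
    all(!nzchar(trimws(readLines(path, warn = FALSE))))
  if (empty) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bedGraph"),
      error = function(e) {
        stop("malformed bedGraph in '", path, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  if (length(gr) > 0 && any(gr$score < 0)) {
    stop("negative signal value in '", path, "'", call. = FALSE)
  }
  nms <- as.character(GenomicRanges::seqnames(gr))
  want <- if (!is.null(seq_lengths)) names(seq_lengths) else unique(nms)
  lapply(want, function(nm) {
    sel <- which(nms == nm)
    starts <- GenomicRanges::start(gr)[sel]   # 1-based inclusive
    ends <- GenomicRanges::end(gr)[sel]
    if (length(sel) > 1) {
      if (is.unsorted(starts, strictly = TRUE)) {
        stop("bedGraph records for '", nm, "' are not sorted", call. = FALSE)
      }
      if (any(starts[-1] <= ends[-length(ends)])) {
        stop("overlapping bedGraph records for '", nm, "'", call. = FALSE)
      }
    }
    len <- if (!is.null(seq_lengths)) seq_lengths[[nm]] else max(ends, 0)
    if (length(sel) > 0 && max(ends) > len) {
      stop("bedGraph record beyond declared length of '", nm, "'",
           call. = FALSE)
    }
    v <- numeric(len)
    for (j in seq_along(sel)) {
      v[starts[j]:ends[j]] <- gr$score[sel[j]]
    }
    signal_track(nm, strand, v)
  })
}

#' Write a signal track as bedGraph
#'
#' Zero runs are omitted, non-zero runs are merged into intervals; 0-based
#' half-open. Round-trips through [read_bedgraph()].
#'
#' @param track A `signal_track` (or pseudo-read track; the counts are
#'   written as-is).
#' @param path Output path.
#' @param append Append to an existing file (for multi-sequence output).
#' @export
write_bedgraph <- function(track, path, append = FALSE) {
  v <- if (inherits(track, "pseudo_read_track")) track$counts else track$values
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$name, starts[keep], ends[keep],
                   format(runs$values[keep], scientific = FALSE, trim = TRUE))
  if (!append && length(lines) == 0) file.create(path)
  if (length(lines) > 0) {
    cat(lines, file = path, sep = "\n", append = append)
    cat("\n", file = path, append = TRUE)
  }
  invisible(path)
}

#' Convert a log10(s+1) signal track to integer pseudo-read counts
#'
#' Per base, `x = 10^v - 1`; values below one pseudo-read are set to zero,
#' values of one or more are rounded half away from zero to the nearest
#' integer. This inverts the predictor's encoding exactly: for integer
#' `s >= 0`, `to_pseudo_reads(log10(s+1)) == s`.
#'
#' @param track A `signal_track`.
#' @return A list of class `pseudo_read_track` with fields `name`, `strand`,
#'   `counts`.
#' @export
to_pseudo_reads <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  x <- 10^track$values - 1
  counts <- floor(x + 0.5)
  counts[x < 1] <- 0
  structure(list(name = track$name, strand = track$strand, counts = counts),
            class = "pseudo_read_track")
}

#' Call TSS positions from a pseudo-read track
#'
#' A position is a transcription start site when its count meets the calling
#' threshold.
#'
#' @param track A `pseudo_read_track` (or any list with `name`, `strand`,
#'   `counts`).
#' @param threshold Minimum count (>= 1) required to call a TSS.
#' @return A data.frame with columns `name`, `strand`, `pos` (0-based,
#'   strictly increasing), `count`.
#' @export
call_tss <- function(track, threshold = 1L) {
  stopifnot(threshold >= 1)
  hit <- which(track$counts >= threshold)
  data.frame(
    name = rep(track$name, length(hit)),
    strand = rep(track$strand, length(hit)),
    pos = hit - 1L,
    count = track$counts[hit],
    stringsAsFactors = FALSE
  )
}

#' Stitch window-level tracks into one sequence-level track
#'
#' Values of each window track are placed at `offset + local position`;
#' gaps between windows are zero-filled. Windows must not overlap.
#'
#' @param window_tracks A list, each element a list with fields `offset`
#'   (0-based start of the window in the source sequence) and `values`.
#' @param total_length Optional total length; defaults to the largest
#'   `offset + length(values)`.
#' @param name,strand Identifiers for the stitched track.
#' @return A `signal_track` spanning the full sequence.
#' @export
stitch_windows <- function(window_tracks, total_length = NULL,
                           name = "stitched", strand = "+") {
  offs <- vapply(window_tracks, function(w) w$offset, numeric(1))
  lens <- vapply(window_tracks, function(w) length(w$values), numeric(1))
  o <- order(offs)
  if (any(offs[o][-1] < (offs[o] + lens[o])[-length(o)])) {
    stop("overlapping windows", call. = FALSE)
  }
  L <- if (is.null(total_length)) max(offs + lens, 0) else total_length
  v <- numeric(L)
  for (w in window_tracks) {
    if (length(w$values) == 0) next
    v[(w$offset + 1):(w$offset + length(w$values))] <- w$values
  }
  signal_track(name, strand, v)
}

#' Aggregate several tracks for the same sequence/strand
#'
#' Base-resolution predictors can emit one track per assay; when more than
#' one is supplied they are reduced elementwise before TSS calling. The
#' reduction is configuration, not a modelling claim.
#'
#' @param tracks List of `signal_track` objects of equal length, same name
#'   and strand.
#' @param method `"max"` or `"sum"`.
#' @return A single `signal_track`.
#' @export
aggregate_tracks <- function(tracks, method = c("max", "sum")) {
  method <- match.arg(method)
  stopifnot(length(tracks) >= 1)
  lens <- vapply(tracks, function(t) length(t$values), numeric(1))
  if (length(unique(lens)) != 1) stop("track lengths differ", call. = FALSE)
  vals <- lapply(tracks, `[[`, "values")
  v <- if (method == "max") Reduce(pmax, vals) else Reduce(`+`, vals)
  signal_track(tracks[[1]]$name, tracks[[1]]$strand, v)
}
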