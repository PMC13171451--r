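# Case-preserving genome IO and softmask interval extraction.
#
# A "genome" throughout the package is a named character vector of residue
# strings over {A,C,G,T,N,a,c,g,t,n}. Lowercase carries the repeat softmask,
# exactly as in softmasked reference assemblies, so case must survive every
# read/write round trip byte-for-byte. All coordinates are 0-based half-open,
# matching BED/bedGraph.

VALID_ALPHABET_RE <- "[^ACGTNacgtn]"

.validate_residues <- function(seqs, context = "sequence") {
  bad <- grepl(VALID_ALPHABET_RE, seqs)
  if (any(bad)) {
    nm <- names(seqs)[bad][1]
    ch <- regmatches(seqs[bad][1], regexpr(VALID_ALPHABET_RE, seqs[bad][1]))
    stop("illegal character '", ch, "' in ", context, " '", nm,
         "': alphabet is {A,C,G,T,N} upper or lower case", call. = FALSE)
  }
  invisible(seqs)
}

#' Read a softmasked FASTA file, preserving case
#'
#' Residue case is significant (lowercase marks repeats), so sequences are
#' read as raw strings rather than through a case-normalising DNA container.
#' Multi-line records are concatenated; record order is preserved; sequence
#' names are the header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl(VALID_ALPHABET_RE, seqs)
  if (any(bad)) {
    # locate the offending line so the error is actionable
    lines <- readLines(path, warn = FALSE)
    hit <- which(!startsWith(lines, ">") & grepl(VALID_ALPHABET_RE, lines))[1]
    stop("illegal character at line ", hit, " of '", path,
         "': alphabet is {A,C,G,T,N} upper or lower case", call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' Round-trips byte-identically through [read_fasta()] for a matching
#' `line_width`.
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param line_width Residues per line.
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  stopifnot(length(seqs) == 0 || !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = line_width)
  invisible(path)
}

#' Tile sequences into fixed-width analysis windows
#'
#' Splits each sequence into windows starting at offsets `0, step, 2*step,
#' ...`. The terminal window may be shorter than `window`; it is kept by
#' default and flagged in the `partial` column (downstream stages here have no
#' fixed-length requirement, so discarding data is opt-in).
#'
#' @param seqs Named character vector of residue strings.
#' @param window Window width in bases.
#' @param step Step between window starts in bases; `step == window` gives a
#'   non-overlapping tiling whose concatenation reproduces the input.
#' @param keep_partial Keep terminal windows shorter than `window`?
#' @return A data.frame with columns `source_name`, `offset` (0-based),
#'   `residues`, `partial`.
#' @export
tile_sequence <- function(seqs, window = 100000L, step = window,
                          keep_partial = TRUE) {
  stopifnot(window >= 1, step >= 1)
  out <- lapply(names(seqs), function(nm) {
    len <- nchar(seqs[[nm]])
    offsets <- seq.int(0L, len - 1L, by = step)
    widths <- pmin(window, len - offsets)
    if (!keep_partial) {
      keep <- widths == window
      offsets <- offsets[keep]
      widths <- widths[keep]
    }
    if (length(offsets) == 0) return(NULL)
    data.frame(
      source_name = nm,
      offset = offsets,
      residues = substring(seqs[[nm]], offsets + 1L, offsets + widths),
      partial = widths < window,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Extract repeat/non-repeat intervals from residue case
#'
#' Maximal runs of lowercase residues become `repeat` intervals, maximal runs
#' of uppercase become `non_repeat`; together they tile each sequence exactly.
#' `N`/`n` follow their case like any other residue.
#'
#' @param seqs Named character vector of residue strings.
#' @return A data.frame with columns `name`, `start`, `end` (0-based
#'   half-open), `class` (`"repeat"` or `"non_repeat"`).
#' @export
case_mask_intervals <- function(seqs) {
  .validate_residues(seqs)
  out <- lapply(names(seqs), function(nm) {
    r <- charToRaw(seqs[[nm]])
    if (length(r) == 0) return(NULL)
    lower <- r >= as.raw(97)  # ASCII 'a'; alphabet is validated above
    runs <- rle(as.vector(lower))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    data.frame(
      name = nm,
      start = starts,
      end = ends,
      class = ifelse(runs$values, "repeat", "non_repeat"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write mask intervals as BED4
#'
#' 0-based half-open, tab-separated, interval class in column 4.
#'
#' @param intervals Data.frame as returned by [case_mask_intervals()].
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    intervals$name,
    format(intervals$start, scientific = FALSE, trim = TRUE),
    format(intervals$end, scientific = FALSE, trim = TRUE),
    intervals$class
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 mask file
#'
#' @param path Path to a BED4 file written by [write_bed()] (or equivalent).
#' @return Data.frame with columns `name`, `start`, `end`, `class`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(data.frame(name = character(), start = integer(),
                      end = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("name", "start", "end", "class"),
                   colClasses = c("character", "integer", "integer",
                                  "character"))
  df
}
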