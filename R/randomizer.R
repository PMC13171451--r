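# Genome randomization operators: reversal, exact k-let shuffles (global and
# sliding-window), and softmask-class-restricted randomization.
#
# The dinucleotide (k = 2) shuffle is the Euler-path construction on the de
# Bruijn multigraph (Altschul & Erickson style): the multiset of overlapping
# k-lets is preserved EXACTLY, and the first and last (k-1)-mers are fixed by
# construction. Characters carry their case with them, so shuffling a
# softmasked sequence scrambles the mask along with the residues; repeat
# analyses on randomized genomes use the original mask coordinates via BED.

#' Specification for a k-let shuffle
#'
#' @param k k-let order: 1 preserves mononucleotide counts, 2 preserves the
#'   exact multiset of overlapping dinucleotides. Higher k is supported via
#'   (k-1)-mer vertices but is outside the validated range.
#' @param scope `"global"` (whole sequence) or `"windowed"` (sliding windows
#'   shuffled in place, left to right).
#' @param window Window width in bases (windowed scope).
#' @param step Step between window starts in bases (windowed scope); steps
#'   smaller than `window` re-shuffle overlapping content sequentially.
#' @param seed Top-level RNG seed; per-record and per-window substreams are
#'   derived with [derive_seed()].
#' @return A list of class `shuffle_spec`.
#' @export
shuffle_spec <- function(k = 2L, scope = c("global", "windowed"),
                         window = 100L, step = 50L, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(k >= 1, step >= 1)
  if (scope == "windowed" && window < k) {
    stop("window must be >= k", call. = FALSE)
  }
  structure(list(k = as.integer(k), scope = scope,
                 window = as.integer(window), step = as.integer(step),
                 seed = as.integer(seed)),
            class = "shuffle_spec")
}

#' Reverse sequences (no complementation)
#'
#' Character order is reversed; each residue keeps its case. Applying twice is
#' the identity.
#'
#' @param seqs Named character vector of residue strings.
#' @return Named character vector, reversed.
#' @export
reverse_sequence <- function(seqs) {
  out <- vapply(seqs, function(s) rawToChar(rev(charToRaw(s))), character(1))
  names(out) <- names(seqs)
  out
}

# -- internal k-let machinery (operates on integer code vectors; the caller
#    owns the RNG state) --------------------------------------------------

.sample_one <- function(x) x[[sample.int(length(x), 1L)]]

.shuffle_codes_k1 <- function(codes) codes[sample.int(length(codes))]

# Exact k-let shuffle via a random Eulerian path. Vertices are (k-1)-mers,
# edges are the n-k+1 overlapping k-lets. A uniformly sampled last-edge
# assignment is rejection-tested for connectivity to the final vertex, then
# remaining out-edges are randomly ordered and the path is walked.
.shuffle_codes_euler <- function(codes, k) {
  n <- length(codes)
  if (n <= k) return(codes)
  km1 <- k - 1L
  nv <- n - km1 + 1L                     # vertices along the walk
  if (km1 == 1L) {
    keys <- codes
  } else {
    keys <- vapply(seq_len(nv), function(i) {
      paste(codes[i:(i + km1 - 1L)], collapse = ",")
    }, character(1))
  }
  uk <- unique(keys)
  vs <- match(keys, uk)                  # walk as vertex ids 1..V
  V <- length(uk)
  ne <- nv - 1L
  if (ne < 2L) return(codes)
  from <- vs[seq_len(ne)]
  to <- vs[-1L]
  f <- vs[nv]
  out_by_v <- split(to, factor(from, levels = seq_len(V)))
  # last symbol appended when an edge enters each vertex
  last_sym <- codes[match(seq_len(V), vs) + km1 - 1L]

  choosers <- setdiff(which(lengths(out_by_v) > 0L), f)
  last_t <- rep(NA_integer_, V)
  if (length(choosers) > 0L) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      for (v in choosers) last_t[v] <- .sample_one(out_by_v[[v]])
      # every chooser must reach f along chosen last edges (no cycles)
      state <- integer(V)                # 0 unknown, 1 reaches f
      state[f] <- 1L
      valid <- TRUE
      for (v in choosers) {
        path <- integer(0)
        cur <- v
        while (state[cur] == 0L) {
          if (cur %in% path) { valid <- FALSE; break }
          path <- c(path, cur)
          cur <- last_t[cur]
          if (is.na(cur)) { valid <- FALSE; break }  # dead end off f
        }
        if (!valid) break
        state[path] <- 1L
      }
      if (valid) { ok <- TRUE; break }
    }
    if (!ok) return(codes)               # unique-arrangement fallback
  }

  # order out-edges: random permutation, designated last edge at the end
  adj <- vector("list", V)
  for (v in seq_len(V)) {
    tv <- out_by_v[[v]]
    if (length(tv) == 0L) next
    if (!is.na(last_t[v])) {
      i <- match(last_t[v], tv)
      rest <- tv[-i]
      adj[[v]] <- c(rest[sample.int(length(rest))], last_t[v])
    } else {
      adj[[v]] <- tv[sample.int(length(tv))]
    }
  }

  ptr <- integer(V)
  walk_sym <- integer(ne)
  cur <- vs[1L]
  for (i in seq_len(ne)) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- adj[[cur]][ptr[cur]]
    walk_sym[i] <- last_sym[nxt]
    cur <- nxt
  }
  c(codes[seq_len(km1)], walk_sym)
}

.shuffle_codes <- function(codes, k) {
  if (k == 1L) .shuffle_codes_k1(codes) else .shuffle_codes_euler(codes, k)
}

#' Global exact k-let shuffle
#'
#' For `k = 1` a uniform permutation of the residues (mononucleotide counts
#' exactly preserved); for `k = 2` a random Eulerian path on the dinucleotide
#' de Bruijn multigraph (overlapping dinucleotide multiset exactly preserved;
#' first and last residues fixed). When the k-let graph admits only one
#' arrangement the input is returned unchanged. Deterministic for a fixed
#' `spec$seed`; record `i` of a multi-sequence input uses substream
#' `derive_seed(seed, i)`, and the whole-sequence shuffle itself runs in
#' window substream 1 (so a single-window [shuffle_klet_windowed()] call is
#' bitwise-identical to the global shuffle).
#'
#' @param seqs Named character vector of residue strings.
#' @param spec A [shuffle_spec()].
#' @return Named character vector of shuffled sequences.
#' @export
shuffle_klet_global <- function(seqs, spec = shuffle_spec()) {
  stopifnot(inherits(spec, "shuffle_spec"))
  out <- vapply(seq_along(seqs), function(i) {
    codes <- utf8ToInt(seqs[[i]])
    if (length(codes) < spec$k) {
      stop("sequence shorter than k", call. = FALSE)
    }
    rec_seed <- derive_seed(spec$seed, i)
    withr::with_seed(derive_seed(rec_seed, 1L), {
      intToUtf8(.shuffle_codes(codes, spec$k))
    })
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Sliding-window exact k-let shuffle
#'
#' Windows of `spec$window` bases at offsets `0, step, 2*step, ...` (terminal
#' window truncated) are k-let-shuffled in place, left to right, each shuffle
#' acting on the current — possibly already re-shuffled — content. Total
#' mononucleotide composition is exactly preserved. Window `j` of record `i`
#' uses substream `derive_seed(derive_seed(seed, i), j)`.
#'
#' @inheritParams shuffle_klet_global
#' @return Named character vector of shuffled sequences.
#' @export
shuffle_klet_windowed <- function(seqs, spec = shuffle_spec(scope = "windowed")) {
  stopifnot(inherits(spec, "shuffle_spec"))
  out <- vapply(seq_along(seqs), function(i) {
    codes <- utf8ToInt(seqs[[i]])
    len <- length(codes)
    if (len == 0L) return("")
    rec_seed <- derive_seed(spec$seed, i)
    offsets <- seq.int(0L, len - 1L, by = spec$step)
    for (j in seq_along(offsets)) {
      idx <- (offsets[j] + 1L):min(offsets[j] + spec$window, len)
      if (length(idx) < spec$k) next
      withr::with_seed(derive_seed(rec_seed, j), {
        codes[idx] <- .shuffle_codes(codes[idx], spec$k)
      })
    }
    intToUtf8(codes)
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Randomize only the repeat (or only the non-repeat) runs of a genome
#'
#' Every maximal run of the target case class (lowercase = repeat) is
#' independently reversed or k-let-shuffled and reinserted at its original
#' coordinates; every other position is byte-identical. The softmask pattern
#' of the output equals that of the input, because each run is uniform in
#' case. Run `r` of record `i` uses substream
#' `derive_seed(derive_seed(seed, i), r)`.
#'
#' @param seqs Named character vector of residue strings.
#' @param target `"repeat"` (lowercase runs) or `"non_repeat"` (uppercase).
#' @param method `"reverse"` or `"shuffle"`. The shuffle applied per run is
#'   the global k-let shuffle of `spec` (default mononucleotide).
#' @param spec A [shuffle_spec()]; only `k` and `seed` are used.
#' @return Named character vector with the target runs randomized in place.
#' @export
randomize_mask_class <- function(seqs,
                                 target = c("repeat", "non_repeat"),
                                 method = c("reverse", "shuffle"),
                                 spec = shuffle_spec(k = 1L)) {
  target <- match.arg(target)
  method <- match.arg(method)
  stopifnot(inherits(spec, "shuffle_spec"))
  .validate_residues(seqs)
  want_lower <- target == "repeat"
  out <- vapply(seq_along(seqs), function(i) {
    r <- charToRaw(seqs[[i]])
    if (length(r) == 0L) return("")
    lower <- as.vector(r >= as.raw(97))
    runs <- rle(lower)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    rec_seed <- derive_seed(spec$seed, i)
    hits <- which(runs$values == want_lower)
    for (ri in seq_along(hits)) {
      j <- hits[ri]
      idx <- starts[j]:ends[j]
      if (method == "reverse") {
        r[idx] <- r[rev(idx)]
      } else {
        if (length(idx) < spec$k) next
        codes <- as.integer(r[idx])
        withr::with_seed(derive_seed(rec_seed, ri), {
          codes <- .shuffle_codes(codes, spec$k)
        })
        r[idx] <- as.raw(codes)
      }
    }
    rawToChar(r)
  }, character(1))
  names(out) <- names(seqs)
  out
}
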