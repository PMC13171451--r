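# Independent oracles and small generators used across the suite. These stay
# deliberately naive (brute force, enumeration) so they never share code with
# the implementation they check.

# multiset of overlapping k-lets as a sorted character vector
klet_multiset <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  sort(substring(s, 1:(n - k + 1), k:n))
}

# per-character counts as a named table-like vector
char_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  table(factor(v, levels = sort(unique(v))))
}

# O(n^2) transitive-closure max-gap clustering: merge i,j directly when
# |pos_i - pos_j| <= max_gap, then take connected components (union-find).
brute_cluster <- function(pos, max_gap) {
  n <- length(pos)
  if (n == 0) {
    return(data.frame(start = integer(), end = integer(), n = integer()))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(pos[i] - pos[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(pos, roots)
  df <- data.frame(
    start = vapply(comps, min, numeric(1)),
    end = vapply(comps, max, numeric(1)),
    n = lengths(comps)
  )
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# every permutation of the characters of s that preserves the overlapping
# dinucleotide multiset and the first character (enumeration oracle)
enumerate_dinuc_arrangements <- function(s) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (p in perms(x[-i])) out <- c(out, list(c(x[i], p)))
    }
    out
  }
  target <- klet_multiset(s, 2)
  cand <- unique(vapply(perms(v), paste, character(1), collapse = ""))
  cand[vapply(cand, function(x) {
    substring(x, 1, 1) == v[1] && identical(klet_multiset(x, 2), target)
  }, logical(1))]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_mixed_case <- function(n) {
  paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t"), n, replace = TRUE),
        collapse = "")
}

all_strings <- function(len, alphabet = c("A", "C", "G", "T")) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}

worked_tss_set <- function() {
  data.frame(name = "s", strand = "+", pos = c(100L, 110L, 140L, 200L),
             count = c(2L, 1L, 1L, 5L), stringsAsFactors = FALSE)
}
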