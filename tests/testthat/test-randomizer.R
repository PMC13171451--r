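test_that("reversal reverses characters, keeps case, and is an involution", {
  expect_identical(reverse_sequence(c(a = "ACGTa")), c(a = "aTGCA"))
  expect_identical(reverse_sequence(c(p = "ACGCA")), c(p = "ACGCA"))
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- c(x = random_mixed_case(sample(1:60, 1)))
      expect_identical(reverse_sequence(reverse_sequence(s)), s)
    }
  })
})

test_that("reversal preserves mononucleotide counts and reverses dinucleotides", {
  withr::with_seed(5, {
    for (i in 1:10) {
      s <- random_dna(sample(2:40, 1))
      r <- reverse_sequence(c(x = s))[[1]]
      expect_identical(char_counts(r), char_counts(s))
      rev_dn <- vapply(klet_multiset(s, 2), function(d) {
        paste0(substring(d, 2, 2), substring(d, 1, 1))
      }, character(1))
      expect_identical(klet_multiset(r, 2), sort(unname(rev_dn)))
    }
  })
})

test_that("dinucleotide shuffle returns the unique arrangement when only one exists", {
  sp <- shuffle_spec(k = 2, seed = 9)
  expect_identical(shuffle_klet_global(c(x = "AAC"), sp), c(x = "AAC"))
  expect_identical(shuffle_klet_global(c(x = "ATATAT"), sp), c(x = "ATATAT"))
  # enumeration confirms these dinucleotide multisets admit a single string
  expect_length(enumerate_dinuc_arrangements("AAC"), 1)
  expect_length(enumerate_dinuc_arrangements("ATATAT"), 1)
})

test_that("k=1 shuffle preserves character counts; homopolymers are fixed points", {
  sp1 <- shuffle_spec(k = 1, seed = 2)
  expect_identical(shuffle_klet_global(c(x = "AAAA"), sp1), c(x = "AAAA"))
  withr::with_seed(13, {
    for (i in 1:20) {
      s <- random_mixed_case(sample(2:50, 1))
      out <- shuffle_klet_global(c(x = s), sp1)[[1]]
      expect_identical(char_counts(out), char_counts(s))
    }
  })
})

test_that("k=2 shuffle preserves the exact overlapping-dinucleotide multiset", {
  # exhaustive over short strings, sampled over longer ones (deeper
  # enumeration runs in the acceptance suite)
  for (len in 2:4) {
    for (s in all_strings(len)) {
      out <- shuffle_klet_global(c(x = s), shuffle_spec(k = 2, seed = 1))[[1]]
      expect_identical(klet_multiset(out, 2), klet_multiset(s, 2))
    }
  }
  withr::with_seed(17, {
    for (i in 1:40) {
      s <- random_dna(sample(5:60, 1))
      seed <- sample.int(1e6, 1)
      out <- shuffle_klet_global(c(x = s), shuffle_spec(k = 2, seed = seed))[[1]]
      expect_identical(klet_multiset(out, 2), klet_multiset(s, 2))
      expect_identical(substring(out, 1, 1), substring(s, 1, 1))
      expect_identical(substring(out, nchar(s)), substring(s, nchar(s)))
    }
  })
})

test_that("dinucleotide shuffle reaches every valid arrangement", {
  s <- "AACAGT"
  valid <- enumerate_dinuc_arrangements(s)
  expect_gt(length(valid), 1)
  seen <- unique(vapply(1:2000, function(seed) {
    shuffle_klet_global(c(x = s), shuffle_spec(k = 2, seed = seed))[[1]]
  }, character(1)))
  expect_setequal(seen, valid)
})

test_that("shuffles are bitwise-reproducible for a fixed seed", {
  s <- c(x = random_dna(200))
  for (sp in list(shuffle_spec(k = 1, seed = 4), shuffle_spec(k = 2, seed = 4),
                  shuffle_spec(k = 2, scope = "windowed", seed = 4))) {
    fn <- if (sp$scope == "global") shuffle_klet_global else shuffle_klet_windowed
    expect_identical(fn(s, sp), fn(s, sp))
  }
  expect_identical(
    randomize_mask_class(c(x = "acgTTAggaccc"), "repeat", "shuffle",
                         shuffle_spec(k = 1, seed = 8)),
    randomize_mask_class(c(x = "acgTTAggaccc"), "repeat", "shuffle",
                         shuffle_spec(k = 1, seed = 8)))
})

test_that("windowed shuffle preserves global composition; one window equals global", {
  withr::with_seed(19, {
    s <- c(x = paste(rep("ACGT", 50), collapse = ""))  # length 200
    for (k in 1:2) {
      sp <- shuffle_spec(k = k, scope = "windowed", window = 100, step = 50,
                         seed = 6)
      out <- shuffle_klet_windowed(s, sp)[[1]]
      expect_identical(char_counts(out), char_counts(s[[1]]))
    }
  })
  # homopolymer is a fixed point under any window layout
  hp <- c(h = strrep("t", 130))
  expect_identical(
    shuffle_klet_windowed(hp, shuffle_spec(k = 2, scope = "windowed",
                                           window = 100, step = 50, seed = 1)),
    hp)
  # a window covering the whole sequence degenerates to the global shuffle
  s2 <- c(y = random_dna(40))
  spw <- shuffle_spec(k = 2, scope = "windowed", window = 100, step = 100,
                      seed = 31)
  spg <- shuffle_spec(k = 2, seed = 31)
  expect_identical(shuffle_klet_windowed(s2, spw),
                   shuffle_klet_global(s2, spg))
})

test_that("mask-restricted reversal matches the hand-worked example", {
  expect_identical(
    randomize_mask_class(c(x = "acgTTAgga"), "repeat", "reverse"),
    c(x = "gcaTTAagg"))
  expect_identical(
    randomize_mask_class(c(x = "ACGTAG"), "repeat", "reverse"),
    c(x = "ACGTAG"))
})

test_that("mask-restricted randomization never touches case pattern or off-target bases", {
  case_of <- function(s) {
    grepl("[a-z]", strsplit(s, "")[[1]])
  }
  withr::with_seed(23, {
    for (i in 1:60) {
      s <- random_mixed_case(sample(2:60, 1))
      target <- sample(c("repeat", "non_repeat"), 1)
      method <- sample(c("reverse", "shuffle"), 1)
      out <- randomize_mask_class(c(x = s), target, method,
                                  shuffle_spec(k = 1, seed = i))[[1]]
      expect_equal(nchar(out), nchar(s))
      expect_identical(case_of(out), case_of(s))
      expect_identical(case_mask_intervals(c(x = out)),
                       case_mask_intervals(c(x = s)))
      # off-target positions byte-identical
      off <- case_of(s) != (target == "repeat")
      sc <- strsplit(s, "")[[1]]; oc <- strsplit(out, "")[[1]]
      expect_identical(oc[off], sc[off])
      # composition preserved within each target run
      m <- case_mask_intervals(c(x = s))
      for (j in which(m$class == target)) {
        idx <- (m$start[j] + 1):m$end[j]
        expect_identical(char_counts(paste(oc[idx], collapse = "")),
                         char_counts(paste(sc[idx], collapse = "")))
      }
    }
  })
})

test_that("non-repeat shuffle keeps lowercase bytes fixed and permutes the run", {
  out <- randomize_mask_class(c(x = "acgTTAgga"), "non_repeat", "shuffle",
                              shuffle_spec(k = 1, seed = 2))[[1]]
  expect_identical(substring(out, 1, 3), "acg")
  expect_identical(substring(out, 7, 9), "gga")
  expect_identical(char_counts(substring(out, 4, 6)), char_counts("TTA"))
})
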