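test_that("bedGraph records expand to per-base values with zero fill", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("s\t2\t4\t0.5", f)
  tr <- read_bedgraph(f, seq_lengths = c(s = 6))
  expect_length(tr, 1)
  expect_equal(tr[[1]]$values, c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(tr[[1]]$name, "s")
})

test_that("empty bedGraph yields all-zero tracks for the expected sequences", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(f)
  tr <- read_bedgraph(f, seq_lengths = c(a = 4, b = 2))
  expect_length(tr, 2)
  expect_equal(tr[[1]]$values, rep(0, 4))
  expect_equal(tr[[2]]$values, rep(0, 2))
})

test_that("bedGraph ingestion rejects overlaps and negative values", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("s\t0\t3\t1", "s\t2\t4\t1"), f)
  expect_error(read_bedgraph(f, seq_lengths = c(s = 6)), "overlap")
  writeLines("s\t0\t2\t-1", f)
  expect_error(read_bedgraph(f, seq_lengths = c(s = 6)), "negative")
})

test_that("bedGraph write/read round trip preserves the track", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  tr <- signal_track("q", "+", c(0, 0.25, 0.25, 0, 1.5, 0))
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, seq_lengths = c(q = 6))
  expect_equal(back[[1]]$values, tr$values)
})

test_that("pseudo-read conversion follows the 10^v - 1 rule with half-up rounding", {
  tr <- signal_track("s", "+", c(0, 1.0, 0.25, log10(3.5)))
  pr <- to_pseudo_reads(tr)
  # 10^0-1 = 0; 10^1-1 = 9; 10^0.25-1 ~ 0.78 -> 0; 3.5-1 = 2.5 -> 3
  expect_equal(pr$counts, c(0, 9, 0, 3))
  # boundary: exactly one pseudo-read maps to 1
  expect_equal(to_pseudo_reads(signal_track("s", "+", log10(2)))$counts, 1)
})

test_that("pseudo-read conversion is monotone and zero exactly below log10(2)", {
  v <- seq(0, 3, by = 0.01)
  cnt <- to_pseudo_reads(signal_track("s", "+", v))$counts
  expect_true(all(diff(cnt) >= 0))
  expect_identical(cnt == 0, v < log10(2))
})

test_that("pseudo-read conversion exactly inverts the log10(s+1) encoding", {
  withr::with_seed(29, {
    s <- c(0:50, sample.int(1e6, 300))
  })
  cnt <- to_pseudo_reads(signal_track("s", "+", log10(s + 1)))$counts
  expect_equal(cnt, s)
})

test_that("TSS calling thresholds counts and is monotone in the threshold", {
  tr <- list(name = "s", strand = "+", counts = c(0, 2, 0, 1))
  expect_equal(call_tss(tr, 1)$pos, c(1, 3))
  expect_equal(call_tss(tr, 2)$pos, 1)
  expect_equal(nrow(call_tss(list(name = "s", strand = "+",
                                  counts = rep(0, 5)), 1)), 0)
  withr::with_seed(31, {
    counts <- sample(0:5, 200, replace = TRUE)
    tr2 <- list(name = "x", strand = "-", counts = counts)
    for (a in 1:4) {
      expect_true(all(call_tss(tr2, a + 1)$pos %in% call_tss(tr2, a)$pos))
    }
  })
})

test_that("stitching places windows at their offsets and zero-fills gaps", {
  w1 <- list(offset = 0, values = c(1, 2))
  w2 <- list(offset = 4, values = c(3, 4))
  st <- stitch_windows(list(w1, w2), total_length = 8)
  expect_equal(st$values, c(1, 2, 0, 0, 3, 4, 0, 0))

  st1 <- stitch_windows(list(list(offset = 0, values = c(5, 6))))
  expect_equal(st1$values, c(5, 6))

  expect_error(stitch_windows(list(list(offset = 0, values = 1:3),
                                   list(offset = 2, values = 1:2))),
               "overlap")
})

test_that("stitch then slice returns the original windows", {
  withr::with_seed(37, {
    offs <- c(0, 30, 75)
    wins <- lapply(offs, function(o) list(offset = o, values = runif(20)))
    st <- stitch_windows(wins, total_length = 120)
    for (w in wins) {
      expect_equal(st$values[(w$offset + 1):(w$offset + 20)], w$values)
    }
  })
})

test_that("track aggregation reduces multi-assay tracks elementwise", {
  a <- signal_track("s", "+", c(0, 1, 2))
  b <- signal_track("s", "+", c(2, 0.5, 2))
  expect_equal(aggregate_tracks(list(a, b), "max")$values, c(2, 1, 2))
  expect_equal(aggregate_tracks(list(a, b), "sum")$values, c(2, 1.5, 4))
  expect_error(aggregate_tracks(list(a, signal_track("s", "+", c(1, 2))),
                                "max"), "lengths differ")
})
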