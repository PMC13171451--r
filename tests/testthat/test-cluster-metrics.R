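test_that("max-gap clustering matches hand-worked merges", {
  cl <- cluster_tss(worked_tss_set(), 25)
  expect_equal(cl$start, c(100, 140, 200))
  expect_equal(cl$end, c(110, 140, 200))
  expect_equal(cl$n_tss, c(2, 1, 1))
  expect_equal(cl$width, c(11, 1, 1))

  single <- data.frame(name = "s", strand = "+", pos = 42L, count = 1L)
  cs <- cluster_tss(single, 25)
  expect_equal(cs$width, 1)

  # chained merges at exactly the gap bound
  chain <- data.frame(name = "s", strand = "+", pos = c(0L, 25L, 50L),
                      count = 1L)
  cc <- cluster_tss(chain, 25)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$width, 51)
  expect_equal(cc$n_tss, 3)
})

test_that("clustering equals the brute-force transitive-closure merge", {
  withr::with_seed(41, {
    for (i in 1:200) {
      n <- sample(1:50, 1)
      pos <- sort(sample(0:9999, n))
      tss <- data.frame(name = "s", strand = "+", pos = pos, count = 1L)
      for (mg in c(0, 1, 25, 100)) {
        got <- cluster_tss(tss, mg)
        want <- brute_cluster(pos, mg)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$n_tss, want$n)
        expect_equal(sum(got$n_tss), n)
      }
    }
  })
})

test_that("clustering never crosses sequence or strand boundaries", {
  tss <- data.frame(name = c("a", "a", "b"), strand = c("+", "-", "+"),
                    pos = c(10L, 12L, 11L), count = 1L)
  cl <- cluster_tss(tss, 25)
  expect_equal(nrow(cl), 3)
  expect_equal(inter_cluster_distances(cl), numeric())
})

test_that("metrics row matches the hand computation for the worked fixture", {
  tss <- worked_tss_set()
  cl <- cluster_tss(tss, 25)
  row <- compute_metrics(tss, cl, label = "fixture", threshold = 1)
  expect_equal(row$n_tss, 4)
  expect_equal(row$n_clusters, 3)
  expect_equal(row$mean_cluster_width, 13 / 3)
  expect_equal(row$mean_tss_per_cluster, 4 / 3)
  expect_equal(row$mean_inter_tss_distance, (10 + 30 + 60) / 3)
  expect_equal(row$mean_inter_cluster_distance, (30 + 60) / 2)

  fmt <- format_metrics(row)
  expect_equal(fmt$mean_cluster_width, 4.3)
  expect_equal(fmt$mean_tss_per_cluster, 1.33)
  expect_equal(fmt$mean_inter_tss_distance, 33)
})

test_that("metrics handle degenerate inputs: empty sets and single clusters", {
  empty <- data.frame(name = character(), strand = character(),
                      pos = integer(), count = integer())
  row <- compute_metrics(empty, cluster_tss(empty, 25), "empty", 1)
  expect_equal(row$n_tss, 0)
  expect_equal(row$n_clusters, 0)
  expect_true(is.na(row$mean_inter_tss_distance))
  expect_true(is.na(row$mean_inter_cluster_distance))

  two <- data.frame(name = "s", strand = "+", pos = c(5L, 10L), count = 1L)
  row2 <- compute_metrics(two, cluster_tss(two, 25), "one-cluster", 1)
  expect_equal(row2$n_clusters, 1)
  expect_true(is.na(row2$mean_inter_cluster_distance))
  expect_equal(row2$mean_inter_tss_distance, 5)
})

test_that("mean TSSs per cluster times cluster count recovers the TSS count", {
  withr::with_seed(43, {
    for (i in 1:30) {
      pos <- sort(sample(0:5000, sample(2:80, 1)))
      tss <- data.frame(name = "s", strand = "+", pos = pos, count = 1L)
      cl <- cluster_tss(tss, 25)
      row <- compute_metrics(tss, cl)
      expect_equal(row$mean_tss_per_cluster * row$n_clusters, row$n_tss)
    }
  })
})

test_that("cluster count is non-increasing in max_gap", {
  withr::with_seed(47, {
    pos <- sort(sample(0:20000, 300))
    tss <- data.frame(name = "s", strand = "+", pos = pos, count = 1L)
    ncl <- vapply(c(0, 1, 5, 25, 100, 1000), function(mg) {
      nrow(cluster_tss(tss, mg))
    }, numeric(1))
    expect_true(all(diff(ncl) <= 0))
  })
})

test_that("inter-cluster distances are gaps between adjacent spans", {
  cl <- cluster_tss(worked_tss_set(), 25)
  expect_equal(inter_cluster_distances(cl), c(30, 60))
  # minimal legal separation after a max-gap merge is max_gap + 1
  tss <- data.frame(name = "s", strand = "+", pos = c(10L, 36L), count = 1L)
  cl2 <- cluster_tss(tss, 25)
  expect_equal(nrow(cl2), 2)
  expect_equal(inter_cluster_distances(cl2), 26)
})

test_that("distance histogram bins on a log scale and conserves counts", {
  h <- distance_histogram(c(10, 10, 1000), n_bins = 4, range = c(1, 10000))
  # left-closed right-open: 10 falls in [10, 100), 1000 in [1000, 10000)
  expect_equal(h$counts, c(0, 2, 0, 1))
  expect_equal(sum(h$counts), h$total)

  he <- distance_histogram(numeric(), n_bins = 4, range = c(1, 10000))
  expect_equal(he$counts, rep(0, 4))

  hs <- distance_histogram(rep(50, 7), n_bins = 10, range = c(1, 1e4))
  expect_equal(sum(hs$counts > 0), 1)

  expect_error(distance_histogram(c(1, 0)), "positive")
  withr::with_seed(53, {
    d <- 10^runif(500, 0, 7.9)
    h2 <- distance_histogram(d)
    expect_equal(sum(h2$counts), 500)
  })
})

test_that("mode counting finds one mode for a unimodal sample, three for the mixture", {
  withr::with_seed(59, {
    uni <- pmax(1, round(rlnorm(2000, log(300), 0.4)))
    expect_equal(count_modes(distance_histogram(uni)), 1)

    comp <- sample.int(3, 3000, replace = TRUE, prob = c(0.3, 0.3, 0.4))
    tri <- pmax(1, round(rlnorm(3000, log(c(50, 300, 15000))[comp],
                                c(0.35, 0.3, 0.5)[comp])))
    h <- distance_histogram(tri)
    expect_equal(count_modes(h), 3)
    pk <- find_histogram_peaks(h)
    expect_equal(nrow(pk), 3)
    ratio <- pk$center / c(50, 300, 15000)
    expect_true(all(ratio > 0.5 & ratio < 2))
  })
  expect_equal(count_modes(distance_histogram(numeric())), 0)
})

test_that("threshold sweep reruns the pipeline per threshold with falling TSS counts", {
  tr <- structure(list(name = "s", strand = "+",
                       counts = c(0, 2, 0, 1, 5)),
                  class = "pseudo_read_track")
  sw <- threshold_sweep(tr, c(1, 2, 5))
  expect_equal(sw$n_tss, c(3, 2, 1))
  expect_true(all(diff(sw$n_tss) <= 0))

  # a one-element ladder reproduces the direct pipeline row
  direct <- compute_metrics(call_tss(tr, 1), cluster_tss(call_tss(tr, 1), 25),
                            label = "", threshold = 1L)
  expect_equal(threshold_sweep(tr, 1L), direct)

  # thresholds above the maximum count give empty rows
  sw0 <- threshold_sweep(tr, c(6, 10))
  expect_equal(sw0$n_tss, c(0, 0))
})
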