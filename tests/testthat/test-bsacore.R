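test_that("site_index is the non-reference read proportion", {
  expect_equal(site_index(10, 10), 0.5)
  expect_equal(site_index(0, 25), 1.0)
  expect_equal(site_index(35, 15), 0.3)  # the filter boundary
  expect_true(is.na(site_index(0, 0)))
  expect_equal(site_index(c(10, 0), c(10, 0)), c(0.5, NA))
  expect_error(site_index(-1, 5), "non-negative")
})

test_that("delta_index subtracts the fertile-pool from the sterile-pool index", {
  # causal-site expectation when the restorer parent is the reference:
  # sterile pool fixed non-reference (1), fertile pool at 1/3
  expect_equal(delta_index(1.0, 1/3), 2/3, tolerance = 1e-4)
  expect_equal(delta_index(0.5, 0.5), 0)
  expect_equal(delta_index(0.0, 1.0), -1.0)
})

test_that("the low-index filter follows the both-pools-below policy", {
  sites <- data.frame(
    chrom = "c", pos = 1:5,
    f_index = c(0.20, 0.20, 0.30, 0.90, NA),
    s_index = c(0.25, 0.90, 0.30, 0.10, 0.80))
  sites$delta <- sites$s_index - sites$f_index
  kept <- filter_low_index(sites)
  # both below -> dropped; one pool >= 0.3 -> retained; boundary (strict <)
  # -> retained; undefined in either pool -> dropped
  expect_identical(kept$pos, c(2L, 3L, 4L))
  expect_identical(attr(kept, "n_discarded"), 2L)
  strict <- filter_low_index(sites, policy = "either")
  expect_identical(strict$pos, 3L)
  expect_error(filter_low_index(sites, threshold = 1.5), "\\[0, 1\\]")
})

test_that("raising the filter threshold never increases retained sites", {
  set.seed(201)
  for (i in 1:20) {
    sites <- random_indexed_sites(200)
    thresholds <- sort(runif(5))
    counts <- vapply(thresholds,
                     function(t) nrow(filter_low_index(sites, t)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
    for (t in thresholds) {
      kept <- filter_low_index(sites, t)
      expect_true(all(kept$pos %in% sites$pos))  # subset, order preserved
      expect_identical(kept$pos, sites$pos[sites$pos %in% kept$pos])
    }
  }
})

test_that("make_windows anchors full windows at 1 with a short-chromosome fallback", {
  w <- make_windows(3e6)
  expect_equal(nrow(w), 21L)
  expect_equal(w$start, seq(1, 2000001, by = 1e5))
  expect_equal(w$end, w$start + 1e6 - 1)
  expect_equal(nrow(make_windows(1e6)), 1L)
  short <- make_windows(5e5)
  expect_equal(nrow(short), 1L)
  expect_equal(c(short$start, short$end), c(1, 5e5))
  expect_error(make_windows(1e6, window = 0), "positive")
  expect_error(make_windows(1e6, step = -1), "positive")
})

test_that("window means are exact averages over the contained sites", {
  sites <- data.frame(
    chrom = "c", pos = c(100, 200),
    variant_class = c("SNP", "InDel"),
    f_index = c(0.4, 0.6), s_index = c(0.9, 1.0))
  sites$delta <- sites$s_index - sites$f_index
  w <- window_scan(sites, c(c = 1000), window = 1000, step = 1000)
  expect_equal(nrow(w), 1L)
  expect_equal(w$mean_f_index, 0.5)
  expect_equal(w$mean_s_index, 0.95)
  expect_equal(w$mean_delta, 0.45)
  expect_equal(w$n_snp_sites, 1L)
  expect_equal(w$n_indel_sites, 1L)
  # an empty window carries NA means
  w2 <- window_scan(sites, c(c = 1000, d = 1000), window = 1000, step = 1000)
  expect_true(is.na(w2$mean_delta[w2$chrom == "d"]))
  expect_equal(w2$n_sites[w2$chrom == "d"], 0L)
  expect_error(
    window_scan(data.frame(chrom = "zz", pos = 1, f_index = 1, s_index = 1,
                           delta = 0),
                c(c = 1000)),
    "zz")
})

test_that("window scan matches a naive per-window recomputation", {
  set.seed(301)
  genome <- c(chrA = 4e6, chrB = 2.5e6)
  sites <- rbind(random_indexed_sites(700, "chrA", 4e6),
                 random_indexed_sites(300, "chrB", 2.5e6))
  w <- window_scan(sites, genome)
  for (i in sample(nrow(w), min(40, nrow(w)))) {
    in_win <- sites$chrom == w$chrom[i] &
      sites$pos >= w$start[i] & sites$pos <= w$end[i]
    expect_equal(w$n_sites[i], sum(in_win))
    if (any(in_win)) {
      expect_equal(w$mean_f_index[i], mean(sites$f_index[in_win]),
                   tolerance = 1e-12)
      expect_equal(w$mean_s_index[i], mean(sites$s_index[in_win]),
                   tolerance = 1e-12)
      expect_equal(w$mean_delta[i], mean(sites$delta[in_win]),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(w$mean_delta[i]))
    }
  }
  # linearity: the mean delta is the difference of the mean indices
  inf <- !is.na(w$mean_delta)
  expect_equal(w$mean_delta[inf], w$mean_s_index[inf] - w$mean_f_index[inf],
               tolerance = 1e-12)
})

test_that("interval calling merges consecutive qualifying windows", {
  mk <- function(deltas, step = 1e5, window = 1e6) {
    w <- data.frame(chrom = "c", start = 1 + (seq_along(deltas) - 1) * step,
                    mean_delta = deltas)
    w$end <- w$start + window - 1
    attr(w, "step") <- step
    w
  }
  iv <- call_intervals(mk(c(0.2, 0.6, 0.7, 0.3)))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 100001)
  expect_equal(iv$end, 1200000)
  expect_equal(iv$width, iv$end - iv$start + 1)
  expect_equal(iv$peak_abs_delta, 0.7)
  expect_equal(iv$n_windows, 2L)
  # below threshold everywhere: nothing called
  expect_equal(nrow(call_intervals(mk(c(0.2, 0.4, -0.3)))), 0L)
  # negative deltas qualify through the absolute value
  expect_equal(nrow(call_intervals(mk(c(-0.8, -0.6)))), 1L)
  # windows separated by more than a step but physically overlapping merge
  iv2 <- call_intervals(mk(c(0.6, 0.2, 0.2, 0.2, 0.6)))
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$n_windows, 2L)
  # distinct chromosomes never merge
  w2 <- rbind(
    transform(mk(c(0.6, 0.6)), chrom = "c1"),
    transform(mk(c(0.6, 0.6)), chrom = "c2"))
  attr(w2, "step") <- 1e5
  expect_equal(nrow(call_intervals(w2)), 2L)
  # min_windows suppresses single-window calls
  expect_equal(nrow(call_intervals(mk(c(0.2, 0.6, 0.2, 0.2, 0.2, 0.2,
                                        0.2, 0.2, 0.2, 0.2, 0.2, 0.6)),
                                   min_windows = 2)), 0L)
})

test_that("swapping the pools negates deltas and preserves |delta| calls", {
  set.seed(401)
  for (i in 1:10) {
    sites <- random_indexed_sites(500, "chrA", 5e6)
    swapped <- sites
    swapped[, c("f_ref", "f_alt", "s_ref", "s_alt")] <-
      sites[, c("s_ref", "s_alt", "f_ref", "f_alt")]
    swapped <- compute_indices(swapped)
    expect_equal(swapped$delta, -sites$delta)
    w1 <- window_scan(sites, c(chrA = 5e6))
    w2 <- window_scan(swapped, c(chrA = 5e6))
    iv1 <- call_intervals(w1, threshold = 0.2)
    iv2 <- call_intervals(w2, threshold = 0.2)
    expect_equal(iv1$start, iv2$start)
    expect_equal(iv1$end, iv2$end)
    expect_equal(iv1$peak_abs_delta, iv2$peak_abs_delta)
  }
})

test_that("bsa_scan recovers the causal region on a simulated experiment", {
  ex <- tiny_experiment(seed = 57)
  res <- bsa_scan(ex$sites, tiny_genome(), window = 5e5, step = 1e5)
  expect_s3_class(res$windows, "scan_windows")
  expect_gte(nrow(res$intervals), 1L)
  top <- res$intervals[which.max(res$intervals$peak_abs_delta), ]
  expect_identical(top$chrom, "chr1")
  expect_true(top$start <= 1e6 && top$end >= 1e6)
})
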