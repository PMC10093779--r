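bins <- make_bins(default_genome(), 5e6)

test_that("window concordance restricts to aberrant windows", {
  b <- tiny_bins(3, 10)
  a <- prof(c(1, 2, 2), c(1, 1, 0))
  expect_equal(window_concordance(a, a, b)$prop_identical, 1)

  bb <- prof(c(1, 2, 1), c(1, 1, 1))
  r <- window_concordance(a, bb, b)
  expect_equal(r$n_windows_considered, 2L)   # bins 2 and 3
  expect_equal(r$prop_identical, 0.5)        # identical in bin 2 only

  dip <- prof(rep(1, 3))
  r0 <- window_concordance(dip, dip, b)
  expect_false(r0$defined)
  expect_true(is.na(r0$prop_identical))
  expect_equal(r0$n_windows_considered, 0L)
})

test_that("unordered pairs and doubling normalization in window comparison", {
  b <- tiny_bins(2, 10)
  a <- prof(c(2, 1), c(0, 1))
  sw <- prof(c(0, 1), c(2, 1))
  expect_equal(window_concordance(a, sw, b)$prop_identical, 1)  # unordered
  r <- window_concordance(a, a * 2L, b, wgd_a = FALSE, wgd_b = TRUE)
  expect_equal(r$prop_identical, 1)  # halved before comparison
  r2 <- window_concordance(a, a * 2L, b, wgd_a = FALSE, wgd_b = TRUE,
                           normalize_wgd = FALSE)
  expect_lt(r2$prop_identical, 1)
})

test_that("binned median copy number follows the overlap-weighted rule", {
  fine <- make_bins(c(chr1 = 10000), 1000)
  seg <- data.frame(chrom = "chr1", start = 0, end = 10000, total_cn = 3)
  expect_equal(binned_median_cn(seg, fine), rep(3, 10))

  seg2 <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 10000),
                     total_cn = c(2, 4))
  v <- binned_median_cn(seg2, fine)
  expect_equal(v[1], 3)          # 50/50 split -> midpoint
  expect_equal(v[2], 4)

  seg3 <- data.frame(chrom = "chr1", start = 0, end = 9000, total_cn = 2)
  v3 <- binned_median_cn(seg3, fine)
  expect_true(is.na(v3[10]))     # uncovered telomeric bin
  expect_equal(v3[1:9], rep(2, 9))

  seg4 <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(5000, 10000),
                     total_cn = c(2, 3))
  expect_error(binned_median_cn(seg4, fine), "overlapping")
})

test_that("correlation matrix is Pearson with pairwise-complete handling", {
  set.seed(51)
  v <- rnorm(5000)
  m <- cbind(a = v, b = 2 * v + 1, c = v[sample(5000)])
  r <- correlation_matrix(m, min_complete = 100)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], 1)                      # affine invariance
  expect_lt(abs(r["a", "c"]), 0.1)                  # permutation null
  expect_equal(r, t(r))
  # textbook Pearson agreement
  num <- sum((m[, 1] - mean(m[, 1])) * (m[, 3] - mean(m[, 3])))
  den <- sqrt(sum((m[, 1] - mean(m[, 1]))^2) * sum((m[, 3] - mean(m[, 3]))^2))
  expect_equal(r["a", "c"], num / den, tolerance = 1e-12)
})

test_that("zero-variance samples get missing correlations with a warning", {
  m <- cbind(a = rnorm(200), b = rep(2, 200))
  expect_warning(r <- correlation_matrix(m, min_complete = 100),
                 "zero variance")
  expect_true(is.na(r["a", "b"]))
  expect_equal(r["a", "a"], 1)
})

test_that("sample clustering groups by correlation with strict threshold", {
  set.seed(52)
  v <- rnorm(1000)
  m <- cbind(s1 = v, s2 = v, s3 = rnorm(1000))
  r <- correlation_matrix(m, min_complete = 100)
  cl <- cluster_samples(r, threshold = 0.5)
  expect_equal(unname(cl$groups["s1"]), unname(cl$groups["s2"]))
  expect_false(cl$groups["s3"] == cl$groups["s1"])
  expect_equal(length(unique(cl$groups)), 2L)
  # threshold 0: everything separate, even identical samples
  cl0 <- cluster_samples(r, threshold = 0)
  expect_equal(length(unique(cl0$groups)), 3L)
})

test_that("segment round trip: profile -> segments -> binned vector", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 15,
                              seed = 53)
  p <- tr$profiles$clone1
  seg <- profile_to_segments(p, bins)
  expect_true(all(seg$end > seg$start))
  v <- binned_median_cn(seg, bins)
  expect_equal(v, as.numeric(p[, 1] + p[, 2]))
})

test_that("concordance decreases with private events; related pairs correlate", {
  props <- matrix(NA_real_, 3, 4)
  for (s in 1:3) {
    ct <- simulate_clonal_truth(bins, n_clones = 5, n_truncal_events = 20,
                                n_private_events = 2, deletion_bias = 0.7,
                                seed = s, topology = "chain")
    for (k in 1:4)
      props[s, k] <- window_concordance(
        ct$profiles$clone1, ct$profiles[[paste0("clone", k + 1)]],
        bins)$prop_identical
  }
  expect_true(all(diff(colMeans(props)) < 0))

  panel <- simulate_sample_panel(bins, n_pairs = 2, seed = 3)
  fine <- make_bins(stats::setNames(
    tapply(bins$end, bins$chrom, max)[unique(bins$chrom)],
    unique(bins$chrom)), 1000)
  vecs <- vapply(panel$profiles, function(p)
    binned_median_cn(profile_to_segments(p, bins), fine),
    numeric(n_bins(fine)))
  r <- correlation_matrix(vecs)
  within <- c(r["p1_a", "p1_b"], r["p2_a", "p2_b"])
  between <- c(r["p1_a", "p2_a"], r["p1_a", "p2_b"],
               r["p1_b", "p2_a"], r["p1_b", "p2_b"])
  expect_gt(min(within), max(between))
})
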