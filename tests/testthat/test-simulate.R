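bins <- make_bins(default_genome(), 5e6)

test_that("degenerate truths: no events and pure doubling", {
  t0 <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 0,
                              p_wgd = 0, seed = 1)
  expect_identical(t0$profiles$clone1, t0$profiles$diploid)

  t1 <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 0,
                              p_wgd = 1, seed = 1)
  expect_true(all(t1$profiles$clone1 == 2L))
  expect_equal(t1$wgd_edges, "clone1")
})

test_that("deletion_bias = 1 yields only losses among interval events", {
  tr <- simulate_clonal_truth(bins, n_clones = 2, n_truncal_events = 15,
                              n_private_events = 5, deletion_bias = 1,
                              seed = 11)
  ev <- do.call(rbind, tr$edge_events)
  ev <- ev[ev$haplotype != "both", ]
  expect_true(all(ev$delta == -1L))
})

test_that("the same seed reproduces truth and observations exactly", {
  a <- simulate_clonal_truth(bins, n_clones = 3, seed = 5)
  b <- simulate_clonal_truth(bins, n_clones = 3, seed = 5)
  expect_identical(a, b)
  oa <- simulate_cells(a, n_cells = 50, seed = 9)
  ob <- simulate_cells(b, n_cells = 50, seed = 9)
  expect_identical(oa, ob)
  oc <- simulate_cells(a, n_cells = 50, seed = 10)
  expect_false(identical(oa$read_count, oc$read_count))
})

test_that("replaying root-path events reproduces every clone profile", {
  for (s in 1:5) {
    tr <- simulate_clonal_truth(bins, n_clones = 4, n_truncal_events = 15,
                                n_private_events = 4, p_wgd = 0.5, seed = s)
    for (cl in tr$clone_ids)
      expect_identical(replay_truth_profile(tr, cl), tr$profiles[[cl]])
  }
})

test_that("no event regains a lost haplotype in deletion-heavy truths", {
  tr <- simulate_clonal_truth(bins, n_clones = 3, n_truncal_events = 40,
                              n_private_events = 10, deletion_bias = 0.9,
                              seed = 3)
  # replay applying validity checks throws if irreversibility is violated
  for (cl in tr$clone_ids)
    expect_silent(replay_truth_profile(tr, cl))
  expect_true(all(vapply(tr$profiles, min, integer(1)) >= 0))
})

test_that("per-bin read counts match the analytic Poisson mean", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 10,
                              seed = 2, normal_fraction = 0)
  obs <- simulate_cells(tr, n_cells = 1000, mean_coverage = 0.02,
                        noise_cell_fraction = 0, depth_sd = 0, seed = 2)
  tumor <- obs$true_clone == "clone1"
  mu <- expected_bin_reads(tr$profiles$clone1, bins, 0.02)
  obs_mean <- rowMeans(obs$read_count[, tumor])
  se <- sqrt(mu / sum(tumor))
  expect_true(all(abs(obs_mean - mu) <= 3.5 * se + 1e-9))
  # total depth budget: expected reads sum to coverage * genome / read_len
  expect_equal(sum(mu), 0.02 * sum(bin_lengths(bins)) / 100)
})

test_that("BAF behaves at balanced and LOH bins", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 25,
                              deletion_bias = 1, seed = 4, normal_fraction = 0.5)
  obs <- simulate_cells(tr, n_cells = 400, mean_coverage = 0.05,
                        noise_cell_fraction = 0, seed = 4)
  normal <- obs$true_clone == "normal"
  baf_norm <- sum(obs$b_count[, normal]) / sum(obs$snp_total[, normal])
  expect_lt(abs(baf_norm - 0.5), 0.02)
  # (cnA, 0) bins: all SNP reads from haplotype A
  loh <- which(tr$profiles$clone1[, "B"] == 0L & tr$profiles$clone1[, "A"] > 0L)
  if (length(loh)) {
    tumor <- obs$true_clone == "clone1"
    expect_equal(sum(obs$b_count[loh, tumor]), 0L)
    expect_gt(sum(obs$snp_total[loh, tumor]), 0L)
  }
})

test_that("aberrant fraction grows with the truncal event count on average", {
  mean_ab <- function(k) {
    mean(vapply(1:20, function(s) {
      tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = k,
                                  seed = s)
      aberrant_fraction(tr$profiles$clone1, bins, wgd = FALSE)
    }, numeric(1)))
  }
  ab <- vapply(c(5, 15, 30), mean_ab, numeric(1))
  expect_true(all(diff(ab) > 0))
})

test_that("min_private_span enforces clone separation", {
  tr <- simulate_clonal_truth(bins, n_clones = 3, n_truncal_events = 20,
                              n_private_events = 1, seed = 8,
                              min_private_span = 0.15)
  parent_of <- stats::setNames(tr$edges$parent, tr$edges$child)
  for (cl in tr$clone_ids[-1]) {
    span <- cell_distance(tr$profiles[[cl]], tr$profiles[[parent_of[[cl]]]],
                          bins = bins)
    expect_gte(span, 0.15)
  }
})
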