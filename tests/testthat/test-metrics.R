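bins <- make_bins(default_genome(), 5e6)
b10 <- tiny_bins(10, 10)

test_that("detect_wgd flags tetraploid but not diploid or deletion-heavy", {
  expect_true(detect_wgd(prof(rep(2, 10)), b10))
  expect_false(detect_wgd(prof(rep(1, 10)), b10))
  # exactly 2x an aneuploid non-doubled profile with most of the genome >= (2,2)
  base <- prof(c(1, 1, 1, 1, 1, 1, 2, 1, 0, 1), c(1, 1, 1, 1, 1, 1, 1, 0, 0, 1))
  expect_false(detect_wgd(base, b10))
  expect_true(detect_wgd(base * 2L, b10))
})

test_that("aberrant_fraction uses the doubling-dependent baseline", {
  expect_equal(aberrant_fraction(prof(rep(1, 10)), b10, wgd = FALSE), 0)
  p <- prof(rep(1, 10)); p[1, ] <- c(2L, 0L)
  expect_equal(aberrant_fraction(p, b10, wgd = FALSE), 0.1)
  expect_equal(aberrant_fraction(prof(rep(2, 10)), b10, wgd = TRUE), 0)
  # unordered comparison: swapping haplotypes changes nothing
  q <- prof(c(2, 1, 1, 0, 1, 1, 1, 1, 1, 1), c(0, 1, 2, 1, 1, 1, 1, 1, 1, 1))
  qs <- q[, c(2, 1)]; colnames(qs) <- c("A", "B")
  expect_equal(aberrant_fraction(q, b10, FALSE), aberrant_fraction(qs, b10, FALSE))
})

test_that("deletion/amplification rules follow the per-allele baseline", {
  p20 <- prof(2, 0)
  expect_equal(unname(deletion_amplification_fractions(p20, tiny_bins(1, 10), FALSE)),
               c(1, 1))   # 0 < 1 deleted AND 2 > 1 amplified
  expect_equal(unname(deletion_amplification_fractions(p20, tiny_bins(1, 10), TRUE)),
               c(1, 0))   # under the doubled baseline only deleted
  p11 <- prof(1, 1)
  expect_equal(unname(deletion_amplification_fractions(p11, tiny_bins(1, 10), FALSE)),
               c(0, 0))
})

test_that("doubling commutes with the baseline shift", {
  for (s in 1:5) {
    tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 20,
                                deletion_bias = 0.7, seed = s)
    base <- tr$profiles$clone1
    expect_identical(deletion_amplification_fractions(base, bins, FALSE),
                     deletion_amplification_fractions(base * 2L, bins, TRUE))
    expect_identical(aberrant_fraction(base, bins, FALSE),
                     aberrant_fraction(base * 2L, bins, TRUE))
  }
})

test_that("subclonal fraction counts disagreement with the modal state", {
  b <- tiny_bins(10, 10)
  modal <- prof(rep(1, 10))
  expect_equal(subclonal_fraction(modal, modal, b), 0)
  p <- modal; p[1:2, "B"] <- 0L
  expect_equal(subclonal_fraction(p, modal, b), 0.2)
})

test_that("a non-doubled subpopulation inside a doubled tumor is subclonal over the aberrant share", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 20,
                              deletion_bias = 0.7, seed = 12)
  base <- tr$profiles$clone1
  doubled <- base * 2L
  # doubled cells dominate: modal state is the doubled profile
  calls <- structure(list(
    bins = bins, cell_ids = sprintf("c%02d", 1:10),
    cnA = cbind(matrix(doubled[, "A"], n_bins(bins), 7),
                matrix(base[, "A"], n_bins(bins), 3)),
    cnB = cbind(matrix(doubled[, "B"], n_bins(bins), 7),
                matrix(base[, "B"], n_bins(bins), 3))), class = "cell_cn")
  m <- modal_state(calls)
  expect_identical(unname(m), unname(doubled))
  fs <- subclonal_fraction(base, m, bins)
  # they differ wherever the doubled state differs from the base state,
  # i.e. everywhere the base profile is not all-zero
  w <- bin_lengths(bins)
  expect_equal(fs, sum(w[rowSums(base) > 0]) / sum(w))
})

test_that("locus status classifies LOH and copy-neutral LOH", {
  b <- tiny_bins(10, 10)
  loc <- list(chrom = "chr1", start = 20, end = 40)
  p <- prof(rep(1, 10))
  expect_equal(locus_status(p, loc, b, wgd = FALSE)$status, "no_loh")
  p[3:4, "B"] <- 0L
  expect_equal(locus_status(p, loc, b, wgd = FALSE)$status, "loh")
  p[3:4, "A"] <- 2L
  st <- locus_status(p, loc, b, wgd = FALSE)
  expect_equal(st$status, "cn_loh")
  expect_equal(unname(st$cn_at_locus), c(2L, 0L))
  expect_error(locus_status(p, list(chrom = "chrX", start = 0, end = 10), b),
               "outside")
})

test_that("cell_metrics fractions respect their invariants", {
  tr <- simulate_clonal_truth(bins, n_clones = 2, n_truncal_events = 25,
                              n_private_events = 5, seed = 13)
  obs <- simulate_cells(tr, n_cells = 60, mean_coverage = 0.03, seed = 13)
  met <- cell_metrics(call_cells(compute_signals(obs)))
  expect_true(all(met$frac_aberrant >= 0 & met$frac_aberrant <= 1))
  expect_true(all(met$frac_aberrant <= met$frac_deleted + met$frac_amplified + 1e-12))
  expect_true(all(met$frac_subclonal >= 0 & met$frac_subclonal <= 1))
  expect_equal(met$wgd, rep(met$wgd[1], nrow(met)))  # tumor-level flag
})

test_that("metrics from truth profiles equal metrics from replayed events", {
  tr <- simulate_clonal_truth(bins, n_clones = 3, n_truncal_events = 20,
                              n_private_events = 5, seed = 14)
  for (cl in tr$clone_ids) {
    replayed <- replay_truth_profile(tr, cl)
    expect_identical(aberrant_fraction(tr$profiles[[cl]], bins, FALSE),
                     aberrant_fraction(replayed, bins, FALSE))
    expect_identical(deletion_amplification_fractions(tr$profiles[[cl]], bins, FALSE),
                     deletion_amplification_fractions(replayed, bins, FALSE))
  }
})
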