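bins <- make_bins(default_genome(), 5e6)

# hand-built observation set: 2 cells, uniform coverage on a 4-bin genome
toy_obs <- function() {
  b <- tiny_bins(4, 10)
  structure(list(
    bins = b, cell_ids = c("c1", "c2"),
    read_count = cbind(c1 = rep(100L, 4), c2 = c(100L, 100L, 0L, 200L)),
    b_count = cbind(c1 = c(5L, 0L, 3L, 10L), c2 = rep(0L, 4)),
    snp_total = cbind(c1 = c(10L, 0L, 9L, 20L), c2 = rep(0L, 4)),
    true_clone = c("normal", "normal")), class = "cell_obs")
}

test_that("compute_signals builds RDR and BAF with missing-data contract", {
  obs <- toy_obs()
  sig <- compute_signals(obs, reference = rep(0.25, 4))
  expect_equal(unname(sig$rdr[, "c1"]), rep(1, 4))       # uniform/uniform
  expect_equal(unname(sig$baf[1, "c1"]), 0.5)            # 5/10
  expect_true(is.na(sig$baf[2, "c1"]))                   # snp_total 0 -> NA
  expect_false(any(sig$baf[2, ] == 0, na.rm = TRUE))
})

test_that("cells with zero total reads are dropped with a warning", {
  obs <- toy_obs()
  obs$read_count[, "c2"] <- 0L
  expect_warning(sig <- compute_signals(obs, reference = rep(0.25, 4)),
                 "zero total reads")
  expect_equal(sig$cell_ids, "c1")
})

test_that("fit_scale resolves the diploid/tetraploid tie toward low ploidy", {
  b <- tiny_bins(20, 10)
  sig <- structure(list(
    bins = b, cell_ids = "c1",
    rdr = matrix(1, 20, 1, dimnames = list(NULL, "c1")),
    baf = matrix(0.5, 20, 1),
    snp_total = matrix(30L, 20, 1)), class = "cell_signals")
  s <- fit_scale(sig, 1)
  expect_equal(as.numeric(s), 2, tolerance = 1e-6)
  prof <- call_cell(sig, s, 1)
  expect_true(all(prof$cn[, "A"] == 1L & prof$cn[, "B"] == 1L))
})

test_that("unbalanced BAF forces the higher-ploidy solution", {
  # rdr flat at 1, half the genome at BAF 0.25: only total 4 = {3,1} fits
  b <- tiny_bins(20, 10)
  sig <- structure(list(
    bins = b, cell_ids = "c1",
    rdr = matrix(1, 20, 1, dimnames = list(NULL, "c1")),
    baf = matrix(c(rep(0.5, 10), rep(0.25, 10)), 20, 1),
    snp_total = matrix(200L, 20, 1)), class = "cell_signals")
  s <- fit_scale(sig, 1)
  expect_equal(as.numeric(s), 4, tolerance = 1e-6)
  prof <- call_cell(sig, s, 1)
  expect_true(all(prof$cn[11:20, "A"] == 3L & prof$cn[11:20, "B"] == 1L))
  expect_true(all(prof$cn[1:10, "A"] == 2L & prof$cn[1:10, "B"] == 2L))
})

test_that("rdr of 2 against a diploid reference maps to total copy 4", {
  b <- tiny_bins(20, 10)
  sig <- structure(list(
    bins = b, cell_ids = "c1",
    rdr = matrix(2, 20, 1, dimnames = list(NULL, "c1")),
    baf = matrix(0.5, 20, 1),
    snp_total = matrix(30L, 20, 1)), class = "cell_signals")
  s <- fit_scale(sig, 1)
  prof <- call_cell(sig, s, 1)
  expect_true(all(prof$cn[, "A"] + prof$cn[, "B"] == 4L))
})

test_that("allele splits follow BAF with deterministic ties", {
  b <- tiny_bins(3, 10)
  sig <- structure(list(
    bins = b, cell_ids = "c1",
    rdr = matrix(c(2, 2, 3) / 2, 3, 1, dimnames = list(NULL, "c1")),
    baf = matrix(c(0.5, 0.02, 0.33), 3, 1),
    snp_total = matrix(50L, 3, 1)), class = "cell_signals")
  prof <- call_cell(sig, scale = 2, cell = 1)
  expect_equal(unname(prof$cn[1, ]), c(1L, 1L))   # balanced
  expect_equal(unname(prof$cn[2, ]), c(2L, 0L))   # copy-neutral LOH state
  expect_equal(unname(prof$cn[3, ]), c(2L, 1L))   # nearest split
})

test_that("reported ploidy is the length-weighted mean of called totals", {
  tr <- simulate_clonal_truth(bins, n_clones = 2, n_truncal_events = 20,
                              seed = 6)
  obs <- simulate_cells(tr, n_cells = 30, mean_coverage = 0.05, seed = 6)
  calls <- call_cells(compute_signals(obs))
  w <- bin_lengths(bins)
  for (j in seq_along(calls$cell_ids)) {
    expect_equal(calls$ploidy[j],
                 sum(w * (calls$cnA[, j] + calls$cnB[, j])) / sum(w))
  }
})

test_that("calls recover the truth on clean high-coverage data", {
  tr <- simulate_clonal_truth(bins, n_clones = 2, n_truncal_events = 20,
                              n_private_events = 5, seed = 7,
                              normal_fraction = 0.2)
  obs <- simulate_cells(tr, n_cells = 60, mean_coverage = 0.05,
                        noise_cell_fraction = 0, seed = 7)
  calls <- call_cells(compute_signals(obs))
  match_frac <- vapply(seq_along(calls$cell_ids), function(j) {
    tl <- obs$true_clone[j]
    tp <- if (tl == "normal") tr$profiles$diploid else tr$profiles[[tl]]
    1 - cell_distance(cbind(A = calls$cnA[, j], B = calls$cnB[, j]), tp,
                      bins = bins)
  }, numeric(1))
  expect_gte(mean(match_frac >= 0.99), 0.95)
})

test_that("doubling every count leaves calls invariant (ratio normalization)", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 15,
                              seed = 9, normal_fraction = 0.3)
  obs <- simulate_cells(tr, n_cells = 40, mean_coverage = 0.03, seed = 9)
  calls1 <- call_cells(compute_signals(obs))
  obs2 <- obs
  obs2$read_count <- obs$read_count * 2L
  obs2$b_count <- obs$b_count * 2L
  obs2$snp_total <- obs$snp_total * 2L
  calls2 <- call_cells(compute_signals(obs2))
  expect_identical(calls1$cnA, calls2$cnA)
  expect_identical(calls1$cnB, calls2$cnB)
})
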