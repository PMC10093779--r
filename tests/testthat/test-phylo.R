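bins <- make_bins(default_genome(), 5e6)
b5 <- tiny_bins(5, 10)
b3 <- tiny_bins(3, 10)

test_that("interval-event distance handles the canonical small cases", {
  p <- prof(rep(1, 5))
  expect_equal(interval_event_distance(p, p, b5)$count, 0)
  expect_equal(nrow(interval_event_distance(p, p, b5)$events), 0L)

  c1 <- prof(c(1, 2, 2, 2, 1), rep(1, 5))
  d1 <- interval_event_distance(p, c1, b5)
  expect_equal(d1$count, 1)
  expect_equal(d1$events$start_bin, 1L)
  expect_equal(d1$events$end_bin, 4L)

  c2 <- prof(c(2, 3, 2), rep(1, 3))
  expect_equal(interval_event_distance(prof(rep(1, 3)), c2, b3)$count, 2)

  expect_error(interval_event_distance(prof(c(0, 1, 1)), prof(c(1, 1, 1)), b3),
               "no valid event path")
})

test_that("event replay maps parent to child for random profile pairs", {
  set.seed(31)
  for (rep in 1:40) {
    pv <- prof(sample(0:3, 5, TRUE), sample(0:3, 5, TRUE))
    ev_n <- sample(1:4, 1)
    cv <- pv
    for (k in seq_len(ev_n)) {
      i <- sample(1:5, 1); j <- sample(i:5, 1)
      hap <- sample(c("A", "B"), 1)
      dir <- sample(c(-1L, 1L), 1)
      seg <- cv[i:j, hap]
      if (dir > 0 && all(seg > 0) && all(seg < 6)) cv[i:j, hap] <- seg + 1L
      if (dir < 0 && all(seg > 0)) cv[i:j, hap] <- seg - 1L
    }
    d <- interval_event_distance(pv, cv, b5)
    expect_identical(unname(apply_events(pv, d$events)), unname(cv))
    expect_lte(d$count, ev_n)
  }
})

test_that("a doubled edge splits events optimally around the doubling", {
  p <- prof(rep(1, 3))
  r <- interval_event_distance(p, p * 2L, b3, allow_wgd = TRUE)
  expect_equal(r$count, 1); expect_true(r$wgd)
  # pre-doubling gain is cheaper than two post-doubling gains
  cc <- prof(c(2, 2, 4), c(2, 2, 2))
  r2 <- interval_event_distance(p, cc, b3, allow_wgd = TRUE)
  expect_equal(r2$count, 2)
  expect_identical(unname(apply_events(p, r2$events)), unname(cc))
  # without allow_wgd the same child needs 4 events (3 on A, 1 on B)
  expect_equal(interval_event_distance(p, cc, b3, allow_wgd = FALSE)$count, 4)
})

test_that("adding a non-merging private event raises the count by exactly 1", {
  set.seed(32)
  for (rep in 1:10) {
    tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 10,
                                seed = rep)
    base <- tr$profiles$clone1
    d0 <- interval_event_distance(tr$profiles$diploid, base, bins)$count
    # place a 2-bin gain inside a chromosome where it cannot merge:
    # pick a run of >= 4 constant non-zero bins and alter its middle
    cbi <- chrom_bin_index(bins)
    placed <- FALSE
    for (ch in sample(names(cbi))) {
      idx <- cbi[[ch]]
      v <- base[idx, "A"]
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
      k <- which(r$lengths >= 4 & r$values > 0)
      if (length(k)) {
        k <- k[1]
        mid <- idx[starts[k] + 1L]
        child <- base
        child[mid:(mid + 1L), "A"] <- child[mid:(mid + 1L), "A"] + 1L
        d1 <- interval_event_distance(tr$profiles$diploid, child, bins)$count
        expect_equal(d1, d0 + 1)
        placed <- TRUE
        break
      }
    }
    expect_true(placed)
  }
})

test_that("event classification follows the LOH taxonomy", {
  p <- prof(rep(1, 3))
  ev <- scnaclonal:::event_row
  loh_ev <- ev("B", "chr1", 0L, 2L, -1L)
  out <- classify_events(loh_ev, p, b3)
  expect_equal(out$kind, "loh")
  # (1,1) -> (0,2): joint loss+gain over the same interval is cn_loh
  both <- rbind(ev("B", "chr1", 0L, 2L, -1L), ev("A", "chr1", 0L, 2L, 1L))
  out2 <- classify_events(both, p, b3)
  expect_equal(out2$kind[out2$delta == -1L], "cn_loh")
  expect_equal(out2$kind[out2$delta == 1L], "gain")
  # (2,1) -> (1,1): copies remain, plain deletion
  out3 <- classify_events(ev("A", "chr1", 0L, 3L, -1L), prof(rep(2, 3), rep(1, 3)), b3)
  expect_equal(out3$kind, "del")
  # genome-wide doubling
  out4 <- classify_events(scnaclonal:::wgd_event(), p, b3)
  expect_equal(out4$kind, "wgd")
})

test_that("a single clone hangs off the diploid root with its truncal events", {
  tr <- simulate_clonal_truth(bins, n_clones = 1, n_truncal_events = 12, seed = 41)
  tree <- reconstruct_tree(tr$profiles["clone1"], bins)
  expect_equal(nrow(tree$edges), 1L)
  expect_equal(tree$edges$parent, "diploid")
  expect_true(all(tree$nodes$diploid == 1L))
  expect_identical(unname(apply_events(tree$nodes$diploid,
                                       tree$edge_events$clone1)),
                   unname(tr$profiles$clone1))
})

test_that("two clones sharing truncal events get a common unobserved ancestor", {
  b <- tiny_bins(12, 10)
  shared <- prof(c(2, 2, 2, 2, 1, 1, 1, 1, 0, 0, 1, 1),
                 c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  c1 <- shared; c1[5, "B"] <- 0L   # one private event each
  c2 <- shared; c2[11:12, "A"] <- 2L
  tree <- reconstruct_tree(list(cloneA = c1, cloneB = c2), b)
  expect_equal(tree$total_events, 2 + 1 + 1)  # truncal (2) + 2 privates
  anc <- names(tree$node_type)[tree$node_type == "ancestor"]
  expect_length(anc, 1L)
  expect_identical(unname(tree$nodes[[anc]]), unname(shared))
  expect_true(edges_replay_exactly(tree))
})

test_that("reconstruction places a doubling on the correct edge", {
  b <- tiny_bins(12, 10)
  base <- prof(c(2, 2, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1), rep(1, 12))
  doubled <- base * 2L
  doubled[1:2, "A"] <- doubled[1:2, "A"] + 1L  # one post-doubling gain
  tree <- reconstruct_tree(list(low = base, high = doubled), b)
  wgd_edges <- vapply(tree$edge_events, function(e) any(e$haplotype == "both"),
                      logical(1))
  expect_equal(sum(wgd_edges), 1L)
  expect_true(wgd_edges[["high"]])
  expect_true(edges_replay_exactly(tree))
})

test_that("more than 8 clones is refused", {
  profs <- lapply(1:9, function(i) {
    p <- prof(rep(1, 5)); p[seq_len(min(i, 5)), "A"] <- 2L; p
  })
  names(profs) <- paste0("c", 1:9)
  expect_error(reconstruct_tree(profs, b5), "more than 8")
})
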