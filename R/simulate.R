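#' Simulate a clonal copy-number evolution
#'
#' Generates a rooted clone tree whose root is the normal diploid profile,
#' with truncal interval events on the root edge and private events on each
#' later edge. Each interval event adds or removes one copy of one haplotype
#' over a contiguous sub-interval of a uniformly chosen chromosome; losses
#' are drawn with probability \code{deletion_bias} (tumors of this kind are
#' deletion-dominated). A whole-genome doubling is inserted on one uniformly
#' chosen edge with probability \code{p_wgd}. Loss of heterozygosity is
#' irreversible: an event that would push a haplotype below 0, or regain a
#' haplotype already at 0, is resampled (the number of resamples is
#' recorded).
#'
#' @param bins A \code{\link{make_bins}} grid.
#' @param n_clones Number of tumor clones (>= 1).
#' @param n_truncal_events Interval events on the root edge, shared by all
#'   clones.
#' @param n_private_events Interval events private to each non-founder
#'   clone edge.
#' @param p_wgd Probability that one edge carries a whole-genome doubling.
#' @param deletion_bias Probability that an interval event is a loss.
#' @param seed Integer seed; the same seed reproduces the truth exactly.
#' @param topology \code{"random"} attaches each new clone to a uniformly
#'   chosen existing clone; \code{"chain"} builds a linear
#'   clone1 -> clone2 -> ... chain.
#' @param clone_proportions Optional tumor-clone fractions (summing to 1);
#'   default draws from a symmetric Dirichlet and sorts decreasing.
#' @param normal_fraction Fraction of sampled cells that are normal diploid.
#' @param min_event_bins Minimum event width in bins (default 1).
#' @param min_private_span Optional genome fraction: each non-founder clone
#'   must differ from its parent over at least this fraction of the genome;
#'   extra private events are drawn until the span is reached. NULL (the
#'   default) applies exactly \code{n_private_events}.
#' @return A \code{clonal_truth} object: tree edges, per-edge event tables,
#'   per-node profiles, clone proportions, WGD edges and bookkeeping.
#' @export
simulate_clonal_truth <- function(bins, n_clones,
                                  n_truncal_events = 20,
                                  n_private_events = 5,
                                  p_wgd = 0,
                                  deletion_bias = 0.7,
                                  seed = 1L,
                                  topology = c("random", "chain"),
                                  clone_proportions = NULL,
                                  normal_fraction = 0.1,
                                  min_event_bins = 1L,
                                  min_private_span = NULL) {
  topology <- match.arg(topology)
  stopifnot(n_clones >= 1, n_truncal_events >= 0, n_private_events >= 0,
            p_wgd >= 0, p_wgd <= 1, deletion_bias >= 0, deletion_bias <= 1,
            normal_fraction >= 0, normal_fraction < 1)
  cbi <- chrom_bin_index(bins)
  resamples <- 0L

  with_seed(substream_seed(seed, "truth"), {
    clone_ids <- paste0("clone", seq_len(n_clones))
    parent_of <- c(clone1 = "diploid")
    if (n_clones > 1) {
      for (k in 2:n_clones) {
        parent_of[clone_ids[k]] <-
          if (topology == "chain") clone_ids[k - 1L]
          else sample(clone_ids[seq_len(k - 1L)], 1L)
      }
    }
    # sample one valid interval event given the current profile
    sample_event <- function(profile) {
      for (attempt in seq_len(1000L)) {
        ch <- sample(names(cbi), 1L)
        idx <- cbi[[ch]]
        nb <- length(idx)
        if (nb < min_event_bins) next
        lens <- min_event_bins:nb
        len <- if (length(lens) == 1L) lens else
          sample(lens, 1L, prob = nb - lens + 1)   # uniform over sub-intervals
        start_local <- sample.int(nb - len + 1L, 1L) - 1L
        s <- idx[1L] - 1L + start_local            # global 0-based
        hap <- sample(c("A", "B"), 1L)
        delta <- if (runif(1) < deletion_bias) -1L else 1L
        cur <- profile[(s + 1L):(s + len), hap]
        if (delta < 0L && all(cur + delta >= 0L))
          return(event_row(hap, ch, s, s + len, delta))
        if (delta > 0L && all(cur > 0L))
          return(event_row(hap, ch, s, s + len, delta))
        resamples <<- resamples + 1L
      }
      stop("could not sample a valid event after 1000 attempts")
    }

    wgd_edge <- if (runif(1) < p_wgd) sample(clone_ids, 1L) else NULL

    profiles <- list(diploid = diploid_profile(bins))
    edge_events <- list()
    for (cl in clone_ids) {
      par <- parent_of[[cl]]
      prof <- profiles[[par]]
      nev <- if (par == "diploid") n_truncal_events else n_private_events
      evs <- empty_events()
      if (identical(wgd_edge, cl)) {
        evs <- rbind(evs, wgd_event())
        prof <- prof * 2L
      }
      if (nev > 0) for (j in seq_len(nev)) {
        ev <- sample_event(prof)
        prof <- apply_events(prof, ev)
        evs <- rbind(evs, ev)
      }
      if (!is.null(min_private_span) && par != "diploid") {
        w <- bin_lengths(bins)
        span <- function(a, b) sum(w[a[, 1] != b[, 1] | a[, 2] != b[, 2]]) / sum(w)
        guard <- 0L
        while (span(prof, profiles[[par]]) < min_private_span) {
          ev <- sample_event(prof)
          prof <- apply_events(prof, ev)
          evs <- rbind(evs, ev)
          guard <- guard + 1L
          if (guard > 500L) stop("min_private_span unreachable")
        }
      }
      edge_events[[cl]] <- evs
      profiles[[cl]] <- prof
    }

    if (is.null(clone_proportions)) {
      w <- sort(stats::rgamma(n_clones, shape = 5), decreasing = TRUE)
      clone_proportions <- w / sum(w)
    }
    if (abs(sum(clone_proportions) - 1) > 1e-8)
      stop("clone_proportions must sum to 1")
    names(clone_proportions) <- clone_ids

    structure(list(
      bins = bins,
      clone_ids = clone_ids,
      edges = data.frame(parent = unname(parent_of[clone_ids]),
                         child = clone_ids, stringsAsFactors = FALSE),
      edge_events = edge_events,
      profiles = profiles,
      clone_proportions = clone_proportions,
      wgd_edges = if (is.null(wgd_edge)) character(0) else wgd_edge,
      normal_fraction = normal_fraction,
      deletion_bias = deletion_bias,
      seed = seed,
      resample_count = resamples
    ), class = "clonal_truth")
  })
}

# ordered edge keys (child node names) from the diploid root to a node
root_path_edges <- function(truth, node) {
  parent_of <- stats::setNames(truth$edges$parent, truth$edges$child)
  path <- character(0)
  v <- node
  while (v != "diploid") { path <- c(v, path); v <- parent_of[[v]] }
  path
}

#' Replay a clone profile from its root-path events
#'
#' Recomputes a clone's profile by applying the edge event tables along
#' the path from the diploid root; by construction this must reproduce
#' \code{truth$profiles[[clone]]} exactly.
#'
#' @param truth A \code{clonal_truth}.
#' @param clone Clone id.
#' @return bins x 2 integer profile matrix.
#' @export
replay_truth_profile <- function(truth, clone) {
  prof <- truth$profiles$diploid
  for (e in root_path_edges(truth, clone))
    prof <- apply_events(prof, truth$edge_events[[e]])
  prof
}

#' @export
print.clonal_truth <- function(x, ...) {
  cat(sprintf("clonal_truth: %d clones on %d bins; truncal events %d; WGD edges: %s\n",
              length(x$clone_ids), n_bins(x$bins),
              nrow(x$edge_events[[x$clone_ids[1]]]),
              if (length(x$wgd_edges)) paste(x$wgd_edges, collapse = ",") else "none"))
  invisible(x)
}

#' Simulate sparse single-cell observations from a clonal truth
#'
#' Draws cells from the clone proportions (plus normal diploid cells and
#' noisy cells), then per-bin read counts and phased B-allele counts at the
#' sparse depths characteristic of droplet single-cell DNA-seq
#' (0.01X-0.05X per cell). Per-bin read counts are Poisson (optionally
#' negative binomial) with mean proportional to bin length times total copy
#' number, normalized so a cell's expected total equals its depth budget
#' (coverage x genome size / read length, times a lognormal per-cell depth
#' factor). SNP-overlapping read totals scale with \code{snp_density},
#' local coverage and local total copy number; B-haplotype counts are
#' binomial with success probability cnB/(cnA+cnB) (0.5 in (0,0) bins).
#' Noisy cells take a random clone profile with each bin resampled from
#' \{0..4\}^2 with probability \code{noise_perturb_prob}.
#'
#' @param truth A \code{clonal_truth}.
#' @param bins Bin grid (defaults to the truth's).
#' @param n_cells Number of cells to draw.
#' @param mean_coverage Mean per-cell sequencing coverage in X-fold units
#'   (default 0.02).
#' @param read_length Read length in bp used to convert coverage to a read
#'   budget (default 100).
#' @param snp_density Heterozygous SNPs per bp (default 1/2000).
#' @param noise_cell_fraction Fraction of cells that are noisy.
#' @param noise_perturb_prob Per-bin resampling probability in noisy cells.
#' @param depth_sd Lognormal sd of the per-cell depth factor.
#' @param overdispersion NULL for Poisson counts, or a negative binomial
#'   size parameter (smaller = more overdispersed).
#' @param seed Integer seed.
#' @return A \code{cell_obs} object: bins, cell ids, integer matrices
#'   \code{read_count}, \code{b_count}, \code{snp_total} (bins x cells) and
#'   the true label of every cell ("normal", "noise" or a clone id).
#' @export
simulate_cells <- function(truth, bins = truth$bins, n_cells,
                           mean_coverage = 0.02, read_length = 100,
                           snp_density = 1 / 2000,
                           noise_cell_fraction = 0.05,
                           noise_perturb_prob = 0.3,
                           depth_sd = 0.1,
                           overdispersion = NULL,
                           seed = 1L) {
  stopifnot(n_cells >= 1, mean_coverage > 0)
  props <- truth$clone_proportions
  if (abs(sum(props) - 1) > 1e-8) stop("clone proportions must sum to 1")
  nb <- n_bins(bins)
  lens <- bin_lengths(bins)
  genome_bp <- sum(lens)

  with_seed(substream_seed(seed, "cells"), {
    type_probs <- c(normal = truth$normal_fraction,
                    noise = noise_cell_fraction)
    tumor_p <- 1 - sum(type_probs)
    if (tumor_p < 0) stop("normal_fraction + noise_cell_fraction exceeds 1")
    labels <- character(n_cells)
    read_count <- b_count <- snp_total <-
      matrix(0L, nrow = nb, ncol = n_cells)

    for (i in seq_len(n_cells)) {
      u <- runif(1)
      if (u < type_probs["normal"]) {
        lab <- "normal"; prof <- truth$profiles$diploid
      } else if (u < sum(type_probs)) {
        lab <- "noise"
        base <- sample(truth$clone_ids, 1L)
        prof <- truth$profiles[[base]]
        hit <- which(runif(nb) < noise_perturb_prob)
        if (length(hit)) {
          prof[hit, "A"] <- sample(0:4, length(hit), replace = TRUE)
          prof[hit, "B"] <- sample(0:4, length(hit), replace = TRUE)
        }
      } else {
        lab <- sample(truth$clone_ids, 1L, prob = props)
        prof <- truth$profiles[[lab]]
      }
      labels[i] <- lab

      tot <- prof[, "A"] + prof[, "B"]
      f <- stats::rlnorm(1, meanlog = -depth_sd^2 / 2, sdlog = depth_sd)
      budget <- mean_coverage * genome_bp / read_length * f
      w <- lens * tot
      lambda <- if (sum(w) > 0) budget * w / sum(w) else rep(0, nb)
      read_count[, i] <- if (is.null(overdispersion))
        stats::rpois(nb, lambda)
      else stats::rnbinom(nb, mu = lambda, size = overdispersion)

      ploidy <- sum(lens * tot) / genome_bp
      cov_local <- if (ploidy > 0) mean_coverage * f * tot / ploidy else rep(0, nb)
      snp_total[, i] <- stats::rpois(nb, snp_density * lens * cov_local)
      pb <- ifelse(tot > 0, prof[, "B"] / pmax(tot, 1L), 0.5)
      b_count[, i] <- stats::rbinom(nb, snp_total[, i], pb)
    }

    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    colnames(read_count) <- colnames(b_count) <- colnames(snp_total) <- cell_ids
    structure(list(bins = bins, cell_ids = cell_ids,
                   read_count = read_count, b_count = b_count,
                   snp_total = snp_total, true_clone = labels,
                   mean_coverage = mean_coverage, seed = seed),
              class = "cell_obs")
  })
}

#' @export
print.cell_obs <- function(x, ...) {
  cat(sprintf("cell_obs: %d cells x %d bins (~%.3fX per cell); truth labels: %s\n",
              length(x$cell_ids), n_bins(x$bins), x$mean_coverage,
              paste(names(table(x$true_clone)), collapse = ", ")))
  invisible(x)
}

# Expected per-bin Poisson mean for a given profile and depth factor:
# exposed for tests of the count model.
expected_bin_reads <- function(profile, bins, mean_coverage, read_length = 100,
                               depth_factor = 1) {
  lens <- bin_lengths(bins)
  tot <- profile[, "A"] + profile[, "B"]
  budget <- mean_coverage * sum(lens) / read_length * depth_factor
  w <- lens * tot
  if (sum(w) > 0) budget * w / sum(w) else rep(0, length(lens))
}
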