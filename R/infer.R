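# Per-cell allele-specific copy-number calling from binned read counts and
# phased B-allele counts. This is a deliberately simple per-cell caller:
# RDR/BAF construction, a grid-plus-refinement fit of the depth-to-copies
# scale, and per-bin integer calls. Joint inference across cells is left to
# the clone stage.

#' Compute read-depth ratios and B-allele frequencies
#'
#' Converts raw per-bin counts into the two signals the caller consumes:
#' RDR, the cell's bin read proportion divided by the reference (diploid)
#' bin proportion, which is proportional to total copy number; and BAF,
#' the fraction of phased SNP reads supporting the B haplotype, missing
#' (NA) in bins with no SNP reads.
#'
#' @param obs A \code{cell_obs} object.
#' @param reference Per-bin expected read proportions under a diploid
#'   genome. Default NULL: built from the cells labelled "normal" when the
#'   observations carry truth labels, else from the pseudobulk of all
#'   cells.
#' @return A \code{cell_signals} object with matrices \code{rdr},
#'   \code{baf}, \code{snp_total} (bins x cells). Cells with zero total
#'   reads are dropped with a warning.
#' @export
compute_signals <- function(obs, reference = NULL) {
  if (length(obs$cell_ids) == 0L) stop("no cells")
  if (is.null(reference)) {
    normals <- which(obs$true_clone == "normal")
    ref_counts <- if (length(normals) >= 5)
      rowSums(obs$read_count[, normals, drop = FALSE])
    else rowSums(obs$read_count)
    reference <- ref_counts / sum(ref_counts)
  }
  if (abs(sum(reference) - 1) > 1e-6)
    stop("reference proportions must sum to 1")
  totals <- colSums(obs$read_count)
  keep <- totals > 0
  if (any(!keep))
    warning(sprintf("dropped %d cell(s) with zero total reads", sum(!keep)))
  rc <- obs$read_count[, keep, drop = FALSE]
  prop <- sweep(rc, 2, colSums(rc), "/")
  rdr <- prop / reference
  # bins absent from the reference (e.g. homozygous deletion in every
  # contributing cell) carry no depth information: define RDR 0 there
  rdr[reference == 0, ] <- 0
  baf <- obs$b_count[, keep, drop = FALSE] / obs$snp_total[, keep, drop = FALSE]
  baf[obs$snp_total[, keep, drop = FALSE] == 0] <- NA_real_
  structure(list(bins = obs$bins, cell_ids = obs$cell_ids[keep],
                 rdr = rdr, baf = baf,
                 snp_total = obs$snp_total[, keep, drop = FALSE],
                 reference = reference,
                 true_clone = obs$true_clone[keep]),
            class = "cell_signals")
}

# Scale-independent part of the fitting cost: per bin, the best-achievable
# squared BAF distance for every candidate integer total, with the
# SNP-depth and bin-length weights. Built once per cell.
make_scale_ctx <- function(baf, snp_total, lens, max_cn = 8L,
                           baf_weight = 2) {
  cand <- 0:max_cn
  nb <- length(baf)
  bd <- matrix(0, nb, length(cand))
  has_baf <- !is.na(baf)
  for (j in seq_along(cand)) {
    t <- cand[j]
    if (t == 0L) { bd[has_baf, j] <- (baf[has_baf] - 0.5)^2; next }
    fr <- (0:t) / t
    bd[has_baf, j] <- apply(abs(outer(baf[has_baf], fr, "-")), 1, min)^2
  }
  w_snp <- snp_total / max(mean(snp_total), 1)
  w_len <- lens / mean(lens)
  list(cand = cand, nb = nb,
       baf_part = baf_weight * bd * w_snp * w_len, w_len = w_len)
}

# Per-bin fitting cost for a candidate scale: each bin is assigned the
# integer total (and best allele split) minimizing a combined RDR/BAF
# distance; returns the summed weighted cost and the implied totals.
scale_objective <- function(rdr, baf, snp_total, lens, s, max_cn = 8L,
                            baf_weight = 2, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_scale_ctx(baf, snp_total, lens, max_cn,
                                          baf_weight)
  t_hat <- s * rdr
  rd <- (outer(t_hat, ctx$cand, "-"))^2
  cost_mat <- rd * ctx$w_len + ctx$baf_part
  j_best <- max.col(-cost_mat, ties.method = "first")
  list(cost = sum(cost_mat[cbind(seq_len(ctx$nb), j_best)]),
       totals = ctx$cand[j_best])
}

#' Fit the depth-to-copies scale of one cell
#'
#' Finds the factor \code{s} such that \code{s * rdr} sits on integer total
#' copy numbers consistent with the observed BAFs. Candidate scales come
#' from a grid of plausible ploidies (the scale that maps a cell's RDR onto
#' its true totals equals its ploidy); each candidate is scored by the
#' summed per-bin distance between \code{s * rdr} and the nearest integer
#' total achievable given the bin's BAF, weighted by bin length and SNP
#' depth. Ties are broken toward the lowest implied ploidy. The winning
#' scale is then refined by two rounds of weighted least squares against
#' its own integer assignment, which recovers scales between grid points.
#'
#' @param signals A \code{cell_signals} object (single cell: supply
#'   \code{cell} index) or vectors via the \code{rdr}/\code{baf} arguments.
#' @param cell Column index or cell id within \code{signals}.
#' @param ploidy_grid Candidate ploidies (default 1.5 to 4 by 0.5).
#' @param max_cn Per-bin total copy-number cap.
#' @return The fitted scale (numeric scalar) with attribute
#'   \code{"ploidy_pick"}, the winning grid point.
#' @export
fit_scale <- function(signals, cell = 1L,
                      ploidy_grid = c(1.5, 2, 2.5, 3, 3.5, 4),
                      max_cn = 8L) {
  if (length(ploidy_grid) == 0L || any(ploidy_grid <= 0))
    stop("ploidy_grid must be non-empty and positive")
  rdr <- signals$rdr[, cell]
  baf <- signals$baf[, cell]
  snp <- signals$snp_total[, cell]
  lens <- bin_lengths(signals$bins)
  if (all(is.na(baf))) {
    # rdr-only fallback
    baf_use <- rep(NA_real_, length(rdr))
    message("fit_scale: all BAFs missing; using RDR-only objective")
  } else baf_use <- baf

  if (sum(lens * rdr) <= 0) stop("degenerate cell: non-positive mean RDR")
  grid <- sort(ploidy_grid)
  # each grid candidate is refined by least squares against its own integer
  # assignment before scoring: the scale that maps RDR onto true totals is
  # the cell's exact ploidy, which can fall between grid points, and
  # without refinement a doubled solution (2x the true ploidy, which sits
  # near the even grid) would outscore the true one
  ctx <- make_scale_ctx(baf_use, snp, lens, max_cn)
  refine <- function(s) {
    for (it in 1:2) {
      tot <- scale_objective(rdr, baf_use, snp, lens, s, max_cn, ctx = ctx)$totals
      denom <- sum(lens * rdr^2)
      if (denom > 0 && sum(tot) > 0) s <- sum(lens * tot * rdr) / denom
    }
    s
  }
  scales <- vapply(grid, refine, numeric(1))
  fits <- lapply(scales, function(s)
    scale_objective(rdr, baf_use, snp, lens, s, max_cn, ctx = ctx))
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  implied <- vapply(fits, function(f) sum(lens * f$totals) / sum(lens),
                    numeric(1))
  tied <- which(costs <= min(costs) * (1 + 1e-6) + 1e-9)
  best <- tied[order(implied[tied], grid[tied])][1L]  # tie -> lowest implied ploidy
  structure(scales[best], ploidy_pick = grid[best])
}

#' Call one cell's haplotype-specific copy numbers
#'
#' Per bin: total copy number \code{t = round(scale * rdr)} clipped to
#' \code{[0, max_cn]}; the allele split (cnA, cnB) is the pair summing to
#' \code{t} whose implied B fraction \code{cnB/t} is closest to the
#' observed BAF. Bins with missing BAF get the most balanced split; ties go
#' to \code{cnA >= cnB}. cnB always refers to the phased B haplotype, so
#' calls are haplotype-consistent across bins and cells.
#'
#' @param signals A \code{cell_signals} object.
#' @param scale Fitted depth-to-copies factor (see \code{\link{fit_scale}}).
#' @param cell Column index or id.
#' @param max_cn Total copy-number cap (default 8).
#' @param min_baf_reads Minimum SNP reads in a bin before its BAF is
#'   trusted for an unbalanced allele split; sparser bins get the
#'   balanced split. Default NULL: a fifth of the cell's median positive
#'   SNP depth, floored at 5 (below that, a balanced bin shows an extreme
#'   BAF by sampling noise alone often enough to fake LOH). The relative
#'   rule keeps calls invariant under rescaling all counts.
#' @return A \code{cell_profile}: list with \code{cn} (bins x 2 integer
#'   matrix, columns A and B), \code{ploidy} (length-weighted mean total),
#'   \code{scale} and \code{cell_id}.
#' @export
call_cell <- function(signals, scale, cell = 1L, max_cn = 8L,
                      min_baf_reads = NULL) {
  stopifnot(scale > 0)
  rdr <- signals$rdr[, cell]
  baf <- signals$baf[, cell]
  if (!is.null(signals$snp_total)) {
    snp <- signals$snp_total[, cell]
    if (is.null(min_baf_reads))
      min_baf_reads <- max(5, 0.2 * stats::median(snp[snp > 0]))
    baf[snp < min_baf_reads] <- NA_real_
  }
  nb <- length(rdr)
  tot <- pmin(pmax(round(scale * rdr), 0), max_cn)
  clipped <- sum(round(scale * rdr) > max_cn)
  if (clipped > 0)
    message(sprintf("call_cell: clipped %d bin(s) at max_cn=%d", clipped, max_cn))
  cn <- matrix(0L, nb, 2, dimnames = list(NULL, c("A", "B")))
  for (i in seq_len(nb)) {
    t <- tot[i]
    if (t == 0) next
    if (is.na(baf[i])) {
      cn[i, "B"] <- as.integer(floor(t / 2)); cn[i, "A"] <- as.integer(ceiling(t / 2))
    } else {
      bs <- 0:t
      d <- abs(bs / t - baf[i])
      b <- bs[which(d <= min(d) + 1e-12)][1L]  # tie -> smaller cnB (cnA >= cnB)
      cn[i, "B"] <- as.integer(b); cn[i, "A"] <- as.integer(t - b)
    }
  }
  lens <- bin_lengths(signals$bins)
  structure(list(cell_id = if (is.numeric(cell)) signals$cell_ids[cell] else cell,
                 cn = cn,
                 ploidy = sum(lens * (cn[, 1] + cn[, 2])) / sum(lens),
                 scale = as.numeric(scale)),
            class = "cell_profile")
}

#' Call all cells in a signal set
#'
#' Convenience wrapper: fits a scale and calls copy numbers for every cell,
#' returning the calls in matrix form for the clone stage.
#'
#' @inheritParams fit_scale
#' @inheritParams call_cell
#' @return A \code{cell_cn} object: \code{cnA}, \code{cnB} (bins x cells
#'   integer matrices), \code{ploidy}, \code{scale} vectors, the bin grid
#'   and cell ids (plus truth labels when the signals carry them).
#' @export
call_cells <- function(signals, ploidy_grid = c(1.5, 2, 2.5, 3, 3.5, 4),
                       max_cn = 8L, min_baf_reads = NULL) {
  nc <- length(signals$cell_ids)
  nb <- n_bins(signals$bins)
  cnA <- cnB <- matrix(0L, nb, nc, dimnames = list(NULL, signals$cell_ids))
  ploidy <- scale <- numeric(nc)
  for (j in seq_len(nc)) {
    s <- suppressMessages(fit_scale(signals, j, ploidy_grid, max_cn))
    prof <- suppressMessages(call_cell(signals, s, j, max_cn, min_baf_reads))
    cnA[, j] <- prof$cn[, "A"]; cnB[, j] <- prof$cn[, "B"]
    ploidy[j] <- prof$ploidy; scale[j] <- prof$scale
  }
  structure(list(bins = signals$bins, cell_ids = signals$cell_ids,
                 cnA = cnA, cnB = cnB, ploidy = ploidy, scale = scale,
                 true_clone = signals$true_clone),
            class = "cell_cn")
}

#' @export
print.cell_cn <- function(x, ...) {
  cat(sprintf("cell_cn: %d cells x %d bins; ploidy %.2f-%.2f\n",
              length(x$cell_ids), n_bins(x$bins),
              min(x$ploidy), max(x$ploidy)))
  invisible(x)
}

# extract one cell's profile matrix from a cell_cn
profile_of <- function(calls, j) {
  cbind(A = calls$cnA[, j], B = calls$cnB[, j])
}
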