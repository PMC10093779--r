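# Cross-sample SCNA comparison: identical-window concordance between
# primary-clone profiles, fine-binned median copy number from segment
# tables, the Pearson correlation matrix, and correlation-based sample
# grouping.

#' Identical-window concordance between two clone profiles
#'
#' Restricted to bins where at least one profile is aberrant (relative to
#' its own doubling baseline), the proportion of bins whose unordered
#' allele-specific pairs are equal. When exactly one of the pair is
#' whole-genome doubled, the doubled profile is halved (rounded) before
#' comparison, so a diagnosis/relapse pair differing only by a doubling
#' scores as concordant.
#'
#' @param a,b bins x 2 profiles (or objects carrying \code{cn}).
#' @param bins Shared bin grid.
#' @param wgd_a,wgd_b Doubling flags of the two samples.
#' @param normalize_wgd Halve the doubled profile when flags differ
#'   (default TRUE).
#' @return List: \code{prop_identical} (NA when no window qualifies),
#'   \code{n_windows_considered}, \code{defined}.
#' @export
window_concordance <- function(a, b, bins, wgd_a = FALSE, wgd_b = FALSE,
                               normalize_wgd = TRUE) {
  pa <- as_profile_matrix(a); pb <- as_profile_matrix(b)
  if (nrow(pa) != n_bins(bins) || nrow(pb) != n_bins(bins))
    stop("bin grids do not match")
  base_a <- wgd_a; base_b <- wgd_b
  if (normalize_wgd && xor(wgd_a, wgd_b)) {
    if (wgd_a) { pa <- matrix(as.integer(floor(pa / 2 + 0.5)), ncol = 2,
                              dimnames = dimnames(pa)); base_a <- FALSE }
    else { pb <- matrix(as.integer(floor(pb / 2 + 0.5)), ncol = 2,
                        dimnames = dimnames(pb)); base_b <- FALSE }
  }
  ba <- if (base_a) 2L else 1L
  bb <- if (base_b) 2L else 1L
  ab_a <- !(pa[, 1] == ba & pa[, 2] == ba)
  ab_b <- !(pb[, 1] == bb & pb[, 2] == bb)
  win <- which(ab_a | ab_b)
  if (length(win) == 0L)
    return(list(prop_identical = NA_real_, n_windows_considered = 0L,
                defined = FALSE))
  same <- (pmin(pa[win, 1], pa[win, 2]) == pmin(pb[win, 1], pb[win, 2])) &
    (pmax(pa[win, 1], pa[win, 2]) == pmax(pb[win, 1], pb[win, 2]))
  list(prop_identical = mean(same), n_windows_considered = length(win),
       defined = TRUE)
}

#' Bin a segment table to median copy number
#'
#' Converts a BED-like segment table (one sample's copy-number calls) to a
#' per-bin vector of median total copy number over fine non-overlapping
#' windows (1,000 bp by default): per window, the overlap-weighted median
#' of the covering segments' copy numbers (the midpoint of the two
#' straddling values at an exact 50/50 split); windows with no coverage
#' are missing.
#'
#' @param segments data.frame with \code{chrom}, \code{start}, \code{end}
#'   (bp, 0-based half-open) and \code{total_cn}.
#' @param bins A \code{genome_bins} grid (typically
#'   \code{make_bins(..., bin_size = 1000)}).
#' @return Numeric vector, one value per bin, NA where uncovered.
#' @export
binned_median_cn <- function(segments, bins) {
  stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(segments)))
  out <- rep(NA_real_, n_bins(bins))
  bs <- attr(bins, "bin_size")
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop(sprintf("overlapping segments on %s", ch))
    bidx <- which(bins$chrom == ch)
    if (!length(bidx)) stop(sprintf("segment chromosome %s not in bin grid", ch))
    b_start <- bins$start[bidx]; b_end <- bins$end[bidx]
    if (any(seg$end > b_end[length(b_end)]))
      stop(sprintf("segment beyond chromosome end on %s", ch))
    # boundary contributions (partially covered bins)
    bb_idx <- integer(0); bb_val <- numeric(0); bb_w <- numeric(0)
    for (k in seq_len(nrow(seg))) {
      j0 <- floor(seg$start[k] / bs) + 1L
      j1 <- min(ceiling(seg$end[k] / bs), length(bidx))
      full_lo <- if (seg$start[k] == b_start[j0]) j0 else j0 + 1L
      full_hi <- if (seg$end[k] == b_end[j1]) j1 else j1 - 1L
      if (full_lo <= full_hi)
        out[bidx[full_lo:full_hi]] <- seg$total_cn[k]
      part <- setdiff(c(j0, j1), if (full_lo <= full_hi) full_lo:full_hi else integer(0))
      for (j in unique(part)) {
        w <- min(b_end[j], seg$end[k]) - max(b_start[j], seg$start[k])
        if (w > 0) {
          bb_idx <- c(bb_idx, j); bb_val <- c(bb_val, seg$total_cn[k])
          bb_w <- c(bb_w, w)
        }
      }
    }
    for (j in unique(bb_idx)) {
      sel <- bb_idx == j
      out[bidx[j]] <- weighted_median_mid(bb_val[sel], bb_w[sel])
    }
  }
  out
}

# weighted median returning the midpoint of the two straddling values when
# the 50% mass point falls exactly on a boundary
weighted_median_mid <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2
  else x[i]
}

#' Pearson correlation matrix of binned copy-number vectors
#'
#' Pairwise-complete Pearson correlation between samples' binned median
#' copy numbers (the R \code{cor} function underneath). Samples with zero
#' variance get missing correlations with a warning.
#'
#' @param mat Numeric matrix, bins x samples (NAs allowed), or a list of
#'   equal-length vectors.
#' @param min_complete Minimum pairwise-complete bins required (default
#'   100).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(mat, min_complete = 100L) {
  if (is.list(mat)) mat <- do.call(cbind, mat)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  ok <- !is.na(mat)
  for (i in seq_len(ncol(mat))) for (j in seq_len(ncol(mat)))
    if (i < j && sum(ok[, i] & ok[, j]) < min_complete)
      stop(sprintf("fewer than %d pairwise-complete bins for samples %d,%d",
                   min_complete, i, j))
  novar <- apply(mat, 2, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                   all(is.na(v)))
  r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  if (any(novar)) {
    warning(sprintf("%d sample(s) with zero variance: correlations set missing",
                    sum(novar)))
    r[novar, ] <- NA_real_; r[, novar] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Group samples by copy-number correlation
#'
#' Average-linkage hierarchical clustering on distance 1 - r, cut so that
#' samples join a group only when their merge distance is strictly below
#' \code{threshold} (thus threshold 0 keeps every sample separate).
#'
#' @param corr Correlation matrix from \code{\link{correlation_matrix}}.
#' @param threshold Distance cut in [0, 2].
#' @return List: \code{groups} (named integer vector, deterministic
#'   numbering by first member), \code{hclust} (the dendrogram, NULL for a
#'   single sample).
#' @export
cluster_samples <- function(corr, threshold = 0.5) {
  d <- 1 - corr
  if (any(is.na(d))) stop("correlation matrix contains missing values")
  n <- ncol(corr)
  if (n == 1L)
    return(list(groups = stats::setNames(1L, colnames(corr)), hclust = NULL))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = max(threshold - 1e-9, 0) )
  if (threshold <= 0) grp <- seq_len(n)
  # renumber deterministically by first appearance
  first <- match(unique(grp), grp)
  map <- stats::setNames(order(order(first)), unique(grp))
  grp <- unname(map[as.character(grp)])
  names(grp) <- colnames(corr)
  list(groups = grp, hclust = hc)
}

#' Correlation heatmap of samples
#'
#' Renders the correlation matrix as a clustered heatmap (pheatmap).
#' @param corr Correlation matrix.
#' @param ... Passed to \code{pheatmap::pheatmap}.
#' @return The pheatmap object, invisibly.
#' @export
plot_correlation_heatmap <- function(corr, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap not installed")
  invisible(pheatmap::pheatmap(corr, ...))
}

#' Clone profile to segment table
#'
#' Collapses runs of equal total copy number along each chromosome of a
#' clone profile into a BED-like segment table, the input format of the
#' bulk concordance path.
#'
#' @param profile bins x 2 profile.
#' @param bins Bin grid.
#' @return data.frame: chrom, start, end, total_cn, cnA, cnB.
#' @export
profile_to_segments <- function(profile, bins) {
  p <- as_profile_matrix(profile)
  out <- list()
  for (ch in attr(bins, "chrom_names")) {
    idx <- which(bins$chrom == ch)
    if (!length(idx)) next
    key <- paste(p[idx, 1], p[idx, 2])
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
    for (k in seq_along(r$lengths)) {
      i0 <- idx[starts[k]]; i1 <- idx[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = bins$start[i0], end = bins$end[i1],
        total_cn = p[i0, 1] + p[i0, 2], cnA = p[i0, 1], cnB = p[i0, 2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
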