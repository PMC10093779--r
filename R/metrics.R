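# WGD-aware heterogeneity metrics: fraction of aberrant genome, deletion /
# amplification fractions, subclonal-SCNA fraction and locus-level LOH
# status. Baselines follow the doubling state of the tumor: the expected
# state is {1,1} (one copy per allele) without whole-genome doubling and
# {2,2} with it.

as_profile_matrix <- function(profile) {
  if (inherits(profile, "cell_profile")) return(profile$cn)
  if (is.list(profile) && !is.null(profile$cn)) return(profile$cn)
  profile
}

#' Detect whole-genome doubling in a profile
#'
#' Flags a profile as doubled when more than \code{threshold} of the genome
#' (bin-length weighted) has both haplotypes at copy number >= 2. A profile
#' that is exactly twice a typical aneuploid non-doubled profile satisfies
#' this, while deletion-heavy non-doubled genomes do not.
#'
#' @param profile Cell or clone profile (bins x 2 matrix or an object
#'   carrying \code{cn}).
#' @param bins Bin grid.
#' @param threshold Genome fraction cut, default 0.5.
#' @return Logical scalar.
#' @export
detect_wgd <- function(profile, bins, threshold = 0.5) {
  p <- as_profile_matrix(profile)
  w <- bin_lengths(bins)
  both2 <- p[, 1] >= 2 & p[, 2] >= 2
  sum(w[both2]) / sum(w) > threshold
}

#' Fraction of aberrant genome
#'
#' Length-weighted fraction of bins whose unordered allele pair differs
#' from the expected baseline: \{1,1\} without WGD, \{2,2\} with WGD.
#'
#' @inheritParams detect_wgd
#' @param wgd Logical: is the tumor (or this profile) whole-genome doubled?
#' @return Fraction in [0, 1].
#' @export
aberrant_fraction <- function(profile, bins, wgd) {
  p <- as_profile_matrix(profile)
  w <- bin_lengths(bins)
  base <- if (wgd) 2L else 1L
  ab <- !(p[, 1] == base & p[, 2] == base)
  sum(w[ab]) / sum(w)
}

#' Deleted and amplified genome fractions
#'
#' A bin is deleted when either allele-specific copy number is below the
#' expected per-allele baseline (1 without WGD, 2 with WGD) and amplified
#' when either is above it. A bin can be both (e.g. (2,0) without WGD).
#'
#' @inheritParams aberrant_fraction
#' @return Named numeric vector \code{c(frac_deleted, frac_amplified)}.
#' @export
deletion_amplification_fractions <- function(profile, bins, wgd) {
  p <- as_profile_matrix(profile)
  w <- bin_lengths(bins)
  base <- if (wgd) 2L else 1L
  del <- p[, 1] < base | p[, 2] < base
  amp <- p[, 1] > base | p[, 2] > base
  c(frac_deleted = sum(w[del]) / sum(w),
    frac_amplified = sum(w[amp]) / sum(w))
}

#' Modal copy-number state per bin across a dataset
#'
#' The most common ordered (cnA, cnB) state in each bin across all cells;
#' the reference for the subclonal-SCNA fraction. Ties go to the smallest
#' encoded state for determinism.
#'
#' @param calls A \code{cell_cn} object.
#' @return bins x 2 integer matrix.
#' @export
modal_state <- function(calls) {
  code <- calls$cnA * 100L + calls$cnB
  nb <- nrow(code)
  m <- integer(nb)
  for (b in seq_len(nb)) {
    tab <- table(code[b, ])
    best <- as.integer(names(tab)[tab == max(tab)])
    m[b] <- min(best)
  }
  cbind(A = m %/% 100L, B = m %% 100L)
}

#' Subclonal-SCNA fraction of one cell
#'
#' Length-weighted fraction of the genome where the cell's ordered state
#' differs from the dataset's most common state for the same region.
#'
#' @param profile Cell profile (bins x 2) to score.
#' @param modal Modal state matrix from \code{\link{modal_state}}.
#' @param bins Bin grid.
#' @return Fraction in [0, 1].
#' @export
subclonal_fraction <- function(profile, modal, bins) {
  p <- as_profile_matrix(profile)
  if (nrow(p) != nrow(modal)) stop("bin grids do not match")
  w <- bin_lengths(bins)
  diff <- p[, 1] != modal[, 1] | p[, 2] != modal[, 2]
  sum(w[diff]) / sum(w)
}

#' Locus-level LOH status
#'
#' Classifies a genomic locus (e.g. TP53) from the length-weighted majority
#' state of the bins it overlaps: \code{loh} when one allele is completely
#' lost and the retained allele is below the expected baseline total,
#' \code{cn_loh} when one allele is lost but the retained allele is
#' amplified to at least the baseline total copy number (e.g. \{2,0\} in a
#' non-doubled tumor), else \code{no_loh}.
#'
#' @param profile Cell or clone profile.
#' @param locus List or vector with \code{chrom}, \code{start}, \code{end}
#'   (bp, 0-based half-open).
#' @param bins Bin grid.
#' @param wgd Logical doubling state (baseline total 2 without, 4 with).
#' @return List with \code{locus}, \code{status} and \code{cn_at_locus}.
#' @export
locus_status <- function(profile, locus, bins, wgd = FALSE) {
  p <- as_profile_matrix(profile)
  ov <- which(bins$chrom == locus$chrom &
                bins$start < locus$end & bins$end > locus$start)
  if (length(ov) == 0L) stop("locus outside the binned genome")
  w <- pmin(bins$end[ov], locus$end) - pmax(bins$start[ov], locus$start)
  code <- p[ov, 1] * 100L + p[ov, 2]
  wt <- tapply(w, code, sum)
  maj <- as.integer(names(wt)[which.max(wt)])
  cn <- c(maj %/% 100L, maj %% 100L)
  base_total <- if (wgd) 4L else 2L
  status <- if (min(cn) == 0L) {
    if (max(cn) >= base_total) "cn_loh" else "loh"
  } else "no_loh"
  list(locus = locus, status = status,
       cn_at_locus = c(cnA = cn[1], cnB = cn[2]))
}

#' Default TP53 locus (hg19)
#'
#' chr17:7,565,097-7,590,856 in 0-based half-open coordinates, for use with
#' full-scale hg19 bin grids.
#' @return List with chrom/start/end.
#' @export
tp53_locus <- function() list(chrom = "chr17", start = 7565097L, end = 7590856L)

#' Per-cell heterogeneity metrics table
#'
#' Computes ploidy, aberrant / deleted / amplified and subclonal genome
#' fractions and the doubling flag for every cell in a call set. The WGD
#' state is decided at the tumor level (majority of cells doubled) and
#' applied to all cells, with a per-cell override available for tumors
#' containing a doubled subclone.
#'
#' @param calls A \code{cell_cn} object.
#' @param wgd \code{"tumor"} (default: one flag for the whole dataset by
#'   majority vote of per-cell \code{\link{detect_wgd}}), \code{"cell"}
#'   (per-cell flags), or a logical scalar/vector forcing the flag.
#' @param wgd_threshold Genome-fraction cut for \code{\link{detect_wgd}}.
#' @return data.frame, one row per cell: \code{cell_id}, \code{ploidy},
#'   \code{frac_aberrant}, \code{frac_deleted}, \code{frac_amplified},
#'   \code{frac_subclonal}, \code{wgd}.
#' @export
cell_metrics <- function(calls, wgd = "tumor", wgd_threshold = 0.5) {
  nc <- length(calls$cell_ids)
  bins <- calls$bins
  percell <- vapply(seq_len(nc), function(j)
    detect_wgd(profile_of(calls, j), bins, wgd_threshold), logical(1))
  flags <- if (is.logical(wgd)) rep(wgd, length.out = nc)
  else if (identical(wgd, "cell")) percell
  else rep(mean(percell) > 0.5, nc)
  modal <- modal_state(calls)
  w <- bin_lengths(bins)
  rows <- lapply(seq_len(nc), function(j) {
    p <- profile_of(calls, j)
    da <- deletion_amplification_fractions(p, bins, flags[j])
    data.frame(cell_id = calls$cell_ids[j],
               ploidy = sum(w * (p[, 1] + p[, 2])) / sum(w),
               frac_aberrant = aberrant_fraction(p, bins, flags[j]),
               frac_deleted = unname(da["frac_deleted"]),
               frac_amplified = unname(da["frac_amplified"]),
               frac_subclonal = subclonal_fraction(p, modal, bins),
               wgd = flags[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fill clone-level WGD flags
#'
#' @param cloneset A \code{clone_set}.
#' @param threshold Genome-fraction cut for \code{\link{detect_wgd}}.
#' @return The clone_set with each clone's \code{wgd} flag set.
#' @export
flag_clone_wgd <- function(cloneset, threshold = 0.5) {
  for (id in names(cloneset$clones))
    cloneset$clones[[id]]$wgd <-
      detect_wgd(cloneset$clones[[id]]$cn, cloneset$bins, threshold)
  cloneset
}
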