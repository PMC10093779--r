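#' Build a binned genome coordinate system
#'
#' Tiles each chromosome with fixed-size, non-overlapping, contiguous bins
#' (0-based, half-open coordinates). The last bin of each chromosome may be
#' shorter than \code{bin_size}; every other bin has length exactly
#' \code{bin_size}. This grid is the shared coordinate system of all stages:
#' simulation, copy-number calling, clone metrics, phylogeny and concordance.
#'
#' @param chrom_lengths Named numeric vector (or list) of chromosome lengths
#'   in bp; names are chromosome identifiers and their order is kept.
#' @param bin_size Bin width in bp (> 0).
#' @return A \code{genome_bins} object: a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end} and attributes \code{bin_size}
#'   and \code{chrom_names}.
#' @examples
#' make_bins(c(chr1 = 11e6), bin_size = 5e6)  # 3 bins, last is 1 Mb
#' @export
make_bins <- function(chrom_lengths, bin_size) {
  chrom_lengths <- unlist(chrom_lengths)
  if (length(chrom_lengths) == 0L) stop("empty genome")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chromosome lengths must be named")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be > 0")

  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(bins,
            bin_size = bin_size,
            chrom_names = names(chrom_lengths),
            class = c("genome_bins", "data.frame"))
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins on %d chromosomes (bin size %s bp, %s bp total)\n",
              nrow(x), length(attr(x, "chrom_names")),
              format(attr(x, "bin_size"), big.mark = ","),
              format(sum(x$end - x$start), big.mark = ",")))
  invisible(x)
}

n_bins <- function(bins) nrow(bins)

bin_lengths <- function(bins) bins$end - bins$start

#' Default synthetic genome
#'
#' 22 synthetic autosomes with lengths proportional to the hg19 autosomes,
#' scaled to a configurable total size. Sex chromosomes are excluded. The
#' scaled-down default keeps simulations fast while preserving the relative
#' chromosome-arm geometry that interval events act on.
#'
#' @param total_bp Total genome size in bp after scaling (default 500 Mb).
#' @return Named numeric vector of chromosome lengths, chr1..chr22.
#' @export
default_genome <- function(total_bp = 5e8) {
  # hg19 autosome lengths (bp)
  hg19 <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
            159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
            115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
            59128983, 63025520, 48129895, 51304566)
  names(hg19) <- paste0("chr", 1:22)
  round(hg19 / sum(hg19) * total_bp)
}

#' hg19 autosome lengths
#'
#' Full-scale hg19 autosome lengths for runs on a realistic coordinate
#' system (with a correspondingly larger bin count).
#' @return Named numeric vector of lengths in bp, chr1..chr22.
#' @export
hg19_autosomes <- function() {
  hg19 <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
            159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
            115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
            59128983, 63025520, 48129895, 51304566)
  names(hg19) <- paste0("chr", 1:22)
  hg19
}

# per-chromosome global bin index ranges, as a named list of integer vectors
chrom_bin_index <- function(bins) {
  split(seq_len(nrow(bins)), factor(bins$chrom, levels = attr(bins, "chrom_names")))
}

stopifnot_same_bins <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
      !all(a$start == b$start) || !all(a$end == b$end))
    stop("bin grids do not match")
  invisible(TRUE)
}
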