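# Interval events and their application to haplotype-specific profiles.
#
# A profile is an integer matrix n_bins x 2 with columns "A" and "B": the
# copy number of the two parental haplotypes in each genome bin. An event
# record is one row of an event table:
#   kind      gain | del | loh | cn_loh | wgd (NA until classified)
#   haplotype "A" | "B" | "both" (wgd only)
#   chrom     chromosome of the interval (NA for wgd)
#   start_bin, end_bin   global bin indices, 0-based half-open (NA for wgd)
#   delta     +1 | -1 for interval events; NA for wgd

empty_events <- function() {
  data.frame(kind = character(0), haplotype = character(0),
             chrom = character(0), start_bin = integer(0),
             end_bin = integer(0), delta = integer(0),
             stringsAsFactors = FALSE)
}

event_row <- function(haplotype, chrom, start_bin, end_bin, delta,
                      kind = NA_character_) {
  data.frame(kind = kind, haplotype = haplotype, chrom = chrom,
             start_bin = as.integer(start_bin), end_bin = as.integer(end_bin),
             delta = as.integer(delta), stringsAsFactors = FALSE)
}

wgd_event <- function() {
  data.frame(kind = "wgd", haplotype = "both", chrom = NA_character_,
             start_bin = NA_integer_, end_bin = NA_integer_,
             delta = NA_integer_, stringsAsFactors = FALSE)
}

diploid_profile <- function(bins) {
  m <- matrix(1L, nrow = n_bins(bins), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  m
}

#' Apply interval events to a haplotype-specific profile
#'
#' Applies an ordered event table to a per-bin (cnA, cnB) profile. Interval
#' events add \code{delta} to one haplotype over a contiguous bin interval;
#' a \code{wgd} row doubles both haplotypes genome-wide. Loss of
#' heterozygosity is irreversible: a gain touching a bin whose target
#' haplotype is at copy number 0 is an error, as is any loss below 0.
#'
#' @param profile Integer matrix \code{n_bins x 2}, columns A and B.
#' @param events Event table (see \code{\link{interval_event_distance}}).
#' @return The transformed profile.
#' @export
apply_events <- function(profile, events) {
  if (nrow(events) == 0L) return(profile)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (identical(ev$haplotype, "both")) {
      profile <- profile * 2L
      next
    }
    idx <- (ev$start_bin + 1L):ev$end_bin  # 0-based half-open -> R indices
    hap <- ev$haplotype
    cur <- profile[idx, hap]
    if (ev$delta > 0L && any(cur == 0L))
      stop("invalid event: gain on a haplotype at copy number 0")
    if (ev$delta < 0L && any(cur + ev$delta < 0L))
      stop("invalid event: copy number below 0")
    profile[idx, hap] <- cur + ev$delta
  }
  profile
}

# Decompose a non-negative per-bin magnitude vector (one chromosome, one
# haplotype) into maximal constant-height-1 intervals: the classic
# "painting" decomposition whose interval count equals the sum of positive
# increments. Returns a list of c(start, end) local half-open bin intervals,
# one per unit event.
decompose_unit_intervals <- function(mag) {
  out <- list()
  maxh <- if (length(mag)) max(mag) else 0L
  if (maxh == 0L) return(out)
  for (h in seq_len(maxh)) {
    on <- mag >= h
    r <- rle(on)
    pos <- cumsum(c(0L, r$lengths))
    for (j in seq_along(r$values)) {
      if (r$values[j]) out[[length(out) + 1L]] <- c(pos[j], pos[j + 1L])
    }
  }
  out
}

# Count of unit interval events needed to realise a signed per-bin delta
# vector (one chromosome, one haplotype): losses and gains counted
# separately as sums of positive increments.
count_interval_events <- function(delta) {
  g <- pmax(delta, 0L)
  l <- pmax(-delta, 0L)
  sum(pmax(diff(c(0L, g)), 0L)) + sum(pmax(diff(c(0L, l)), 0L))
}

# Build the canonical event list realising child - parent on one chromosome
# and one haplotype (losses first, then gains), as global-bin event rows.
canonical_events <- function(parent_vec, child_vec, hap, chrom, bin_offset) {
  delta <- child_vec - parent_vec
  ev <- empty_events()
  for (iv in decompose_unit_intervals(pmax(-delta, 0L)))
    ev <- rbind(ev, event_row(hap, chrom, bin_offset + iv[1], bin_offset + iv[2], -1L))
  for (iv in decompose_unit_intervals(pmax(delta, 0L)))
    ev <- rbind(ev, event_row(hap, chrom, bin_offset + iv[1], bin_offset + iv[2], +1L))
  ev
}
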