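# Plain-text I/O: per-cell calls TSV (CHISEL-like dialect), clone profile
# TSV, BED-like segment tables, Newick trees with an edge-event sidecar,
# metrics TSV and YAML configs. Internal coordinates are 0-based half-open
# everywhere; 1-based inclusive input is accepted via `one_based = TRUE`.

read_tsv_checked <- function(path, required, one_based = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  if (all(c("start", "end") %in% names(df))) {
    if (one_based) df$start <- df$start - 1L
    bad <- which(df$start < 0 | df$end <= df$start)
    if (length(bad))
      stop(sprintf("%s: invalid coordinates at line %d (start %s, end %s)",
                   path, bad[1L] + 1L, df$start[bad[1L]], df$end[bad[1L]]))
  }
  df
}

#' Write per-cell copy-number calls
#'
#' Long-form TSV, one row per cell per bin, columns \code{chrom},
#' \code{start}, \code{end}, \code{cell_id}, \code{cn} (the string
#' "cnA|cnB") and \code{total_cn} — the dialect also accepted by
#' \code{\link{read_calls_tsv}} for externally produced calls.
#'
#' @param calls A \code{cell_cn} object.
#' @param path Output file.
#' @export
write_calls_tsv <- function(calls, path) {
  nb <- n_bins(calls$bins); nc <- length(calls$cell_ids)
  df <- data.frame(
    chrom = rep(calls$bins$chrom, nc),
    start = rep(calls$bins$start, nc),
    end = rep(calls$bins$end, nc),
    cell_id = rep(calls$cell_ids, each = nb),
    cn = paste0(as.vector(calls$cnA), "|", as.vector(calls$cnB)),
    total_cn = as.vector(calls$cnA + calls$cnB),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-cell copy-number calls
#'
#' Reads the dialect written by \code{\link{write_calls_tsv}} back into a
#' \code{cell_cn} object, reconstructing the bin grid from the coordinate
#' columns. Malformed rows produce line-numbered errors.
#'
#' @param path Input TSV.
#' @param one_based Input uses 1-based inclusive starts (converted).
#' @return A \code{cell_cn} object.
#' @export
read_calls_tsv <- function(path, one_based = FALSE) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "cell_id", "cn"),
                         one_based)
  cnpair <- strsplit(df$cn, "|", fixed = TRUE)
  bad <- which(lengths(cnpair) != 2L)
  if (length(bad))
    stop(sprintf("%s: malformed cn field at line %d", path, bad[1L] + 1L))
  cnA <- suppressWarnings(as.integer(vapply(cnpair, `[`, "", 1L)))
  cnB <- suppressWarnings(as.integer(vapply(cnpair, `[`, "", 2L)))
  if (anyNA(cnA) || anyNA(cnB) || any(cnA < 0) || any(cnB < 0))
    stop(sprintf("%s: non-integer or negative copy number at line %d",
                 path, which(is.na(cnA) | is.na(cnB) | cnA < 0 | cnB < 0)[1L] + 1L))
  ub <- unique(df[, c("chrom", "start", "end")])
  ub <- ub[order(match(ub$chrom, unique(df$chrom)), ub$start), ]
  sizes <- ub$end - ub$start
  bin_size <- as.numeric(names(sort(table(sizes), decreasing = TRUE))[1L])
  bins <- structure(data.frame(chrom = ub$chrom, start = ub$start,
                               end = ub$end, stringsAsFactors = FALSE),
                    bin_size = bin_size, chrom_names = unique(df$chrom),
                    class = c("genome_bins", "data.frame"))
  cells <- unique(df$cell_id)
  key <- paste(df$chrom, df$start)
  bkey <- paste(bins$chrom, bins$start)
  bi <- match(key, bkey); ci <- match(df$cell_id, cells)
  A <- B <- matrix(0L, nrow(bins), length(cells),
                   dimnames = list(NULL, cells))
  A[cbind(bi, ci)] <- cnA; B[cbind(bi, ci)] <- cnB
  w <- bin_lengths(bins)
  structure(list(bins = bins, cell_ids = cells, cnA = A, cnB = B,
                 ploidy = unname(colSums(w * (A + B)) / sum(w)),
                 scale = rep(NA_real_, length(cells)),
                 true_clone = NULL),
            class = "cell_cn")
}

#' Write clone consensus profiles
#'
#' TSV with columns chrom, start, end, clone_id, cnA, cnB, total_cn.
#' @param cloneset A \code{clone_set}.
#' @param path Output file.
#' @export
write_clones_tsv <- function(cloneset, path) {
  bins <- cloneset$bins
  rows <- lapply(cloneset$clones, function(cl)
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               clone_id = cl$clone_id, cnA = cl$cn[, 1], cnB = cl$cn[, 2],
               total_cn = cl$cn[, 1] + cl$cn[, 2], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write / read BED-like segment tables
#'
#' Columns chrom, start, end, total_cn (cnA/cnB kept when present).
#' @param segments Segment data.frame.
#' @param path File path.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_segments_tsv
#' @param one_based Input is 1-based inclusive.
#' @export
read_segments_tsv <- function(path, one_based = FALSE) {
  read_tsv_checked(path, c("chrom", "start", "end", "total_cn"), one_based)
}

#' Write cell-to-clone assignments
#' @param cloneset A \code{clone_set}.
#' @param path Output file.
#' @export
write_assignments_tsv <- function(cloneset, path) {
  utils::write.table(
    data.frame(cell_id = names(cloneset$labels),
               clone_id = unname(cloneset$labels), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a copy-number tree
#'
#' Newick (internal node labels, branch lengths = event counts) plus a
#' sidecar TSV of per-edge events with bp coordinates and classification.
#'
#' @param tree A \code{cn_tree}.
#' @param newick_path Newick output file.
#' @param events_path Optional sidecar events TSV.
#' @export
write_tree <- function(tree, newick_path, events_path = NULL) {
  # recursive serialisation: copy-number trees can contain unary internal
  # clone nodes (a clone ancestral to another clone), which the standard
  # binary-tree containers will not hold
  writeLines(newick_string(tree), newick_path)
  if (!is.null(events_path)) {
    bins <- tree$bins
    rows <- lapply(names(tree$edge_events), function(ch) {
      ev <- tree$edge_events[[ch]]
      if (nrow(ev) == 0L) return(NULL)
      par <- tree$edges$parent[tree$edges$child == ch]
      kind <- if (all(is.na(ev$kind)))
        classify_events(ev, tree$nodes[[par]], bins)$kind else ev$kind
      data.frame(parent = par, child = ch, kind = kind,
                 haplotype = ev$haplotype,
                 chrom = ifelse(is.na(ev$chrom), ".", ev$chrom),
                 start = ifelse(is.na(ev$start_bin), -1L,
                                bins$start[ev$start_bin + 1L]),
                 end = ifelse(is.na(ev$end_bin), -1L, bins$end[ev$end_bin]),
                 delta = ifelse(is.na(ev$delta), 0L, ev$delta),
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows), events_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(tree)
}

#' Write per-cell metrics
#' @param metrics data.frame from \code{\link{cell_metrics}}.
#' @param path Output file.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
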