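# Clone identification: group cells by copy-number similarity, exclude
# noisy cells, and build consensus clone profiles.

#' Length-weighted copy-number distance between two cells
#'
#' Fraction of the genome (bin-length weighted) where the ordered
#' haplotype-specific pairs (cnA, cnB) of two profiles differ. Symmetric,
#' in [0, 1], zero iff identical. (2,0) vs (0,2) counts as different:
#' haplotypes are phased, so the ordered pair is the state.
#'
#' @param a,b \code{cell_profile} objects, or bins x 2 integer matrices.
#' @param bins The shared bin grid (required when matrices are supplied).
#' @return Numeric scalar in [0, 1].
#' @export
cell_distance <- function(a, b, bins = NULL) {
  if (inherits(a, "cell_profile")) { pa <- a$cn } else pa <- a
  if (inherits(b, "cell_profile")) { pb <- b$cn } else pb <- b
  if (is.null(bins)) stop("bins required")
  if (nrow(pa) != n_bins(bins) || nrow(pb) != n_bins(bins))
    stop("bin grids do not match")
  w <- bin_lengths(bins)
  diff <- pa[, 1] != pb[, 1] | pa[, 2] != pb[, 2]
  sum(w[diff]) / sum(w)
}

# All-pairs distance matrix over a cell_cn object, via one-hot state
# encoding (fast for thousands of cells).
pairwise_cell_distance <- function(calls) {
  w <- bin_lengths(calls$bins)
  code <- calls$cnA * 100L + calls$cnB
  vals <- sort(unique(as.vector(code)))
  agree <- 0
  for (v in vals) {
    M <- (code == v) * 1
    agree <- agree + crossprod(M, w * M)
  }
  D <- 1 - agree / sum(w)
  D[D < 0] <- 0
  dimnames(D) <- list(calls$cell_ids, calls$cell_ids)
  D
}

# modal (cnA,cnB) state per bin among member columns; ties resolved toward
# the state of the medoid member (the cell minimizing total distance to the
# other members).
consensus_profile <- function(calls, members, D = NULL) {
  code <- calls$cnA[, members, drop = FALSE] * 100L +
    calls$cnB[, members, drop = FALSE]
  medoid <- if (length(members) == 1L) 1L else {
    Dm <- if (is.null(D)) pairwise_cell_distance(
      structure(list(bins = calls$bins,
                     cnA = calls$cnA[, members, drop = FALSE],
                     cnB = calls$cnB[, members, drop = FALSE],
                     cell_ids = calls$cell_ids[members]), class = "cell_cn"))
    else D[members, members, drop = FALSE]
    which.min(rowSums(Dm))
  }
  nb <- nrow(code)
  cons <- integer(nb)
  for (b in seq_len(nb)) {
    tab <- table(code[b, ])
    best <- as.integer(names(tab)[tab == max(tab)])
    cons[b] <- if (length(best) == 1L) best else {
      med_state <- code[b, medoid]
      if (med_state %in% best) med_state else min(best)
    }
  }
  cbind(A = cons %/% 100L, B = cons %% 100L)
}

#' Group cells into clones
#'
#' Average-linkage agglomerative clustering on the length-weighted
#' copy-number distance, cut at \code{error_rate} (the expected fraction of
#' the genome a cell may disagree with its clone by, default 0.12).
#' Clusters smaller than \code{min_clone_size} are dissolved to NOISY;
#' consensus profiles are built from the remaining clusters; one
#' reassignment pass returns any NOISY cell lying within \code{error_rate}
#' of a consensus to that clone. Cells are processed in sorted-id order so
#' the result is invariant to input order.
#'
#' @param calls A \code{cell_cn} object.
#' @param error_rate Distance cut (fraction of genome), default 0.12.
#' @param min_clone_size Minimum cells per clone; default
#'   \code{max(5, 1\% of cells)}.
#' @param method \code{"hclust"} (default) or \code{"kmedoids"}
#'   (partitioning around medoids with silhouette-selected k).
#' @return A \code{clone_set}: \code{labels} (named cell -> clone id or
#'   "NOISY"), \code{clones} (list with \code{clone_id}, consensus
#'   \code{cn}, \code{n_cells}, \code{wgd} placeholder), the bin grid and
#'   parameters.
#' @export
identify_clones <- function(calls, error_rate = 0.12, min_clone_size = NULL,
                            method = c("hclust", "kmedoids")) {
  method <- match.arg(method)
  nc <- length(calls$cell_ids)
  stopifnot(nc >= 1)
  if (is.null(min_clone_size)) min_clone_size <- max(5L, ceiling(0.01 * nc))

  ord <- order(calls$cell_ids)
  calls_s <- structure(list(bins = calls$bins,
                            cell_ids = calls$cell_ids[ord],
                            cnA = calls$cnA[, ord, drop = FALSE],
                            cnB = calls$cnB[, ord, drop = FALSE]),
                       class = "cell_cn")
  D <- pairwise_cell_distance(calls_s)

  if (nc == 1L) {
    grp <- 1L
  } else if (method == "hclust") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    grp <- stats::cutree(hc, h = error_rate)
  } else {
    if (!requireNamespace("cluster", quietly = TRUE))
      stop("the kmedoids method needs the cluster package")
    kmax <- min(8L, nc - 1L)
    best_k <- 1L; best_sil <- -Inf; best_fit <- NULL
    for (k in 2:max(2L, kmax)) {
      fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
      sil <- fit$silinfo$avg.width
      if (!is.null(sil) && sil > best_sil) {
        best_sil <- sil; best_k <- k; best_fit <- fit
      }
    }
    grp <- if (is.null(best_fit)) rep(1L, nc) else best_fit$clustering
  }

  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_clone_size]
  # deterministic clone numbering: by decreasing size, then first member
  keep <- keep[order(-sizes[keep], vapply(keep, function(g)
    which(grp == g)[1L], integer(1)))]
  labels <- rep("NOISY", nc)
  names(labels) <- calls_s$cell_ids
  clones <- list()
  for (ci in seq_along(keep)) {
    members <- which(grp == keep[ci])
    id <- paste0("clone", ci)
    labels[members] <- id
    clones[[id]] <- list(clone_id = id,
                         cn = consensus_profile(calls_s, members, D),
                         n_cells = length(members), wgd = NA)
  }

  # one reassignment pass for noisy cells near a consensus
  noisy <- which(labels == "NOISY")
  if (length(noisy) && length(clones)) {
    for (i in noisy) {
      prof <- cbind(A = calls_s$cnA[, i], B = calls_s$cnB[, i])
      d <- vapply(clones, function(cl)
        cell_distance(prof, cl$cn, bins = calls_s$bins), numeric(1))
      if (min(d) <= error_rate) {
        id <- names(clones)[which.min(d)]
        labels[i] <- id
        clones[[id]]$n_cells <- clones[[id]]$n_cells + 1L
      }
    }
  }

  structure(list(labels = labels, clones = clones, bins = calls$bins,
                 error_rate = error_rate, min_clone_size = min_clone_size),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set: %d clones, %d cells (%d noisy); error_rate %.2f\n",
              length(x$clones), length(x$labels),
              sum(x$labels == "NOISY"), x$error_rate))
  for (cl in x$clones)
    cat(sprintf("  %s: %d cells\n", cl$clone_id, cl$n_cells))
  invisible(x)
}

#' Audit noisy cells against the identified clones
#'
#' For every cell excluded as NOISY, reports the nearest clone consensus
#' and the distance to it. Supports the control analysis that no coherent
#' rare clone was discarded by the noise filter: genuinely noisy cells sit
#' far (beyond \code{error_rate}) from every consensus, while an excluded
#' coherent subclone would appear as a block of cells at small distance
#' from each other but not from any clone.
#'
#' @param cloneset A \code{clone_set}.
#' @param calls The \code{cell_cn} the clones were built from.
#' @return data.frame with columns \code{cell_id}, \code{nearest_clone},
#'   \code{distance}; zero rows if there are no noisy cells.
#' @export
noisy_cell_audit <- function(cloneset, calls) {
  noisy_ids <- names(cloneset$labels)[cloneset$labels == "NOISY"]
  if (length(noisy_ids) == 0L || length(cloneset$clones) == 0L)
    return(data.frame(cell_id = character(0), nearest_clone = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- lapply(noisy_ids, function(id) {
    j <- match(id, calls$cell_ids)
    prof <- cbind(A = calls$cnA[, j], B = calls$cnB[, j])
    d <- vapply(cloneset$clones, function(cl)
      cell_distance(prof, cl$cn, bins = calls$bins), numeric(1))
    data.frame(cell_id = id, nearest_clone = names(d)[which.min(d)],
               distance = min(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
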