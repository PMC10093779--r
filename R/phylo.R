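# Maximum-parsimony interval-event phylogeny of clone consensus profiles.
#
# The parsimony unit is the interval event: +/-1 copy of one haplotype over
# a contiguous bin interval of one chromosome. A whole-genome doubling
# (x2 on both haplotypes of every bin) costs one event and may occur at
# most once per root path. Loss of heterozygosity is irreversible: a
# haplotype at copy number 0 can never be regained.

# minimal events for a signed delta vector; NA if infeasible handled upstream
event_count_vec <- function(pv, cv) {
  if (any(pv == 0L & cv > 0L)) return(NA_integer_)
  count_interval_events(cv - pv)
}

# DP for the doubled edge: minimize events(p -> q) + events(2q -> c) over
# the intermediate (pre-doubling) profile q, one chromosome one haplotype.
# Returns list(count, q) or NULL if infeasible.
wgd_edge_dp <- function(pv, cv) {
  nb <- length(pv)
  Q <- max(pv, ceiling(max(cv) / 2)) + 1L
  states <- 0:Q
  ok <- function(i, q) {
    if (q == 0L && cv[i] > 0L) return(FALSE)  # post-doubling regain
    if (pv[i] == 0L && q > 0L) return(FALSE)  # pre-doubling regain
    TRUE
  }
  # per-position deltas as functions of q
  inc_cost <- function(prev, cur) max(0L, cur - prev)
  step_cost <- function(i, qprev, q, first) {
    ga <- max(q - pv[i], 0L); la <- max(pv[i] - q, 0L)
    gb <- max(cv[i] - 2L * q, 0L); lb <- max(2L * q - cv[i], 0L)
    if (first) return(ga + la + gb + lb)
    pga <- max(qprev - pv[i - 1L], 0L); pla <- max(pv[i - 1L] - qprev, 0L)
    pgb <- max(cv[i - 1L] - 2L * qprev, 0L); plb <- max(2L * qprev - cv[i - 1L], 0L)
    inc_cost(pga, ga) + inc_cost(pla, la) + inc_cost(pgb, gb) + inc_cost(plb, lb)
  }
  INF <- .Machine$integer.max %/% 4L
  cost <- rep(INF, Q + 1L)
  back <- matrix(NA_integer_, nb, Q + 1L)
  for (q in states) if (ok(1L, q)) cost[q + 1L] <- step_cost(1L, NA, q, TRUE)
  if (nb > 1L) for (i in 2:nb) {
    newc <- rep(INF, Q + 1L)
    for (q in states) {
      if (!ok(i, q)) next
      best <- INF; barg <- NA_integer_
      for (qp in states) {
        if (cost[qp + 1L] >= INF) next
        v <- cost[qp + 1L] + step_cost(i, qp, q, FALSE)
        if (v < best) { best <- v; barg <- qp }
      }
      newc[q + 1L] <- best
      back[i, q + 1L] <- barg
    }
    cost <- newc
  }
  if (all(cost >= INF)) return(NULL)
  qlast <- which.min(cost) - 1L
  q <- integer(nb); q[nb] <- qlast
  if (nb > 1L) for (i in nb:2) q[i - 1L] <- back[i, q[i] + 1L]
  list(count = min(cost), q = q)
}

sort_events <- function(ev, chrom_names) {
  if (nrow(ev) == 0L) return(ev)
  o <- order(is.na(ev$chrom),
             match(ev$chrom, chrom_names), ev$start_bin,
             ev$haplotype, ev$delta)
  ev[o, , drop = FALSE]
}

#' Minimal interval-event distance between two profiles
#'
#' Counts the minimal number of contiguous-interval +/-1 events per
#' haplotype (plus at most one whole-genome doubling when
#' \code{allow_wgd}) transforming \code{parent} into \code{child}, under
#' LOH irreversibility. Without doubling the minimum is the classic
#' segment recurrence: per chromosome and haplotype, the sum over
#' positions of the positive increments of the needed per-bin change,
#' losses and gains counted separately. With doubling, the pre-doubling
#' profile is optimized exactly by a small dynamic program per chromosome
#' and haplotype. Also returns one optimal event list (canonical order:
#' chromosome, start, haplotype) whose replay maps parent to child.
#'
#' @param parent,child bins x 2 integer matrices (columns A, B) or objects
#'   carrying \code{cn}.
#' @param bins Bin grid shared by both profiles.
#' @param allow_wgd Consider a single doubling event on this edge.
#' @return List: \code{count} (integer), \code{events} (event table),
#'   \code{wgd} (logical: does the optimum use a doubling).
#' @export
interval_event_distance <- function(parent, child, bins, allow_wgd = FALSE) {
  p <- as_profile_matrix(parent); cc <- as_profile_matrix(child)
  if (nrow(p) != n_bins(bins) || nrow(cc) != n_bins(bins))
    stop("bin grids do not match")
  cbi <- chrom_bin_index(bins)
  chroms <- attr(bins, "chrom_names")

  plain <- function() {
    if (any(p == 0L & cc > 0L)) return(NULL)
    total <- 0L; evs <- empty_events()
    for (ch in chroms) {
      idx <- cbi[[ch]]
      for (hap in c("A", "B")) {
        pv <- p[idx, hap]; cv <- cc[idx, hap]
        total <- total + count_interval_events(cv - pv)
        evs <- rbind(evs, canonical_events(pv, cv, hap, ch, idx[1L] - 1L))
      }
    }
    list(count = total, events = sort_events(evs, chroms), wgd = FALSE)
  }

  doubled <- function() {
    total <- 1L; pre <- empty_events(); post <- empty_events()
    for (ch in chroms) {
      idx <- cbi[[ch]]
      for (hap in c("A", "B")) {
        pv <- p[idx, hap]; cv <- cc[idx, hap]
        dp <- wgd_edge_dp(pv, cv)
        if (is.null(dp)) return(NULL)
        total <- total + dp$count
        pre <- rbind(pre, canonical_events(pv, dp$q, hap, ch, idx[1L] - 1L))
        post <- rbind(post, canonical_events(2L * dp$q, cv, hap, ch, idx[1L] - 1L))
      }
    }
    list(count = total,
         events = rbind(sort_events(pre, chroms), wgd_event(),
                        sort_events(post, chroms)),
         wgd = TRUE)
  }

  r0 <- plain()
  r1 <- if (allow_wgd) doubled() else NULL
  if (is.null(r0) && is.null(r1)) stop("no valid event path")
  if (is.null(r1)) return(r0)
  if (is.null(r0)) return(r1)
  if (r1$count < r0$count) r1 else r0
}

# ---- tree reconstruction ----------------------------------------------

# all rooted binary leaf-labelled topologies on leaves 1..n, as nested
# lists (a leaf is an integer, an internal node a list of two subtrees);
# enumeration order is deterministic.
enumerate_topologies <- function(n) {
  trees <- list(1L)
  if (n == 1L) return(trees)
  for (k in 2:n) {
    trees <- unlist(lapply(trees, insert_leaf, k = k), recursive = FALSE)
  }
  trees
}

insert_leaf <- function(t, k) {
  out <- list(list(t, k))  # new root above t
  if (is.list(t)) {
    for (nl in insert_leaf(t[[1]], k)) out[[length(out) + 1L]] <- list(nl, t[[2]])
    for (nr in insert_leaf(t[[2]], k)) out[[length(out) + 1L]] <- list(t[[1]], nr)
  }
  out
}

# Assign ancestor profiles on one topology by a per-bin per-haplotype
# Sankoff pass with linear |a-b| cost, candidates restricted to the
# descendant min..max range (0 excluded whenever any descendant is > 0,
# for LOH irreversibility), rooted at the diploid profile.
assign_ancestors <- function(topo, leaf_profiles, nb) {
  M <- max(2L, max(vapply(leaf_profiles, max, integer(1)))) + 1L
  vals <- 0:M
  BIG <- 1e9
  Dab <- abs(outer(vals, vals, "-"))
  # recursive bottom-up: returns list(cost = (2*nb) x (M+1) matrix,
  # lo, hi = per-position candidate bounds, node list for top-down)
  up <- function(t) {
    if (!is.list(t)) {
      prof <- leaf_profiles[[t]]
      v <- c(prof[, "A"], prof[, "B"])
      cost <- matrix(BIG, length(v), M + 1L)
      cost[cbind(seq_along(v), v + 1L)] <- 0
      return(list(leaf = t, v = v, cost = cost, lo = v, hi = v))
    }
    L <- up(t[[1]]); R <- up(t[[2]])
    lo <- pmin(L$lo, R$lo); hi <- pmax(L$hi, R$hi)
    lo <- ifelse(hi > 0L, pmax(lo, 1L), lo)
    contrib <- function(child_cost) {
      # for each candidate a: min_b child_cost[, b] + |a - b|
      sapply(vals, function(a)
        do.call(pmin, lapply(vals, function(b)
          child_cost[, b + 1L] + Dab[a + 1L, b + 1L])))
    }
    cost <- contrib(L$cost) + contrib(R$cost)
    # restrict to candidate range
    pos <- seq_along(lo)
    for (a in vals) cost[a < lo | a > hi, a + 1L] <-
      cost[a < lo | a > hi, a + 1L] + BIG
    list(left = L, right = R, cost = cost, lo = lo, hi = hi)
  }
  root <- up(topo)
  # top-down: parent of topology root is the diploid (value 1 everywhere)
  assignments <- list()   # node path string -> value vector
  down <- function(node, parent_vals, path) {
    if (!is.null(node$leaf)) return(invisible(NULL))
    tot <- node$cost + abs(outer(parent_vals, vals, "-"))
    pick <- vapply(seq_len(nrow(tot)), function(i) {
      best <- which(tot[i, ] <= min(tot[i, ]) + 1e-9) - 1L
      best[order(abs(best - parent_vals[i]), best)][1L]
    }, numeric(1))
    assignments[[path]] <<- as.integer(pick)
    down(node$left, as.integer(pick), paste0(path, "L"))
    down(node$right, as.integer(pick), paste0(path, "R"))
  }
  down(root, rep(1L, 2L * nb), "r")
  assignments
}

#' Reconstruct the clone copy-number phylogeny
#'
#' Finds a rooted tree over clone consensus profiles minimizing the total
#' number of interval events, with the normal diploid profile as root. Two
#' exhaustive candidate families are searched: (i) rooted binary
#' leaf-labelled topologies with unobserved ancestors, whose profiles are
#' initialised per bin and haplotype by a Sankoff-style pass over the
#' descendant min-max candidate range and then refined node-by-node with
#' an exact per-chromosome dynamic program; and (ii) clone-attachment
#' trees in which every node is an observed clone (capturing chains of
#' clones without unobserved intermediates). Each candidate is scored by
#' the exact interval-event distance of its edges, with at most one
#' whole-genome doubling per root path when \code{allow_wgd}; zero-event
#' edges are contracted so a clone can sit at an internal node. Ties go to
#' fewer unobserved ancestors, then to enumeration order. Runtime grows
#' factorially in the clone count; more than 8 clones is refused.
#'
#' @param clones A \code{clone_set}, or a named list of bins x 2 profiles.
#' @param bins Bin grid (taken from the clone_set when given).
#' @param allow_wgd Permit doubling events (default: TRUE when any clone
#'   looks doubled by \code{\link{detect_wgd}}).
#' @return A \code{cn_tree}: \code{nodes} (named profile list),
#'   \code{node_type} (root / clone / ancestor), \code{edges} (parent,
#'   child, n_events), \code{edge_events} (by child), \code{total_events}.
#' @export
reconstruct_tree <- function(clones, bins = NULL, allow_wgd = NULL) {
  if (inherits(clones, "clone_set")) {
    bins <- clones$bins
    profs <- lapply(clones$clones, `[[`, "cn")
    names(profs) <- names(clones$clones)
  } else profs <- clones
  if (is.null(bins)) stop("bins required")
  n <- length(profs)
  if (n < 1L) stop("need at least one clone")
  if (n > 8L)
    stop("more than 8 clones: exhaustive search refused; reduce the clone set")
  if (is.null(allow_wgd))
    allow_wgd <- any(vapply(profs, detect_wgd, logical(1), bins = bins))
  ids <- names(profs)
  nb <- n_bins(bins)
  root_prof <- diploid_profile(bins)

  if (n == 1L) {
    d <- interval_event_distance(root_prof, profs[[1]], bins, allow_wgd)
    return(build_cn_tree(
      nodes = c(list(diploid = root_prof), profs),
      node_type = c(diploid = "root", stats::setNames("clone", ids)),
      edges = data.frame(parent = "diploid", child = ids,
                         stringsAsFactors = FALSE),
      edge_events = stats::setNames(list(d$events), ids),
      bins = bins))
  }

  candidates <- list()
  for (topo in enumerate_topologies(n)) {
    anc <- assign_ancestors(topo, profs, nb)
    cand <- materialize_topology(topo, anc, profs, root_prof, nb)
    cand$nodes <- refine_ancestors(cand$nodes, cand$node_type, cand$edges,
                                   bins)
    candidates[[length(candidates) + 1L]] <- cand
  }
  if (n <= 6L) {
    for (par_idx in enumerate_attachments(n)) {
      candidates[[length(candidates) + 1L]] <- list(
        nodes = c(list(diploid = root_prof), profs),
        node_type = c(diploid = "root", stats::setNames(rep("clone", n), ids)),
        edges = data.frame(parent = c("diploid", ids)[par_idx + 1L],
                           child = ids, stringsAsFactors = FALSE))
    }
  }

  starts <- which(!duplicated(bins$chrom))
  cbi <- chrom_bin_index(bins)
  best <- NULL
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    sc <- score_candidate_counts(cand, bins, allow_wgd, starts, cbi)
    if (is.null(sc)) next
    key <- c(sc$total, sc$n_internal)
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2])) {
      best <- c(cand, sc); best$key <- key
    }
  }
  if (is.null(best)) stop("no valid event path for any topology")
  finalize_candidate(best, bins)
}

# all parent-assignment vectors for clone-attachment trees: entry k is the
# parent of clone k (0 = diploid, j = clone j); only cycle-free
# assignments are kept. Equivalent to enumerating all labelled trees on
# {diploid, clones} rooted at the diploid.
enumerate_attachments <- function(n) {
  grids <- rep(list(0:n), n)
  combos <- do.call(expand.grid, grids)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    par <- as.integer(combos[r, ])
    if (any(par == seq_len(n))) next
    # reachability from the root
    ok <- TRUE
    for (k in seq_len(n)) {
      seen <- integer(0); v <- k
      while (v != 0L) {
        if (v %in% seen) { ok <- FALSE; break }
        seen <- c(seen, v); v <- par[v]
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- par
  }
  out
}

# materialise a binary topology into named nodes / node_type / edges
materialize_topology <- function(topo, anc, profs, root_prof, nb) {
  ids <- names(profs)
  nodes <- list(diploid = root_prof)
  node_type <- c(diploid = "root")
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  anc_count <- 0L
  walk <- function(t, path, parent_name) {
    if (!is.list(t)) {
      id <- ids[t]
      nodes[[id]] <<- profs[[t]]
      node_type[id] <<- "clone"
      edges <<- rbind(edges, data.frame(parent = parent_name, child = id,
                                        stringsAsFactors = FALSE))
      return(id)
    }
    anc_count <<- anc_count + 1L
    id <- paste0("anc", anc_count)
    nodes[[id]] <<- vec_to_profile(anc[[path]], nb)
    node_type[id] <<- "ancestor"
    edges <<- rbind(edges, data.frame(parent = parent_name, child = id,
                                      stringsAsFactors = FALSE))
    walk(t[[1]], paste0(path, "L"), id)
    walk(t[[2]], paste0(path, "R"), id)
    id
  }
  walk(topo, "r", "diploid")
  list(nodes = nodes, node_type = node_type, edges = edges)
}

# value vectors (length 2*nb, A then B) -> profile matrix
vec_to_profile <- function(v, nb) {
  cbind(A = v[seq_len(nb)], B = v[nb + seq_len(nb)])
}

# Coordinate-descent refinement of the unobserved ancestor profiles of a
# candidate tree: each ancestor is re-optimised exactly against its
# current parent and children (per-chromosome, per-haplotype Steiner DP in
# C++) until no profile changes. The per-bin Sankoff initialisation
# ignores interval coupling: an ancestor state that lets an event merge
# with an adjacent segment can be globally cheaper than the per-bin
# optimum.
refine_ancestors <- function(nodes, node_type, edges, bins, max_sweeps = 4L) {
  cbi <- chrom_bin_index(bins)
  anc <- names(node_type)[node_type == "ancestor"]
  if (length(anc) == 0L) return(nodes)
  parent_of <- stats::setNames(edges$parent, edges$child)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (a in anc) {
      pv_all <- nodes[[parent_of[[a]]]]
      kid_ids <- edges$child[edges$parent == a]
      cur <- nodes[[a]]
      new <- cur
      for (idx in cbi) {
        for (hap in c("A", "B")) {
          kidm <- vapply(kid_ids, function(k) nodes[[k]][idx, hap],
                         integer(length(idx)))
          if (is.null(dim(kidm))) kidm <- matrix(kidm, nrow = length(idx))
          x <- steiner_dp_cpp(pv_all[idx, hap], kidm)
          if (length(x)) new[idx, hap] <- x
        }
      }
      if (!identical(new, cur)) { nodes[[a]] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  nodes
}

# fast event count for one edge (no event construction); NA if infeasible
edge_count_fast <- function(p, cc, starts) {
  if (any(p == 0L & cc > 0L)) return(NA_integer_)
  tot <- 0L
  for (h in 1:2) {
    dh <- cc[, h] - p[, h]
    g <- pmax(dh, 0L); l <- pmax(-dh, 0L)
    gl <- c(0L, g[-length(g)]); gl[starts] <- 0L
    ll <- c(0L, l[-length(l)]); ll[starts] <- 0L
    tot <- tot + sum(pmax(g - gl, 0L)) + sum(pmax(l - ll, 0L))
  }
  tot
}

# fast doubled-edge count: 1 + optimal pre/post split per chromosome and
# haplotype; NA if infeasible
wgd_count_fast <- function(p, cc, cbi) {
  tot <- 1L
  for (idx in cbi) {
    for (hap in c("A", "B")) {
      dp <- wgd_edge_dp(p[idx, hap], cc[idx, hap])
      if (is.null(dp)) return(NA_integer_)
      tot <- tot + dp$count
    }
  }
  tot
}

# Score a candidate tree by counts only: per-edge distances with and
# without doubling, the at-most-one-doubling-per-root-path placement DP,
# and the post-contraction ancestor count for tie-breaking. Returns NULL
# if some edge is infeasible in every mode.
score_candidate_counts <- function(cand, bins, allow_wgd, starts, cbi) {
  nodes <- cand$nodes; node_type <- cand$node_type; edges <- cand$edges
  ne <- nrow(edges)
  d0 <- d1 <- rep(NA_integer_, ne)
  for (i in seq_len(ne)) {
    p <- nodes[[edges$parent[i]]]; cc <- nodes[[edges$child[i]]]
    d0[i] <- edge_count_fast(p, cc, starts)
    if (allow_wgd) d1[i] <- wgd_count_fast(p, cc, cbi)
  }
  children_of <- split(seq_len(ne), edges$parent)
  INF <- 1e9
  use_wgd <- rep(FALSE, ne)
  cost_edge <- function(i, used) {
    kids <- children_of[[edges$child[i]]]
    sub <- function(u) if (is.null(kids)) 0 else
      sum(vapply(kids, cost_edge, numeric(1), used = u))
    c0 <- if (is.na(d0[i])) INF else d0[i] + sub(used)
    c1 <- if (used || is.na(d1[i])) INF else d1[i] + sub(TRUE)
    min(c0, c1)
  }
  pick_edge <- function(i, used) {
    kids <- children_of[[edges$child[i]]]
    sub <- function(u) if (is.null(kids)) 0 else
      sum(vapply(kids, cost_edge, numeric(1), used = u))
    c0 <- if (is.na(d0[i])) INF else d0[i] + sub(used)
    c1 <- if (used || is.na(d1[i])) INF else d1[i] + sub(TRUE)
    w <- c1 < c0
    use_wgd[i] <<- w
    if (!is.null(kids)) for (k in kids) pick_edge(k, used || w)
  }
  top <- children_of[["diploid"]]
  total <- sum(vapply(top, cost_edge, numeric(1), used = FALSE))
  if (total >= INF) return(NULL)
  for (k in top) pick_edge(k, FALSE)
  counts <- ifelse(use_wgd, d1, d0)
  # simulate contraction on counts to get the effective ancestor count
  nt <- node_type; ed <- edges; cn <- counts
  repeat {
    z <- which(cn == 0L & (nt[ed$child] == "ancestor" |
                             nt[ed$parent] == "ancestor"))
    if (length(z) == 0L) break
    i <- z[1L]
    if (nt[ed$child[i]] == "ancestor") { keep <- ed$parent[i]; drop <- ed$child[i] }
    else { keep <- ed$child[i]; drop <- ed$parent[i] }
    ed <- ed[-i, , drop = FALSE]; cn <- cn[-i]
    ed$parent[ed$parent == drop] <- keep
    ed$child[ed$child == drop] <- keep
    nt <- nt[names(nt) != drop]
  }
  list(total = total, use_wgd = use_wgd, counts = counts,
       n_internal = sum(nt == "ancestor"))
}

# build full event lists for the winning candidate and contract
finalize_candidate <- function(best, bins) {
  edges <- best$edges
  edge_events <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    p <- best$nodes[[edges$parent[i]]]; cc <- best$nodes[[edges$child[i]]]
    r <- interval_event_distance(p, cc, bins, allow_wgd = best$use_wgd[i])
    edge_events[[i]] <- r$events
  }
  names(edge_events) <- edges$child
  edges$n_events <- best$counts
  contract_tree(best$nodes, best$node_type, edges, edge_events, bins)
}

# contract zero-event edges whose child or parent is an unobserved
# ancestor, so clones can occupy internal positions; renumber ancestors
# in preorder for determinism.
contract_tree <- function(nodes, node_type, edges, edge_events, bins) {
  repeat {
    z <- which(edges$n_events == 0L &
                 (node_type[edges$child] == "ancestor" |
                    node_type[edges$parent] == "ancestor"))
    if (length(z) == 0L) break
    i <- z[1L]
    par <- edges$parent[i]; ch <- edges$child[i]
    # always dissolve the ancestor endpoint
    if (node_type[ch] == "ancestor") { keep <- par; drop <- ch }
    else { keep <- ch; drop <- par }
    edges <- edges[-i, , drop = FALSE]
    if (drop == ch) {
      edge_events[[ch]] <- NULL          # incoming zero-event entry
    } else {
      # dropped node is the parent ancestor: the child inherits its
      # incoming edge (and that edge's events)
      edge_events[[ch]] <- NULL
      if (!is.null(edge_events[[drop]])) {
        edge_events[[ch]] <- edge_events[[drop]]
        edge_events[[drop]] <- NULL
      }
    }
    edges$parent[edges$parent == drop] <- keep
    edges$child[edges$child == drop] <- keep
    nodes[[drop]] <- NULL
    node_type <- node_type[names(node_type) != drop]
  }
  # rename ancestors in preorder
  anc_ids <- names(node_type)[node_type == "ancestor"]
  if (length(anc_ids)) {
    ord <- character(0)
    visit <- function(nm) {
      if (node_type[nm] == "ancestor") ord <<- c(ord, nm)
      for (ch in edges$child[edges$parent == nm]) visit(ch)
    }
    visit("diploid")
    map <- stats::setNames(paste0("anc", seq_along(ord)), ord)
    rn <- function(x) ifelse(x %in% names(map), map[x], x)
    edges$parent <- unname(rn(edges$parent))
    edges$child <- unname(rn(edges$child))
    names(nodes) <- unname(rn(names(nodes)))
    names(node_type) <- unname(rn(names(node_type)))
    names(edge_events) <- unname(rn(names(edge_events)))
  }
  build_cn_tree(nodes, node_type, edges, edge_events, bins)
}

build_cn_tree <- function(nodes, node_type, edges, edge_events, bins) {
  edges$n_events <- vapply(edge_events[edges$child], nrow, integer(1))
  structure(list(nodes = nodes, node_type = node_type, edges = edges,
                 edge_events = edge_events,
                 total_events = sum(edges$n_events), bins = bins),
            class = "cn_tree")
}

#' @export
print.cn_tree <- function(x, ...) {
  cat(sprintf("cn_tree: %d nodes (%d clones, %d ancestors), %d events total\n",
              length(x$nodes), sum(x$node_type == "clone"),
              sum(x$node_type == "ancestor"), x$total_events))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s  (%d events)\n", x$edges$parent[i],
                x$edges$child[i], x$edges$n_events[i]))
  invisible(x)
}

#' Classify the events on an edge
#'
#' Fills the \code{kind} column of an edge's event table by the standard
#' taxonomy: gains (\code{gain}); losses (\code{del}); losses that end
#' with the affected haplotype completely lost over the interval
#' (\code{loh}); losses where the lost interval's other haplotype sits
#' above the per-allele baseline after the edge, i.e. the retained allele
#' is simultaneously amplified (\code{cn_loh}); and \code{wgd}.
#'
#' @param events Edge event table, valid on \code{parent}.
#' @param parent Parent profile at the start of the edge.
#' @param bins Bin grid.
#' @param wgd_baseline Is the per-allele baseline already doubled above
#'   this edge? (An on-edge doubling raises it too.)
#' @return The event table with \code{kind} filled.
#' @export
classify_events <- function(events, parent, bins, wgd_baseline = FALSE) {
  p <- as_profile_matrix(parent)
  final <- apply_events(p, events)
  has_wgd <- any(events$haplotype == "both")
  base <- if (wgd_baseline || has_wgd) 2L else 1L
  w <- bin_lengths(bins)
  kinds <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (identical(ev$haplotype, "both")) { kinds[i] <- "wgd"; next }
    if (ev$delta > 0L) { kinds[i] <- "gain"; next }
    idx <- (ev$start_bin + 1L):ev$end_bin
    hap <- ev$haplotype; other <- if (hap == "A") "B" else "A"
    if (all(final[idx, hap] == 0L)) {
      amp_w <- sum(w[idx][final[idx, other] > base])
      kinds[i] <- if (amp_w > sum(w[idx]) / 2) "cn_loh" else "loh"
    } else kinds[i] <- "del"
  }
  events$kind <- kinds
  events
}

#' Convert a copy-number tree to an ape phylogeny
#'
#' Edge lengths are event counts; internal node labels are kept.
#' @param x A \code{cn_tree}.
#' @param ... Unused.
#' @return An \code{ape::phylo} object.
#' @export
as.phylo.cn_tree <- function(x, ...) {
  nm <- names(x$nodes)
  is_leaf <- !(nm %in% x$edges$parent)
  tips <- nm[is_leaf]; internals <- nm[!is_leaf]
  # ape wants root first among internal nodes
  internals <- c("diploid", setdiff(internals, "diploid"))
  idx <- c(stats::setNames(seq_along(tips), tips),
           stats::setNames(length(tips) + seq_along(internals), internals))
  phy <- list(edge = cbind(idx[x$edges$parent], idx[x$edges$child]),
              tip.label = tips, node.label = internals,
              edge.length = as.numeric(x$edges$n_events),
              Nnode = length(internals))
  attr(phy, "class") <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' @export
plot.cn_tree <- function(x, ...) {
  phy <- as.phylo.cn_tree(x)
  ape::plot.phylo(phy, show.node.label = TRUE, ...)
  invisible(x)
}
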