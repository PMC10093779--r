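# Shared fixtures: tiny deterministic bin grids and profiles built in code.

# one chromosome, n equal bins of width `w` bp
tiny_bins <- function(n = 10, w = 10) {
  make_bins(stats::setNames(n * w, "chr1"), w)
}

# profile constructor from per-bin haplotype vectors
prof <- function(a, b = a) {
  cbind(A = as.integer(a), B = as.integer(b))
}

# vectorized minimal-event counts for one parent row against a matrix of
# children (single haplotype, one chromosome); -1 where unreachable.
# Independent re-statement of the segment recurrence used to cross-check
# whole matrices quickly in the oracle test.
vec_counts <- function(pv, childm) {
  delta <- sweep(childm, 2, pv)
  g <- pmax(delta, 0); l <- pmax(-delta, 0)
  gi <- cbind(0, g[, -ncol(g), drop = FALSE])
  li <- cbind(0, l[, -ncol(l), drop = FALSE])
  cnt <- rowSums(pmax(g - gi, 0)) + rowSums(pmax(l - li, 0))
  zero <- pv == 0
  if (any(zero))
    cnt[rowSums(childm[, zero, drop = FALSE] > 0) > 0] <- -1
  cnt
}

# replay every edge of a cn_tree and check it reproduces the child profile
edges_replay_exactly <- function(tree) {
  for (i in seq_len(nrow(tree$edges))) {
    par <- tree$edges$parent[i]; ch <- tree$edges$child[i]
    got <- apply_events(tree$nodes[[par]], tree$edge_events[[ch]])
    if (!identical(unname(got), unname(tree$nodes[[ch]]))) return(FALSE)
  }
  TRUE
}

# map identified clones to their majority truth label
clone_truth_map <- function(cloneset, obs) {
  vapply(cloneset$clones, function(cl) {
    members <- names(cloneset$labels)[cloneset$labels == cl$clone_id]
    tl <- table(obs$true_clone[match(members, obs$cell_ids)])
    names(tl)[which.max(tl)]
  }, character(1))
}
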