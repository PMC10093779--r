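# Pipeline driver: simulate -> infer -> clones -> metrics -> phylo ->
# concord, from a single validated config and seed, writing every stage's
# outputs in the documented plain-text formats plus a machine-readable
# summary. Reruns with the same config and seed are byte-identical.

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: the
#' scaled-down 22-autosome genome with 5 Mb analysis bins, the sparse
#' droplet coverage regime (0.02X per cell), the deletion-dominated event
#' model, the 0.12 clone-identification error tolerance, the 1.5-4 ploidy
#' grid and the 1,000 bp concordance bin size.
#'
#' @return Nested named list; see the methods vignette for units and
#'   rationale of each entry.
#' @export
default_config <- function() {
  list(
    genome = list(total_bp = 5e8, bin_size = 5e6),
    simulation = list(
      n_clones = 3L, n_truncal_events = 20L, n_private_events = 5L,
      p_wgd = 0, deletion_bias = 0.7, topology = "random",
      clone_proportions = NULL, normal_fraction = 0.1,
      n_cells = 300L, mean_coverage = 0.02, read_length = 100,
      snp_density = 5e-4, noise_cell_fraction = 0.05,
      noise_perturb_prob = 0.3, depth_sd = 0.1),
    calling = list(ploidy_grid = c(1.5, 2, 2.5, 3, 3.5, 4), max_cn = 8L),
    clones = list(error_rate = 0.12, min_clone_size = NULL,
                  method = "hclust"),
    metrics = list(wgd = "tumor", wgd_threshold = 0.5),
    phylo = list(allow_wgd = NULL),
    concordance = list(bin_size = 1000, cluster_threshold = 0.5),
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML config, overlays it on \code{\link{default_config}} and
#' validates: unknown keys are rejected, numeric parameters are
#' range-checked.
#'
#' @param path YAML file; NULL returns the validated defaults.
#' @return Validated config list.
#' @examples
#' cfg <- read_config(system.file("extdata", "demo_config.yaml",
#'                                package = "scnaclonal"))
#' cfg$simulation$n_clones
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "config")
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, where) {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop(sprintf("unknown config key '%s' in %s", k, where))
    if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(where, "$", k))
    else base[[k]] <- user[[k]]
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop(sprintf("config: %s", msg))
  chk(cfg$genome$total_bp > 0, "genome$total_bp must be > 0")
  chk(cfg$genome$bin_size > 0, "genome$bin_size must be > 0")
  s <- cfg$simulation
  chk(s$n_clones >= 1, "simulation$n_clones must be >= 1")
  chk(s$n_truncal_events >= 0 && s$n_private_events >= 0,
      "event counts must be >= 0")
  for (p in c("p_wgd", "deletion_bias", "normal_fraction",
              "noise_cell_fraction", "noise_perturb_prob"))
    chk(s[[p]] >= 0 && s[[p]] <= 1, sprintf("simulation$%s must be in [0,1]", p))
  chk(s$n_cells >= 1 && s$mean_coverage > 0,
      "n_cells >= 1 and mean_coverage > 0 required")
  chk(all(cfg$calling$ploidy_grid > 0), "ploidy_grid must be positive")
  chk(cfg$clones$error_rate >= 0 && cfg$clones$error_rate <= 1,
      "error_rate must be in [0,1]")
  chk(cfg$metrics$wgd_threshold > 0 && cfg$metrics$wgd_threshold < 1,
      "wgd_threshold must be in (0,1)")
  chk(cfg$concordance$bin_size > 0, "concordance$bin_size must be > 0")
  invisible(cfg)
}

newick_string <- function(tree) {
  rec <- function(nm) {
    kids <- sort(tree$edges$child[tree$edges$parent == nm])
    inner <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")") else ""
    len <- tree$edges$n_events[tree$edges$child == nm]
    paste0(inner, nm, if (length(len)) paste0(":", len) else "")
  }
  paste0(rec("diploid"), ";")
}

# truth as a cn_tree (for writing / comparison with reconstructions)
truth_tree <- function(truth) {
  node_type <- c(diploid = "root",
                 stats::setNames(rep("clone", length(truth$clone_ids)),
                                 truth$clone_ids))
  build_cn_tree(truth$profiles, node_type, truth$edges, truth$edge_events,
                truth$bins)
}

#' Write a simulated truth to disk
#'
#' Clone profile TSV, cell table TSV, and the clone tree as Newick with an
#' edge-event sidecar.
#' @param truth A \code{clonal_truth}.
#' @param obs Matching \code{cell_obs} (for the cell table); optional.
#' @param dir Output directory (created).
#' @export
write_truth <- function(truth, obs = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bins <- truth$bins
  rows <- lapply(truth$clone_ids, function(cl)
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               clone_id = cl, cnA = truth$profiles[[cl]][, 1],
               cnB = truth$profiles[[cl]][, 2], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "truth_clone_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- truth_tree(truth)
  write_tree(tt, file.path(dir, "truth_tree.nwk"),
             file.path(dir, "truth_tree_events.tsv"))
  if (!is.null(obs))
    utils::write.table(
      data.frame(cell_id = obs$cell_ids, true_clone = obs$true_clone,
                 stringsAsFactors = FALSE),
      file.path(dir, "truth_cells.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write observations as long-form TSV
#' @param obs A \code{cell_obs}.
#' @param path Output file.
#' @export
write_observations_tsv <- function(obs, path) {
  nb <- n_bins(obs$bins); nc <- length(obs$cell_ids)
  df <- data.frame(
    cell_id = rep(obs$cell_ids, each = nb),
    chrom = rep(obs$bins$chrom, nc),
    start = rep(obs$bins$start, nc),
    end = rep(obs$bins$end, nc),
    read_count = as.vector(obs$read_count),
    b_count = as.vector(obs$b_count),
    snp_total = as.vector(obs$snp_total),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' simulate -> infer -> clones -> metrics -> phylo -> concord, writing
#' each stage's outputs into \code{outdir} and returning (and writing) a
#' machine-readable summary. The concordance stage compares the identified
#' clone consensus profiles pairwise: identical-window proportions on the
#' analysis grid and Pearson correlation of fine-binned median copy
#' numbers from their segment tables. All randomness derives from
#' \code{config$seed}; two runs with the same config produce byte-identical
#' outputs.
#'
#' @param config Validated config (see \code{\link{read_config}}).
#' @param outdir Output directory (created).
#' @return The summary list, invisibly; also written to
#'   \code{summary.yaml}.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  s <- config$simulation

  bins <- stage("simulate", make_bins(default_genome(config$genome$total_bp),
                                      config$genome$bin_size))
  truth <- stage("simulate", simulate_clonal_truth(
    bins, n_clones = s$n_clones, n_truncal_events = s$n_truncal_events,
    n_private_events = s$n_private_events, p_wgd = s$p_wgd,
    deletion_bias = s$deletion_bias, seed = config$seed,
    topology = s$topology, clone_proportions = s$clone_proportions,
    normal_fraction = s$normal_fraction))
  obs <- stage("simulate", simulate_cells(
    truth, n_cells = s$n_cells, mean_coverage = s$mean_coverage,
    read_length = s$read_length, snp_density = s$snp_density,
    noise_cell_fraction = s$noise_cell_fraction,
    noise_perturb_prob = s$noise_perturb_prob, depth_sd = s$depth_sd,
    seed = config$seed))
  write_truth(truth, obs, outdir)
  write_observations_tsv(obs, file.path(outdir, "observations.tsv"))

  signals <- stage("infer", compute_signals(obs))
  calls <- stage("infer", call_cells(signals, config$calling$ploidy_grid,
                                     config$calling$max_cn))
  write_calls_tsv(calls, file.path(outdir, "calls.tsv"))

  cloneset <- stage("clones", identify_clones(
    calls, error_rate = config$clones$error_rate,
    min_clone_size = config$clones$min_clone_size,
    method = config$clones$method))
  cloneset <- flag_clone_wgd(cloneset, config$metrics$wgd_threshold)
  write_assignments_tsv(cloneset, file.path(outdir, "clone_assignments.tsv"))
  write_clones_tsv(cloneset, file.path(outdir, "clone_profiles.tsv"))
  audit <- noisy_cell_audit(cloneset, calls)
  utils::write.table(audit, file.path(outdir, "noisy_cell_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  met <- stage("metrics", cell_metrics(calls, wgd = config$metrics$wgd,
                                       wgd_threshold = config$metrics$wgd_threshold))
  write_metrics_tsv(met, file.path(outdir, "cell_metrics.tsv"))

  tree <- NULL
  if (length(cloneset$clones) >= 1 && length(cloneset$clones) <= 8) {
    tree <- stage("phylo", reconstruct_tree(cloneset,
                                            allow_wgd = config$phylo$allow_wgd))
    write_tree(tree, file.path(outdir, "tree.nwk"),
               file.path(outdir, "tree_events.tsv"))
  }

  conc <- stage("concord", clone_concordance_stage(cloneset, config))
  utils::write.table(conc$table, file.path(outdir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(conc$corr))
    utils::write.table(round(conc$corr, 10), file.path(outdir, "correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)

  clone_sizes <- vapply(cloneset$clones, `[[`, integer(1), "n_cells")
  summary <- list(
    seed = as.integer(config$seed),
    n_cells = length(obs$cell_ids),
    n_clones = length(cloneset$clones),
    n_noisy = unname(sum(cloneset$labels == "NOISY")),
    clone_sizes = as.list(clone_sizes),
    event_resamples = truth$resample_count,
    mean_ploidy = round(mean(met$ploidy), 6),
    mean_frac_aberrant = round(mean(met$frac_aberrant), 6),
    mean_frac_deleted = round(mean(met$frac_deleted), 6),
    mean_frac_amplified = round(mean(met$frac_amplified), 6),
    mean_frac_subclonal = round(mean(met$frac_subclonal), 6),
    clone_mean_frac_aberrant = round(mean(vapply(
      cloneset$clones, function(cl)
        aberrant_fraction(cl$cn, bins, met$wgd[1]), numeric(1))), 6),
    tumor_wgd = unname(met$wgd[1]),
    tree_total_events = if (is.null(tree)) NA else tree$total_events,
    concordance = if (nrow(conc$table))
      lapply(seq_len(nrow(conc$table)), function(i) as.list(conc$table[i, ]))
    else list()
  )
  yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
  invisible(summary)
}

clone_concordance_stage <- function(cloneset, config) {
  cl <- cloneset$clones
  tab <- data.frame(clone_a = character(0), clone_b = character(0),
                    prop_identical = numeric(0),
                    n_windows = integer(0), corr = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(cl) < 2)
    return(list(table = tab, corr = NULL))
  fine <- make_bins(stats::setNames(
    tapply(cloneset$bins$end, cloneset$bins$chrom, max)[
      unique(cloneset$bins$chrom)],
    unique(cloneset$bins$chrom)), config$concordance$bin_size)
  vecs <- vapply(cl, function(x)
    binned_median_cn(profile_to_segments(x$cn, cloneset$bins), fine),
    numeric(n_bins(fine)))
  corr <- correlation_matrix(vecs,
                             min_complete = min(100L, n_bins(fine)))
  for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
    wc <- window_concordance(cl[[i]]$cn, cl[[j]]$cn, cloneset$bins,
                             cl[[i]]$wgd, cl[[j]]$wgd)
    tab <- rbind(tab, data.frame(
      clone_a = cl[[i]]$clone_id, clone_b = cl[[j]]$clone_id,
      prop_identical = round(ifelse(wc$defined, wc$prop_identical, NA), 6),
      n_windows = wc$n_windows_considered,
      corr = round(corr[i, j], 6), stringsAsFactors = FALSE))
  }
  list(table = tab, corr = corr)
}

#' Simulate a panel of related and unrelated samples
#'
#' Builds \code{n_pairs} independent clonal truths and takes two clones
#' from each as a related sample pair (they share that truth's truncal
#' events and differ by private events); clones from different truths are
#' unrelated. The panel is the test bed for the cross-sample concordance
#' and correlation analyses.
#'
#' @param bins Bin grid.
#' @param n_pairs Number of related pairs (default 2).
#' @param n_truncal_events,n_private_events,deletion_bias Event model per
#'   truth (see \code{\link{simulate_clonal_truth}}).
#' @param seed Integer seed.
#' @return List with \code{profiles} (named list of bins x 2 matrices,
#'   "p<i>_a"/"p<i>_b"), \code{pair_of} (named pair index) and
#'   \code{truths}.
#' @export
simulate_sample_panel <- function(bins, n_pairs = 2,
                                  n_truncal_events = 20,
                                  n_private_events = 5,
                                  deletion_bias = 0.7, seed = 1L) {
  profiles <- list(); pair_of <- integer(0); truths <- list()
  for (i in seq_len(n_pairs)) {
    tr <- simulate_clonal_truth(
      bins, n_clones = 2, n_truncal_events = n_truncal_events,
      n_private_events = n_private_events, p_wgd = 0,
      deletion_bias = deletion_bias,
      seed = substream_seed(seed, paste0("panel", i)))
    truths[[i]] <- tr
    profiles[[paste0("p", i, "_a")]] <- tr$profiles$clone1
    profiles[[paste0("p", i, "_b")]] <- tr$profiles$clone2
    pair_of <- c(pair_of, stats::setNames(c(i, i),
                                          paste0("p", i, c("_a", "_b"))))
  }
  list(profiles = profiles, pair_of = pair_of, truths = truths)
}
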