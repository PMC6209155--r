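#' Configuration of a feature-selection run
#'
#' Collects every tunable of the two-stage pipeline.  Defaults follow the
#' experimental setup: an 80% confidence filter (`alpha = 0.20`,
#' permutation test with 999 permutations), clustering into `k_target = 4`
#' clusters on a 3-nearest-neighbour feature graph, and redundancy removal
#' by pruning the single farthest-from-target feature of each cluster.
#'
#' @param band Frequency-band label of the input table (descriptive).
#' @param target Name of the target column (default `"BFM"`).
#' @param alpha Filter keeps features with permutation p-value `<= alpha`;
#'   in `(0, 1]`.
#' @param top_k If non-`NULL`, keep the `top_k` best-scoring features
#'   instead of the p-value rule (exactly one of `alpha` / `top_k` is
#'   active).
#' @param k_init Initial cluster count; default (`NULL`) is one singleton
#'   per filtered feature, so the agglomeration itself builds all
#'   structure.
#' @param k_target Final number of feature clusters (default 4).
#' @param k_neighbors k of the kNN feature graph (default 3).
#' @param alpha_similarity Closeness exponent of the merge criterion.
#' @param reduction `"prune_farthest"` (default; the experiments' rule) or
#'   `"representatives"` (one max-HSIC feature per cluster, the combined
#'   algorithm's final step).
#' @param m_remove Features pruned per cluster under `"prune_farthest"`.
#' @param n_perm Permutations for the filter's p-values.
#' @param seed Master seed; all randomness (permutations, bisection
#'   restarts) flows from it.
#' @param merge_rule `"max"` or the literal `"min"` (see
#'   [mchameleon_merge()]).
#' @param kernel_target `"rbf"` (default) or `"linear"` target kernel.
#' @return A validated `biafs_config` list.
#' @export
selection_config <- function(band = "250kHz", target = "BFM", alpha = 0.20,
                             top_k = NULL, k_init = NULL, k_target = 4L,
                             k_neighbors = 3L, alpha_similarity = 1,
                             reduction = c("prune_farthest",
                                           "representatives"),
                             m_remove = 1L, n_perm = 999L, seed = 1L,
                             merge_rule = c("max", "min"),
                             kernel_target = c("rbf", "linear")) {
  reduction <- match.arg(reduction)
  merge_rule <- match.arg(merge_rule)
  kernel_target <- match.arg(kernel_target)
  stopifnot(alpha > 0, alpha <= 1, k_target >= 1L, k_neighbors >= 1L,
            m_remove >= 0L, n_perm >= 19L)
  if (!is.null(top_k)) stopifnot(top_k >= 1L)
  if (!is.null(k_init)) stopifnot(k_init >= k_target)
  structure(list(band = band, target = target, alpha = alpha, top_k = top_k,
                 k_init = k_init, k_target = as.integer(k_target),
                 k_neighbors = as.integer(k_neighbors),
                 alpha_similarity = alpha_similarity, reduction = reduction,
                 m_remove = as.integer(m_remove),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 merge_rule = merge_rule, kernel_target = kernel_target),
            class = "biafs_config")
}

#' Run the full two-stage feature selection
#'
#' Composes the pipeline end-to-end: expand the bioimpedance feature set,
#' z-score it, rank and filter by HSIC relevance against the target
#' (stage 1, yielding F'), build the kNN similarity graph over F', cluster
#' it with the improved Chameleon agglomeration down to `k_target`
#' clusters, and remove redundant features (stage 2, yielding the optimal
#' set X).  Fully reproducible given `config$seed`.
#'
#' @param table A validated sample table ([read_sample_table()] /
#'   [simulate_cohort()]).
#' @param config A [selection_config()].
#' @return An object of class `biafs_selection`: `selected` (X), `stage1`
#'   (the `hsic_filter` score table; F' is its kept rows), `clusters`
#'   (named list of feature-name vectors), `merge_trace`, `distances`
#'   (prune mode), `removals` (per-feature removal reason:
#'   `irrelevant@filter` or `redundant@cluster`), `config`, `n_samples`.
#' @export
run_selection <- function(table, config = selection_config()) {
  stopifnot(inherits(config, "biafs_config"))
  if (!config$target %in% names(table)) {
    stop("target column not in table: ", config$target)
  }
  target <- table[[config$target]]
  set.seed(config$seed)

  fm <- expand_features(table)
  fmz <- zscore_normalize(fm)
  cspec <- kernel_spec(config$kernel_target)
  stage1 <- rank_and_filter(fmz, target, cspec = cspec,
                            alpha = config$alpha, top_k = config$top_k,
                            n_perm = config$n_perm, seed = config$seed)
  f_prime <- stage1$feature[stage1$kept]
  if (length(f_prime) < config$k_target) {
    stop("only ", length(f_prime), " feature(s) survive the filter, fewer ",
         "than k_target = ", config$k_target,
         "; decrease k_target or increase alpha")
  }

  keep_idx <- match(f_prime, colnames(fmz$values))
  # graph vertices in original column order, like every downstream output
  keep_idx <- sort(keep_idx)
  sub <- fmz
  sub$values <- fmz$values[, keep_idx, drop = FALSE]
  sub$constant <- fmz$constant[keep_idx]
  sim <- feature_similarity(sub)
  graph <- build_knn_graph(sim, min(config$k_neighbors,
                                    length(keep_idx) - 1L))

  state <- if (is.null(config$k_init) ||
               config$k_init >= length(keep_idx)) {
    cluster_state(graph)
  } else {
    initial_partition(graph, config$k_init)
  }
  state <- mchameleon_merge(state, config$k_target,
                            alpha = config$alpha_similarity,
                            merge_rule = config$merge_rule)

  if (config$reduction == "prune_farthest") {
    red <- prune_far_from_target(state, sub, target, config$m_remove)
    selected <- red$selected
    distances <- red$distances
  } else {
    selected <- select_representatives(state, stage1)
    distances <- NULL
  }

  all_feats <- stage1$feature
  removal_row <- function(feats, why) {
    data.frame(feature = feats, reason = rep(why, length(feats)),
               stringsAsFactors = FALSE)
  }
  removals <- rbind(
    removal_row(setdiff(all_feats, f_prime), "irrelevant@filter"),
    removal_row(setdiff(f_prime, selected), "redundant@cluster"))
  removals <- removals[order(match(removals$feature,
                                   colnames(fmz$values))), ]
  rownames(removals) <- NULL

  clusters <- lapply(state$clusters, function(ix) graph$names[ix])
  structure(list(selected = selected, stage1 = stage1,
                 clusters = clusters, merge_trace = state$trace,
                 cluster_state = state, features = sub,
                 distances = distances, removals = removals,
                 config = config, n_samples = nrow(table),
                 target = config$target),
            class = "biafs_selection")
}

#' @export
print.biafs_selection <- function(x, ...) {
  f_prime <- x$stage1$feature[x$stage1$kept]
  cat("biafs selection (target ", x$target, ", n = ", x$n_samples, ")\n",
      sep = "")
  cat("  stage 1 filter : ", nrow(x$stage1), " -> ", length(f_prime),
      " features\n", sep = "")
  cat("  stage 2 cluster: ", length(f_prime), " -> ", length(x$selected),
      " features in ", length(x$clusters), " clusters (",
      x$config$reduction, ")\n", sep = "")
  cat("  X =", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Write all outputs of a selection run
#'
#' Writes the per-feature score CSV, the merge trace, the final cluster
#' table (with distances under prune mode), the selected set, and the
#' removal log.
#'
#' @param result A `biafs_selection`.
#' @param prefix Path prefix; files `<prefix>_scores.csv`,
#'   `<prefix>_merge_trace.csv`, `<prefix>_clusters.csv`,
#'   `<prefix>_selected.csv`, `<prefix>_removals.csv` are created.
#' @return Invisibly, the vector of paths written.
#' @export
write_selection <- function(result, prefix) {
  stopifnot(inherits(result, "biafs_selection"))
  paths <- paste0(prefix, c("_scores.csv", "_merge_trace.csv",
                            "_clusters.csv", "_selected.csv",
                            "_removals.csv"))
  write_score_csv(result$stage1, paths[1L])
  write_cluster_csv(result$cluster_state, trace_path = paths[2L],
                    clusters_path = paths[3L],
                    distances = result$distances)
  write.csv(data.frame(feature = result$selected, stringsAsFactors = FALSE),
            paths[4L], row.names = FALSE)
  write.csv(result$removals, paths[5L], row.names = FALSE)
  invisible(paths)
}
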