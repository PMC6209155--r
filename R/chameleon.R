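#' Pairwise feature similarity
#'
#' Similarity between two features is the absolute Pearson correlation of
#' their sample vectors: 1 for a duplicated (or negated) column, near 0 for
#' independent noise.  Constant features get similarity 0 to every other
#' feature (with a warning).
#'
#' @param fm A `biafs_features` object (or a plain numeric matrix,
#'   features in columns).
#' @return A symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
feature_similarity <- function(fm) {
  v <- if (inherits(fm, "biafs_features")) fm$values else as.matrix(fm)
  stopifnot(ncol(v) >= 2L, nrow(v) >= 3L)
  sds <- apply(v, 2L, sd)
  if (any(sds < .EPS)) {
    warning("constant feature(s) get similarity 0: ",
            paste(colnames(v)[sds < .EPS], collapse = ", "))
  }
  s <- abs(suppressWarnings(cor(v)))
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  s
}

#' Sparse k-nearest-neighbour feature graph
#'
#' Builds the Chameleon feature graph: vertex u is connected to vertex v iff
#' v is among u's `k_neighbors` most similar features or vice versa
#' (symmetrized union), with edge weight equal to the similarity.  Ties at
#' the k-th neighbour are broken towards the lexicographically smaller
#' feature name.  Every vertex has degree >= 1 by construction (k >= 1).
#'
#' @param sim Symmetric similarity matrix with named rows/columns.
#' @param k_neighbors Number of neighbours, `1 <= k < m`.
#' @return A `feature_graph`: list with `names`, weight matrix `w`
#'   (0 off-graph), logical adjacency `adj`, and `k_neighbors`.
#' @export
build_knn_graph <- function(sim, k_neighbors = 3L) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  m <- nrow(sim)
  stopifnot(k_neighbors >= 1L, k_neighbors < m)
  nms <- colnames(sim)
  if (is.null(nms)) nms <- paste0("f", seq_len(m))
  adj <- matrix(FALSE, m, m, dimnames = list(nms, nms))
  for (u in seq_len(m)) {
    others <- setdiff(seq_len(m), u)
    # order by similarity desc, then lexicographic name
    ord <- others[order(-sim[u, others], nms[others])]
    nn <- ord[seq_len(k_neighbors)]
    adj[u, nn] <- TRUE
  }
  adj <- adj | t(adj)
  w <- ifelse(adj, sim, 0)
  diag(w) <- 0
  diag(adj) <- FALSE
  dimnames(w) <- list(nms, nms)
  structure(list(names = nms, w = w, adj = adj,
                 k_neighbors = as.integer(k_neighbors)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat("feature graph:", length(x$names), "vertices,",
      sum(x$adj[upper.tri(x$adj)]), "edges (k =", x$k_neighbors, ")\n")
  invisible(x)
}

# deterministic local RNG scope: the bisection heuristic must be a pure
# function of (members, graph) so cached cut quantities can be recomputed
.with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.cut_quantities <- function(side_a, side_b, graph) {
  wsub <- graph$w[side_a, side_b, drop = FALSE]
  asub <- graph$adj[side_a, side_b, drop = FALSE]
  n_edges <- sum(asub)
  cut <- sum(wsub[asub])
  c(cut = cut, mean = if (n_edges > 0) cut / n_edges else 0)
}

#' Balanced minimum-weight bisection of a cluster
#'
#' Splits a vertex set into two halves whose sizes differ by at most one,
#' minimizing the total weight of graph edges crossing the split.  This is
#' the internal "edge cut" |EC|_f of a cluster used by the relative
#' interconnectivity, and the mean weight of the cut's edges is the internal
#' closeness scale S-bar-EC_f.  Clusters of up to 14 vertices are solved by
#' exhaustive enumeration of all balanced splits; larger clusters use a
#' Kernighan-Lin style swap heuristic with 10 seeded random restarts
#' (deterministic given the cluster and graph).
#'
#' @param members Integer indices (or names) of the cluster's vertices,
#'   size >= 2.
#' @param graph A `feature_graph`.
#' @param method `"auto"` (exhaustive up to 14 vertices), `"exhaustive"`,
#'   or `"heuristic"`.
#' @param n_restarts Restarts for the heuristic.
#' @return List with `cut` (|EC|_f), `mean_cut` (S-bar-EC_f; 0 when the cut
#'   has no graph edges), and the two `sides`.
#' @export
balanced_min_bisection <- function(members, graph,
                                   method = c("auto", "exhaustive",
                                              "heuristic"),
                                   n_restarts = 10L) {
  method <- match.arg(method)
  if (is.character(members)) members <- match(members, graph$names)
  members <- as.integer(members)
  nc <- length(members)
  stopifnot(nc >= 2L, !anyNA(members))
  if (method == "auto") method <- if (nc <= 14L) "exhaustive" else "heuristic"
  if (method == "exhaustive") {
    half <- nc %/% 2L
    # even size: fix the first member in side A to halve the enumeration
    cand <- if (nc %% 2L == 0L) {
      cbind(TRUE, t(combn(nc - 1L, half - 1L, function(ix) {
        z <- rep(FALSE, nc - 1L); z[ix] <- TRUE; z
      })))
    } else {
      t(combn(nc, half, function(ix) {
        z <- rep(FALSE, nc); z[ix] <- TRUE; z
      }))
    }
    best <- NULL
    best_cut <- Inf
    for (r in seq_len(nrow(cand))) {
      in_a <- cand[r, ]
      q <- .cut_quantities(members[in_a], members[!in_a], graph)
      if (q[["cut"]] < best_cut - .EPS) {
        best_cut <- q[["cut"]]
        best <- in_a
      }
    }
    in_a <- best
  } else {
    seed <- (sum(members) * 131L + nc * 7L) %% 1000003L
    in_a <- .with_local_seed(seed, {
      wsub <- graph$w[members, members, drop = FALSE]
      half <- nc %/% 2L
      best <- NULL
      best_cut <- Inf
      for (r in seq_len(n_restarts)) {
        side <- rep(FALSE, nc)
        side[sample.int(nc, half)] <- TRUE
        side <- .kl_refine(side, wsub)
        cut <- sum(wsub[side, !side])
        if (cut < best_cut - .EPS) {
          best_cut <- cut
          best <- side
        }
      }
      best
    })
  }
  q <- .cut_quantities(members[in_a], members[!in_a], graph)
  list(cut = unname(q[["cut"]]), mean_cut = unname(q[["mean"]]),
       sides = list(members[in_a], members[!in_a]))
}

# Kernighan-Lin pass: repeatedly take the best unlocked swap, keep the best
# cumulative prefix, iterate until a full pass yields no improvement
.kl_refine <- function(in_a, w) {
  nc <- length(in_a)
  # D[i] = external - internal connection cost of vertex i
  repeat {
    side <- in_a
    locked <- rep(FALSE, nc)
    gains <- numeric(0)
    swaps <- list()
    npairs <- min(sum(side), sum(!side))
    for (step in seq_len(npairs)) {
      a_idx <- which(side & !locked)
      b_idx <- which(!side & !locked)
      if (length(a_idx) == 0L || length(b_idx) == 0L) break
      best_gain <- -Inf
      best_pair <- NULL
      for (a in a_idx) {
        da <- sum(w[a, !side]) - sum(w[a, side])
        for (b in b_idx) {
          db <- sum(w[b, side]) - sum(w[b, !side])
          g <- da + db - 2 * w[a, b]
          if (g > best_gain + .EPS) {
            best_gain <- g
            best_pair <- c(a, b)
          }
        }
      }
      if (is.null(best_pair)) break
      side[best_pair] <- !side[best_pair]
      locked[best_pair] <- TRUE
      gains <- c(gains, best_gain)
      swaps[[step]] <- best_pair
    }
    if (length(gains) == 0L) return(in_a)
    cum <- cumsum(gains)
    k <- which.max(cum)
    if (cum[k] <= .EPS) return(in_a)
    for (s in seq_len(k)) in_a[swaps[[s]]] <- !in_a[swaps[[s]]]
  }
}

# internal cut cache of one cluster; singleton fallback = mean weight of the
# vertex's incident edges in the full graph (keeps RI/RC finite)
.cluster_internal <- function(members, graph) {
  if (length(members) == 1L) {
    inc <- graph$adj[members, ]
    val <- if (any(inc)) mean(graph$w[members, inc]) else 0
    return(c(ec = val, sec = val))
  }
  b <- balanced_min_bisection(members, graph)
  c(ec = b$cut, sec = b$mean_cut)
}

#' Create a cluster state over a feature graph
#'
#' @param graph A `feature_graph`.
#' @param clusters List of vertex index/name vectors partitioning the graph
#'   (default: all singletons).
#' @return A `cluster_state`: the partition plus cached per-cluster internal
#'   bisection quantities (|EC|_f, S-bar-EC_f) and an empty merge trace.
#' @export
cluster_state <- function(graph, clusters = NULL) {
  stopifnot(inherits(graph, "feature_graph"))
  m <- length(graph$names)
  if (is.null(clusters)) clusters <- as.list(seq_len(m))
  clusters <- lapply(clusters, function(cl) {
    if (is.character(cl)) cl <- match(cl, graph$names)
    sort(as.integer(cl))
  })
  all_v <- sort(unlist(clusters))
  if (!identical(all_v, seq_len(m))) {
    stop("clusters must partition the graph's vertex set")
  }
  names(clusters) <- paste0("C", seq_along(clusters))
  internal <- lapply(clusters, .cluster_internal, graph = graph)
  structure(list(graph = graph, clusters = clusters, internal = internal,
                 next_id = length(clusters) + 1L,
                 trace = .empty_trace()),
            class = "cluster_state")
}

.empty_trace <- function() {
  data.frame(step = integer(0), cluster_a = character(0),
             cluster_b = character(0), ri = numeric(0), rc = numeric(0),
             similarity = numeric(0), h_after = integer(0),
             rule = character(0), stringsAsFactors = FALSE)
}

#' @export
print.cluster_state <- function(x, ...) {
  sizes <- vapply(x$clusters, length, 1L)
  cat("cluster state: h =", length(x$clusters), "clusters, sizes",
      paste(sizes, collapse = "/"), "\n")
  invisible(x)
}

# cross-cluster edge cut EC{c1,c2} and mean cross-edge weight
.pair_cut <- function(state, a, b) {
  .cut_quantities(state$clusters[[a]], state$clusters[[b]], state$graph)
}

#' Relative interconnectivity of two clusters
#'
#' `RI = EC{c1,c2} / (0.5 * (|EC|_c1 + |EC|_c2))`: the cross-cluster edge
#' cut normalized by the clusters' internal balanced min-bisection cut
#' weights.  A zero denominator with a positive numerator is treated as
#' maximal (numerator / 1e-12).
#'
#' @param c1,c2 Cluster names in `state`.
#' @param state A `cluster_state`.
#' @return RI >= 0, symmetric in its arguments.
#' @export
relative_interconnectivity <- function(c1, c2, state) {
  ec <- .pair_cut(state, c1, c2)[["cut"]]
  denom <- 0.5 * (state$internal[[c1]][["ec"]] + state$internal[[c2]][["ec"]])
  if (denom < .EPS) {
    if (ec < .EPS) return(0)
    denom <- .EPS
  }
  ec / denom
}

#' Relative closeness of two clusters
#'
#' `RC = S-bar-EC{c1,c2} / (|c1|/(|c1|+|c2|) * S-bar-EC_c1 +
#' |c2|/(|c1|+|c2|) * S-bar-EC_c2)`: the mean cross-edge weight normalized
#' by the size-weighted mean internal bisection edge weights.  Zero
#' denominator handling as in [relative_interconnectivity()].
#'
#' @inheritParams relative_interconnectivity
#' @return RC >= 0.
#' @export
relative_closeness <- function(c1, c2, state) {
  sec <- .pair_cut(state, c1, c2)[["mean"]]
  n1 <- length(state$clusters[[c1]])
  n2 <- length(state$clusters[[c2]])
  denom <- (n1 * state$internal[[c1]][["sec"]] +
            n2 * state$internal[[c2]][["sec"]]) / (n1 + n2)
  if (denom < .EPS) {
    if (sec < .EPS) return(0)
    denom <- .EPS
  }
  sec / denom
}

#' Merge-criterion similarity of a cluster pair
#'
#' `S = RI * RC^alpha`, the classical Chameleon combination; `alpha`
#' balances interconnectivity against closeness (`alpha = 0` reduces to RI
#' alone).
#'
#' @param ri,rc Nonnegative relative interconnectivity / closeness.
#' @param alpha Closeness exponent (default 1).
#' @return A nonnegative scalar, nondecreasing in each argument.
#' @export
pair_similarity <- function(ri, rc, alpha = 1) {
  stopifnot(ri >= 0, rc >= 0)
  ri * rc^alpha
}

#' Initial partition by recursive balanced bisection
#'
#' Produces `k_init` clusters from the feature graph by repeatedly applying
#' [balanced_min_bisection()] to the currently largest cluster (ties: first
#' created).  With `k_init` equal to the vertex count the partition is all
#' singletons.
#'
#' @param graph A `feature_graph`.
#' @param k_init Target number of initial clusters.
#' @return A `cluster_state` with `k_init` clusters.
#' @export
initial_partition <- function(graph, k_init) {
  m <- length(graph$names)
  stopifnot(k_init >= 1L, k_init <= m)
  parts <- list(seq_len(m))
  while (length(parts) < k_init) {
    sizes <- vapply(parts, length, 1L)
    i <- which.max(sizes)
    b <- balanced_min_bisection(parts[[i]], graph)
    parts <- c(parts[-i], b$sides)
  }
  cluster_state(graph, parts)
}

#' Improved Chameleon merge loop
#'
#' Agglomerates the current partition down to `k_target` clusters.  At every
#' step the RI * RC^alpha similarity is evaluated for all current cluster
#' pairs - including clusters created by earlier merges, which is the
#' "improved" part of the algorithm (a plain pass would only consider the
#' initial sub-clusters) - and the most similar pair is merged, after which
#' the merged cluster's internal bisection cache is recomputed.  If every
#' pair has zero similarity the pair with the largest raw edge cut is
#' merged; if all cuts are zero too, the two smallest clusters are merged
#' (both fallbacks are recorded in the trace).
#'
#' @param state A `cluster_state`.
#' @param k_target Number of clusters to stop at (`1 <= k_target <= h`).
#' @param alpha Closeness exponent of [pair_similarity()].
#' @param merge_rule `"max"` (default) merges the most similar pair;
#'   `"min"` preserves, for auditability, the literal reading of the
#'   printed procedure (merge the least similar pair).
#' @return The merged `cluster_state`; `$trace` records one row per merge
#'   (step, clusters, RI, RC, similarity, h after, rule used).
#' @export
mchameleon_merge <- function(state, k_target, alpha = 1,
                             merge_rule = c("max", "min")) {
  merge_rule <- match.arg(merge_rule)
  stopifnot(inherits(state, "cluster_state"), k_target >= 1L)
  if (length(state$clusters) < k_target) {
    stop("state has fewer clusters than k_target")
  }
  step0 <- nrow(state$trace)
  step <- 0L
  while (length(state$clusters) > k_target) {
    ids <- names(state$clusters)
    h <- length(ids)
    pairs <- combn(h, 2L)
    ri <- rc <- s <- ec <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      a <- ids[pairs[1L, p]]
      b <- ids[pairs[2L, p]]
      ri[p] <- relative_interconnectivity(a, b, state)
      rc[p] <- relative_closeness(a, b, state)
      s[p] <- pair_similarity(ri[p], rc[p], alpha)
      ec[p] <- .pair_cut(state, a, b)[["cut"]]
    }
    rule <- "similarity"
    if (max(s) < .EPS && merge_rule == "max") {
      if (max(ec) >= .EPS) {
        rule <- "max_edge_cut"
        pick <- which.max(ec)
      } else {
        rule <- "smallest_pair"
        sizes <- vapply(state$clusters, length, 1L)
        ord <- order(sizes, seq_along(sizes))
        pick <- which(apply(pairs, 2L, function(pr) {
          setequal(pr, ord[1:2])
        }))[1L]
      }
      message("mchameleon_merge: all pair similarities zero; fallback rule ",
              rule)
    } else {
      pick <- if (merge_rule == "max") which.max(s) else which.min(s)
    }
    a <- ids[pairs[1L, pick]]
    b <- ids[pairs[2L, pick]]
    step <- step + 1L
    new_id <- paste0("C", state$next_id)
    members <- sort(c(state$clusters[[a]], state$clusters[[b]]))
    state$clusters[[a]] <- NULL
    state$clusters[[b]] <- NULL
    state$clusters[[new_id]] <- members
    state$internal[[a]] <- NULL
    state$internal[[b]] <- NULL
    state$internal[[new_id]] <- .cluster_internal(members, state$graph)
    state$next_id <- state$next_id + 1L
    state$trace <- rbind(state$trace, data.frame(
      step = step0 + step, cluster_a = a, cluster_b = b,
      ri = ri[pick], rc = rc[pick], similarity = s[pick],
      h_after = length(state$clusters), rule = rule,
      stringsAsFactors = FALSE))
  }
  state
}

#' Remove the features farthest from the target within each cluster
#'
#' The redundancy-removal rule used in the experiments: within every
#' cluster, each feature's distance to the target is the Euclidean distance
#' between the z-scored feature vector and the z-scored target after
#' aligning the feature's sign with the target (equivalently
#' `sqrt(2 (n-1) (1 - |r|))`, the monotone transform of the absolute
#' Pearson correlation that also weights the graph's edges - a feature and
#' its negation are equally informative about the target, so they must be
#' equally "far").  The `m_remove` largest-distance features per cluster
#' are dropped (never emptying a cluster: at most size - 1 are removed;
#' singletons are untouched).  Survivors keep the original column order.
#'
#' @param state A `cluster_state` over features of `fm`.
#' @param fm The `biafs_features` matrix the graph was built from.
#' @param target Numeric target vector.
#' @param m_remove Features to remove per cluster (default 1; 0 is the
#'   identity).
#' @return List with `selected` (surviving feature names, original order),
#'   `removed` (data frame: feature, cluster, distance) and `distances`
#'   (data frame: feature, cluster, distance, kept).
#' @export
prune_far_from_target <- function(state, fm, target, m_remove = 1L) {
  stopifnot(inherits(state, "cluster_state"), m_remove >= 0L)
  v <- if (inherits(fm, "biafs_features")) fm$values else as.matrix(fm)
  stopifnot(length(target) == nrow(v))
  zt <- as.numeric(scale(target))
  nms <- state$graph$names
  dist_to_target <- vapply(nms, function(f) {
    zf <- as.numeric(scale(v[, f]))
    if (anyNA(zf)) return(Inf)   # constant feature: maximally far
    min(sqrt(sum((zf - zt)^2)), sqrt(sum((zf + zt)^2)))  # sign-aligned
  }, numeric(1))
  rows <- do.call(rbind, lapply(names(state$clusters), function(id) {
    members <- nms[state$clusters[[id]]]
    d <- dist_to_target[members]
    n_rm <- min(m_remove, length(members) - 1L)
    drop <- if (n_rm > 0L) {
      members[order(-d, match(members, nms))][seq_len(n_rm)]
    } else {
      character(0)
    }
    data.frame(feature = members, cluster = id, distance = unname(d),
               kept = !members %in% drop, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(match(rows$feature, nms)), ]
  rownames(rows) <- NULL
  list(selected = rows$feature[rows$kept],
       removed = rows[!rows$kept, c("feature", "cluster", "distance")],
       distances = rows)
}

#' One representative feature per cluster
#'
#' The final step of the combined algorithm: from each cluster the feature
#' with the maximum HSIC score is chosen, so the optimal set X has exactly
#' one member per cluster.  Score ties are broken by the better (lower)
#' rank, which is itself stable in the original column order.
#'
#' @param state A `cluster_state`.
#' @param scores An `hsic_filter` table covering every clustered feature.
#' @return Character vector of selected feature names (original column
#'   order).
#' @export
select_representatives <- function(state, scores) {
  stopifnot(inherits(state, "cluster_state"))
  nms <- state$graph$names
  missing_scores <- setdiff(nms, scores$feature)
  if (length(missing_scores) > 0L) {
    stop("no HSIC score for feature(s): ",
         paste(missing_scores, collapse = ", "))
  }
  reps <- vapply(state$clusters, function(members) {
    tab <- scores[scores$feature %in% nms[members], ]
    tab$feature[order(-tab$hsic, tab$rank)][1L]
  }, character(1))
  reps[order(match(reps, nms))]
}

#' Recompute all cached cut quantities from scratch
#'
#' Test helper for cache consistency: rebuilds every cluster's internal
#' |EC|_f / S-bar-EC_f directly from the graph and reports the maximum
#' absolute deviation from the cached values.
#'
#' @param state A `cluster_state`.
#' @return Largest absolute cache discrepancy (0 when consistent).
#' @export
verify_cluster_cache <- function(state) {
  fresh <- lapply(state$clusters, .cluster_internal, graph = state$graph)
  max(vapply(names(state$clusters), function(id) {
    max(abs(fresh[[id]] - state$internal[[id]]))
  }, numeric(1)))
}

#' Write the merge trace / final clusters to CSV
#'
#' @param state A `cluster_state` after merging.
#' @param trace_path,clusters_path Output paths (either may be `NULL`).
#' @param distances Optional distance table from [prune_far_from_target()]
#'   to enrich the cluster CSV with `distance` and `kept`.
#' @return Invisibly, the list of paths written.
#' @export
write_cluster_csv <- function(state, trace_path = NULL, clusters_path = NULL,
                              distances = NULL) {
  if (!is.null(trace_path)) write.csv(state$trace, trace_path,
                                      row.names = FALSE)
  if (!is.null(clusters_path)) {
    tab <- do.call(rbind, lapply(names(state$clusters), function(id) {
      data.frame(feature = state$graph$names[state$clusters[[id]]],
                 cluster_id = id, stringsAsFactors = FALSE)
    }))
    if (!is.null(distances)) {
      tab <- merge(tab, distances[, c("feature", "distance", "kept")],
                   by = "feature", sort = FALSE)
    }
    tab <- tab[order(match(tab$feature, state$graph$names)), ]
    write.csv(tab, clusters_path, row.names = FALSE)
  }
  invisible(list(trace = trace_path, clusters = clusters_path))
}
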