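# shared fixtures: all built in code at test time

# minimal valid sample table (values arbitrary but physiologic)
toy_table <- function(n = 6, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = paste0("S", seq_len(n)),
    R1 = runif(n, 300, 500), R2 = runif(n, 300, 500),
    R3 = runif(n, 25, 40), R4 = runif(n, 200, 350),
    R5 = runif(n, 200, 350),
    A = runif(n, 20, 60), H = rnorm(n, 168, 7),
    W = runif(n, 50, 90), G = rep_len(c(0, 1), n),
    BFM = runif(n, 8, 35), TBW = runif(n, 25, 45),
    stringsAsFactors = FALSE)
}

write_toy_csv <- function(df, dir = tempdir()) {
  path <- tempfile("sample", tmpdir = dir, fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# build a feature_graph directly from an explicit weighted edge list so
# cluster-level operations can be tested on hand-enumerable toys
graph_from_edges <- function(names, edges) {
  m <- length(names)
  w <- matrix(0, m, m, dimnames = list(names, names))
  adj <- matrix(FALSE, m, m, dimnames = list(names, names))
  for (e in edges) {
    i <- match(e[[1]], names); j <- match(e[[2]], names)
    w[i, j] <- w[j, i] <- as.numeric(e[[3]])
    adj[i, j] <- adj[j, i] <- TRUE
  }
  structure(list(names = names, w = w, adj = adj, k_neighbors = NA_integer_),
            class = "feature_graph")
}

# independent oracle: balanced min bisection by direct enumeration
bisection_oracle <- function(members, graph) {
  nc <- length(members)
  half <- nc %/% 2L
  best <- Inf
  for (ix in utils::combn(nc, half, simplify = FALSE)) {
    a <- members[ix]; b <- members[-ix]
    cut <- sum(graph$w[a, b][graph$adj[a, b, drop = FALSE]])
    if (cut < best) best <- cut
  }
  best
}

# random weighted graph for property tests (block structure optional)
random_graph <- function(m, seed, p_edge = 0.5, blocks = NULL) {
  set.seed(seed)
  nms <- paste0("f", seq_len(m))
  w <- matrix(0, m, m, dimnames = list(nms, nms))
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    same <- !is.null(blocks) && blocks[i] == blocks[j]
    pe <- if (is.null(blocks)) p_edge else if (same) 0.9 else 0.15
    if (runif(1) < pe) {
      adj[i, j] <- adj[j, i] <- TRUE
      w[i, j] <- w[j, i] <- if (same) runif(1, 0.7, 1) else runif(1, 0, 0.3)
    }
  }
  # ensure degree >= 1
  for (i in which(rowSums(adj) == 0)) {
    j <- if (i == 1) 2L else i - 1L
    adj[i, j] <- adj[j, i] <- TRUE
    w[i, j] <- w[j, i] <- runif(1, 0.1, 0.5)
  }
  dimnames(adj) <- list(nms, nms)
  structure(list(names = nms, w = w, adj = adj, k_neighbors = NA_integer_),
            class = "feature_graph")
}

# direct empirical evaluation of the three-expectation HSIC expansion
direct_hsic_expansion <- function(K, L) {
  n <- nrow(K)
  t1 <- sum(K * L) / n^2
  t2 <- (sum(K) / n^2) * (sum(L) / n^2)
  t3 <- sum(rowMeans(K) * rowMeans(L)) / n
  t1 + t2 - 2 * t3
}
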