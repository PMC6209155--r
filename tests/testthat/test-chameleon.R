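test_that("feature similarity is |Pearson r| with unit diagonal", {
  set.seed(1)
  x <- rnorm(50)
  m <- cbind(a = x, b = -x, c = rnorm(50), d = x)
  s <- feature_similarity(m)
  expect_equal(s["a", "b"], 1)            # negation
  expect_equal(s["a", "d"], 1)            # duplicate
  expect_equal(diag(s), rep(1, 4), ignore_attr = TRUE)
  expect_equal(s, t(s))

  set.seed(2)
  big <- cbind(u = rnorm(1000), v = rnorm(1000))
  expect_lt(feature_similarity(big)["u", "v"], 0.1)

  cm <- cbind(a = rnorm(10), k = rep(1, 10))
  expect_warning(sc <- feature_similarity(cm), "constant")
  expect_equal(sc["a", "k"], 0)
})

test_that("kNN graph takes the symmetrized union with lexicographic ties", {
  set.seed(3)
  m <- 6
  sim <- abs(cor(matrix(rnorm(50 * m), 50)))
  dimnames(sim) <- list(letters[1:m], letters[1:m])
  g <- build_knn_graph(sim, m - 1L)
  expect_true(all(g$adj[upper.tri(g$adj)]))   # saturation: complete graph
  expect_equal(g$w[lower.tri(g$w)], sim[lower.tri(sim)])

  # two tight blocks with near-zero cross-similarity: no cross edges at k=2
  blocks <- matrix(0.01, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  blocks[1:3, 1:3] <- 0.9
  blocks[4:6, 4:6] <- 0.9
  diag(blocks) <- 1
  g2 <- build_knn_graph(blocks, 2L)
  expect_false(any(g2$adj[1:3, 4:6]))
  expect_true(all(rowSums(g2$adj) >= 1))

  # exact tie at the k-th neighbour: lexicographically smaller name wins
  tie <- matrix(0.5, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                           c("a", "b", "c", "d")))
  diag(tie) <- 1
  tie["a", "b"] <- tie["b", "a"] <- 0.9
  g3 <- build_knn_graph(tie, 1L)
  # a's single neighbour is b (highest); c and d tie everywhere -> pick "a"
  expect_true(g3$adj["c", "a"])
  expect_false(g3$adj["c", "d"])
})

test_that("balanced min bisection matches hand and enumeration oracles", {
  # path a-b: only split
  g <- graph_from_edges(c("a", "b"), list(list("a", "b", 0.7)))
  b <- balanced_min_bisection(c(1, 2), g)
  expect_equal(b$cut, 0.7)
  expect_equal(b$mean_cut, 0.7)

  # unit 4-cycle: best balanced split cuts opposite pairs, cost 2
  g4 <- graph_from_edges(letters[1:4], list(
    list("a", "b", 1), list("b", "c", 1), list("c", "d", 1),
    list("d", "a", 1)))
  expect_equal(balanced_min_bisection(1:4, g4)$cut, 2)

  # two unit triangles joined by one weak bridge: enumeration oracle
  tri <- graph_from_edges(letters[1:6], list(
    list("a", "b", 1), list("b", "c", 1), list("a", "c", 1),
    list("d", "e", 1), list("e", "f", 1), list("d", "f", 1),
    list("c", "d", 0.1)))
  b6 <- balanced_min_bisection(1:6, tri)
  expect_equal(b6$cut, bisection_oracle(1:6, tri))
  expect_equal(b6$cut, 0.1)
  expect_equal(sort(vapply(b6$sides, length, 1L)), c(3L, 3L))
})

test_that("heuristic bisection equals exhaustive enumeration (<= 14)", {
  for (s in 1:12) {
    m <- sample(4:14, 1)
    g <- random_graph(m, seed = 100 + s, p_edge = runif(1, 0.3, 0.9))
    exh <- balanced_min_bisection(seq_len(m), g, method = "exhaustive")
    heu <- balanced_min_bisection(seq_len(m), g, method = "heuristic")
    expect_equal(heu$cut, exh$cut, tolerance = 1e-12,
                 label = paste("heuristic cut, seed", 100 + s))
  }
})

test_that("RI and RC reproduce the hand-enumerated two-cluster toy", {
  # clusters {a,b} and {c,d}, internal edges weight 1, single cross 0.5
  g <- graph_from_edges(letters[1:4], list(
    list("a", "b", 1), list("c", "d", 1), list("b", "c", 0.5)))
  st <- cluster_state(g, list(c("a", "b"), c("c", "d")))
  expect_equal(relative_interconnectivity("C1", "C2", st), 0.5)
  expect_equal(relative_closeness("C1", "C2", st), 0.5)
  # symmetry
  expect_equal(relative_interconnectivity("C2", "C1", st), 0.5)

  # no cross edges -> both zero
  g0 <- graph_from_edges(letters[1:4], list(
    list("a", "b", 1), list("c", "d", 1)))
  st0 <- cluster_state(g0, list(c("a", "b"), c("c", "d")))
  expect_equal(relative_interconnectivity("C1", "C2", st0), 0)
  expect_equal(relative_closeness("C1", "C2", st0), 0)

  # identical internal and cross mean weights -> RC = 1
  geq <- graph_from_edges(letters[1:4], list(
    list("a", "b", 0.6), list("c", "d", 0.6), list("b", "c", 0.6)))
  steq <- cluster_state(geq, list(c("a", "b"), c("c", "d")))
  expect_equal(relative_closeness("C1", "C2", steq), 1)
})

test_that("pair similarity combines RI and RC monotonically", {
  expect_equal(pair_similarity(0, 0), 0)
  expect_equal(pair_similarity(0.4, 0.9, alpha = 0), 0.4)
  expect_equal(pair_similarity(0.5, 0.5, alpha = 2), 0.125)
  expect_gte(pair_similarity(0.6, 0.5), pair_similarity(0.5, 0.5))
})

test_that("initial partition recovers disconnected cliques and singletons", {
  cl <- list()
  for (i in 0:1) for (a in 1:3) for (b in 1:3) {
    if (a < b) cl <- c(cl, list(list(letters[3 * i + a], letters[3 * i + b],
                                     1)))
  }
  g <- graph_from_edges(letters[1:6], cl)
  st <- initial_partition(g, 2L)
  sides <- lapply(st$clusters, function(ix) sort(g$names[ix]))
  expect_setequal(vapply(sides, paste, "", collapse = ""),
                  c("abc", "def"))

  st_all <- initial_partition(g, 6L)
  expect_equal(length(st_all$clusters), 6L)
  expect_true(all(vapply(st_all$clusters, length, 1L) == 1L))
})

test_that("initial partition recovers planted blocks reachable by halving", {
  # recursive *balanced* bisection can only produce parts whose sizes arise
  # from repeated halving, so plant four blocks of three on 12 vertices:
  # 12 -> 6+6 (two block pairs) -> 3+3 each, all splits along block edges
  blocks <- rep(1:4, each = 3)
  g <- random_graph(12, seed = 77, blocks = blocks)
  st <- initial_partition(g, 4L)
  got <- vapply(lapply(st$clusters, sort), paste, "", collapse = ",")
  expect_setequal(got, c("1,2,3", "4,5,6", "7,8,9", "10,11,12"))
})

test_that("merge loop is a counting no-op at k_target and keeps caches", {
  g <- random_graph(10, seed = 5)
  st <- cluster_state(g)
  expect_identical(mchameleon_merge(st, 10L)$clusters, st$clusters)

  merged <- mchameleon_merge(st, 3L)
  expect_equal(length(merged$clusters), 3L)
  expect_equal(nrow(merged$trace), 7L)  # h_initial - k_target merges
  expect_equal(merged$trace$h_after, 9:3)
  expect_lt(verify_cluster_cache(merged), 1e-10)
})

test_that("duplicated feature pairs cluster together at k_target = 2", {
  set.seed(9)
  x <- rnorm(60); y <- rnorm(60)
  m <- cbind(x1 = x, x2 = x + rnorm(60, 0, 0.01),
             y1 = y, y2 = y + rnorm(60, 0, 0.01))
  sim <- feature_similarity(m)
  g <- build_knn_graph(sim, 2L)
  st <- mchameleon_merge(cluster_state(g), 2L)
  got <- lapply(st$clusters, function(ix) sort(g$names[ix]))

  # oracle: best 2-partition by total within-cluster similarity, enumerated
  parts <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                list(c(1, 4), c(2, 3)))
  within <- vapply(parts, function(p) {
    sum(vapply(p, function(ix) sum(sim[ix, ix]), 1))
  }, 1)
  best <- parts[[which.max(within)]]
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(best, function(ix) {
                    paste(sort(colnames(m)[ix]), collapse = ",")
                  }, ""))
})

test_that("cache consistency holds along random merge paths", {
  for (s in 1:4) {
    g <- random_graph(sample(8:18, 1), seed = 200 + s)
    st <- mchameleon_merge(cluster_state(g), sample(2:4, 1))
    expect_lt(verify_cluster_cache(st), 1e-10)
  }
})

test_that("pruning removes the farthest features but never empties a cluster", {
  set.seed(10)
  n <- 40
  t_vec <- rnorm(n)
  mk <- function(r) r * t_vec + sqrt(1 - r^2) * rnorm(n)
  feats <- c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5, 0.45, 0.4, 0.35, 0.3, 0.25,
             0.2, 0.15, 0.1)
  m <- vapply(feats, mk, numeric(n))
  colnames(m) <- paste0("f", seq_along(feats))
  g <- random_graph(14, seed = 11)
  g$names <- colnames(m)
  dimnames(g$w) <- dimnames(g$adj) <- list(g$names, g$names)
  st <- cluster_state(g, list(1:2, 3:7, 8:12, 13:14))  # sizes 2,5,5,2

  pr <- prune_far_from_target(st, m, t_vec, m_remove = 1L)
  expect_equal(length(pr$selected), 10L)                 # 14 - 4
  expect_equal(nrow(pr$removed), 4L)
  # survivors keep original order
  expect_identical(pr$selected,
                   intersect(colnames(m), pr$selected))
  # within each cluster the removed feature has the max distance
  for (id in names(st$clusters)) {
    rows <- pr$distances[pr$distances$cluster == id, ]
    expect_equal(rows$feature[which.max(rows$distance)],
                 rows$feature[!rows$kept])
  }

  expect_equal(prune_far_from_target(st, m, t_vec, 0L)$selected,
               colnames(m))

  st1 <- cluster_state(g, list(1L, 2:14))
  pr1 <- prune_far_from_target(st1, m, t_vec, 1L)
  expect_true("f1" %in% pr1$selected)   # singleton cluster untouched
  expect_equal(length(pr1$selected), 13L)
})

test_that("pruning distance is sign-invariant in the feature", {
  set.seed(12)
  t_vec <- rnorm(30)
  m <- cbind(pos = t_vec + rnorm(30, 0, 0.1),
             neg = -t_vec + rnorm(30, 0, 0.1),
             junk = rnorm(30))
  g <- build_knn_graph(feature_similarity(m), 1L)
  st <- cluster_state(g, list(1:3))
  pr <- prune_far_from_target(st, m, t_vec, 1L)
  expect_equal(pr$removed$feature, "junk")
})

test_that("representatives are the max-HSIC feature per cluster", {
  g <- graph_from_edges(c("a", "b", "c", "d"), list(
    list("a", "b", 0.9), list("c", "d", 0.9), list("b", "c", 0.1)))
  st <- cluster_state(g, list(c("a", "b"), c("c", "d")))
  scores <- structure(data.frame(
    feature = c("b", "a", "c", "d"), hsic = c(0.9, 0.5, 0.4, 0.4),
    p_value = rep(0.01, 4), rank = 1:4, kept = TRUE,
    stringsAsFactors = FALSE), class = c("hsic_filter", "data.frame"))
  reps <- select_representatives(st, scores)
  expect_equal(length(reps), 2L)
  expect_true("b" %in% reps)
  expect_true("c" %in% reps)   # tie 0.4/0.4 broken by lower rank (c)
  expect_error(select_representatives(st, scores[-1, ]), "b")
})

test_that("planted bilateral pairs are never split across final clusters", {
  n_seeds <- 30
  ok <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(100, seed = 300 + s)
    fmz <- zscore_normalize(expand_features(co$table))
    sim <- feature_similarity(fmz)
    g <- build_knn_graph(sim, 3L)
    st <- mchameleon_merge(cluster_state(g), 4L)
    members <- lapply(st$clusters, function(ix) g$names[ix])
    ok[s] <- all(vapply(co$truth$redundancy_groups, function(pair) {
      any(vapply(members, function(cl) all(pair %in% cl), logical(1)))
    }, logical(1)))
  }
  expect_gte(mean(ok), 0.95)
})
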