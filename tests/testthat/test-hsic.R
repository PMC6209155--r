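test_that("gram matrices match the kernel definitions", {
  expect_equal(gram_matrix(c(0, 1), kernel_spec("linear")),
               matrix(c(0, 0, 0, 1), 2))

  v <- rnorm(10)
  K <- gram_matrix(v, kernel_spec("rbf"))
  expect_equal(diag(K), rep(1, 10))
  expect_equal(K, t(K))

  # huge bandwidth: all points indistinguishable
  K_inf <- gram_matrix(c(-3, 0, 7), kernel_spec("rbf", 1e8))
  expect_equal(K_inf, matrix(1, 3, 3), tolerance = 1e-10)

  expect_error(kernel_spec("rbf", 0), "positive")
})

test_that("median bandwidth is the median non-zero pairwise difference", {
  expect_equal(median_bandwidth(c(0, 1, 2)), 1)
  expect_equal(median_bandwidth(c(0, 10)), 10)
  expect_equal(median_bandwidth(c(0, 0, 1)), 1)  # zero diffs dropped
  expect_error(median_bandwidth(c(5, 5, 5)), "constant")
})

test_that("trace-form HSIC equals the direct expectation expansion", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    K <- gram_matrix(rnorm(n), kernel_spec("rbf"))
    L <- gram_matrix(rnorm(n), kernel_spec("rbf"))
    # estimator scale is 1/(n-1)^2; the plain expansion is 1/n^2
    expect_equal(empirical_hsic(K, L) * (n - 1)^2 / n^2,
                 direct_hsic_expansion(K, L), tolerance = 1e-10)
  }
})

test_that("HSIC is zero for constants, symmetric, and nonnegative", {
  n <- 8
  K <- gram_matrix(rnorm(n), kernel_spec("rbf"))
  ones <- matrix(1, n, n)
  expect_equal(empirical_hsic(K, ones), 0, tolerance = 1e-12)
  L <- gram_matrix(rnorm(n), kernel_spec("linear"))
  expect_equal(empirical_hsic(K, L), empirical_hsic(L, K))
  expect_error(empirical_hsic(K, matrix(1, 3, 3)), "same size")
  set.seed(3)
  for (i in 1:20) {
    kind <- sample(c("rbf", "linear"), 2, replace = TRUE)
    K <- gram_matrix(rnorm(12), kernel_spec(kind[1]))
    L <- gram_matrix(rnorm(12), kernel_spec(kind[2]))
    expect_gte(empirical_hsic(K, L), -1e-12)
  }
})

test_that("hsic_score is affine invariant under the median heuristic", {
  set.seed(5)
  f <- rnorm(40)
  y <- f + rnorm(40, 0, 0.3)
  base <- hsic_score(f, y)$score
  expect_gt(base, 0)
  expect_equal(hsic_score(3.7 * f + 11, y)$score, base, tolerance = 1e-10)
  expect_warning(z <- hsic_score(rep(2, 40), y), "constant")
  expect_equal(z$score, 0, tolerance = 1e-12)
})

test_that("score is invariant under joint permutation of sample pairs", {
  set.seed(6)
  f <- rnorm(25)
  y <- 2 * f + rnorm(25)
  base <- hsic_score(f, y)$score
  for (i in 1:5) {
    p <- sample(25)
    expect_equal(hsic_score(f[p], y[p])$score, base, tolerance = 1e-10)
  }
})

test_that("a permuted-target feature scores inside its own null", {
  set.seed(8)
  n <- 1000
  y <- rnorm(n)
  f <- sample(y)   # same marginal, independent pairing
  pv <- permutation_pvalue(f, y, n_perm = 499, seed = 9)
  expect_gt(pv$p_value, 0.05)
  expect_lt(pv$score, quantile(pv$null_scores, 0.95))
})

test_that("permutation p-value formula and reproducibility", {
  set.seed(7)
  f <- rnorm(50)
  # target identical to feature: no permutation beats the identity pairing
  expect_equal(permutation_pvalue(f, f, n_perm = 99, seed = 1)$p_value,
               1 / 100)
  expect_equal(permutation_pvalue(f, f, n_perm = 19, seed = 1)$p_value,
               0.05)
  y <- rnorm(50)
  a <- permutation_pvalue(f, y, n_perm = 49, seed = 3)
  b <- permutation_pvalue(f, y, n_perm = 49, seed = 3)
  expect_identical(a$null_scores, b$null_scores)
})

test_that("rank_and_filter orders by score and applies alpha / top_k", {
  co <- simulate_cohort(60, seed = 2)
  fmz <- zscore_normalize(expand_features(co$table))
  y <- co$table$BFM

  all_kept <- rank_and_filter(fmz, y, top_k = 29L, n_perm = 49, seed = 1)
  expect_true(all(all_kept$kept))
  expect_equal(all_kept$rank, seq_len(29))
  expect_equal(order(all_kept$hsic, decreasing = TRUE), seq_len(29))

  lax <- rank_and_filter(fmz, y, alpha = 1, n_perm = 49, seed = 1)
  expect_true(all(lax$kept))

  expect_error(rank_and_filter(fmz, y, alpha = 1.5), "alpha")
})

test_that("planted generative features outrank pure-noise features", {
  co <- simulate_cohort(100, seed = 1)
  fmz <- zscore_normalize(expand_features(co$table))
  sc <- rank_and_filter(fmz, co$table$BFM, n_perm = 199, seed = 1)
  generative <- c("W", "A", "G", "R4", "R5", "1/R4", "1/R5",
                  "R4^2", "R5^2", "R4R5")
  noise <- co$truth$noise_features
  expect_lt(max(sc$rank[sc$feature %in% generative]),
            min(sc$rank[sc$feature %in% noise]))
})

test_that("rbf Gram matrices agree with an independent kernel library", {
  set.seed(14)
  v <- rnorm(20)
  h <- 1.3
  ours <- gram_matrix(v, kernel_spec("rbf", h))
  ref <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / (2 * h^2)),
                               matrix(v, ncol = 1))
  expect_equal(ours, ref@.Data, tolerance = 1e-12, ignore_attr = TRUE)

  lin <- gram_matrix(v, kernel_spec("linear"))
  ref_lin <- kernlab::kernelMatrix(kernlab::vanilladot(),
                                   matrix(v, ncol = 1))
  expect_equal(lin, ref_lin@.Data, tolerance = 1e-12, ignore_attr = TRUE)
})
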