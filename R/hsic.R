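#' Kernel specification
#'
#' @param kind `"rbf"` (Gaussian, `exp(-(x - x')^2 / (2 h^2))`) or
#'   `"linear"` (`x * x'`).
#' @param bandwidth For the rbf kernel: a positive bandwidth `h`, or
#'   `"median"` to use the median heuristic ([median_bandwidth()]).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), bandwidth = "median") {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.numeric(bandwidth)) {
      if (length(bandwidth) != 1L || !is.finite(bandwidth) || bandwidth <= 0) {
        stop("bandwidth must be a single positive number or \"median\"")
      }
    } else if (!identical(bandwidth, "median")) {
      stop("bandwidth must be a single positive number or \"median\"")
    }
  }
  structure(list(kind = kind, bandwidth = bandwidth), class = "kernel_spec")
}

#' Median-heuristic kernel bandwidth
#'
#' The median of the non-zero pairwise absolute differences of `v`.  This is
#' the usual scale-adaptive choice for the Gaussian kernel: an affine
#' transform `a * v + b` scales the bandwidth by `|a|`, leaving the Gram
#' matrix (and hence any HSIC score) unchanged.
#'
#' @param v Numeric vector with at least two distinct values.
#' @return A positive scalar.
#' @export
median_bandwidth <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 2L, all(is.finite(v)))
  d <- abs(outer(v, v, "-"))
  d <- d[upper.tri(d)]
  d <- d[d > 0]
  if (length(d) == 0L) stop("constant input: no non-zero pairwise differences")
  median(d)
}

#' Gram matrix of a univariate sample
#'
#' @param v Numeric vector (n >= 2, finite).
#' @param spec A [kernel_spec()].
#' @return An n x n symmetric positive semi-definite matrix; for the rbf
#'   kernel the diagonal is identically 1.
#' @export
gram_matrix <- function(v, spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"), is.numeric(v), length(v) >= 2L)
  if (any(!is.finite(v))) stop("non-finite values in kernel input")
  if (spec$kind == "linear") {
    return(outer(v, v))
  }
  h <- spec$bandwidth
  if (identical(h, "median")) h <- median_bandwidth(v)
  if (h <= 0) stop("rbf bandwidth must be positive")
  d <- outer(v, v, "-")
  exp(-(d * d) / (2 * h * h))
}

# double centring: H M H with H = I - (1/n) 11'
.centre_gram <- function(M) {
  rm <- rowMeans(M)
  sweep(sweep(M, 1L, rm, "-"), 2L, colMeans(M) - mean(rm), "-")
}

#' Empirical HSIC from two Gram matrices
#'
#' The biased plug-in estimator of the squared Hilbert-Schmidt norm of the
#' cross-covariance operator between the two kernel embeddings:
#' `tr(K H L H) / (n - 1)^2`, with `H` the centring matrix.  Zero iff the
#' embedded samples are empirically uncorrelated in feature space; for
#' characteristic kernels the population quantity is zero iff the variables
#' are independent.
#'
#' @param K,L Same-size symmetric Gram matrices.
#' @return A scalar, nonnegative (up to ~1e-12 rounding) for PSD inputs and
#'   symmetric in `(K, L)`.
#' @export
empirical_hsic <- function(K, L) {
  if (!is.matrix(K) || !is.matrix(L) || nrow(K) != ncol(K) ||
      !all(dim(K) == dim(L))) {
    stop("K and L must be square matrices of the same size")
  }
  n <- nrow(K)
  sum(.centre_gram(K) * L) / (n - 1)^2
}

#' HSIC relevance score of one feature against a target
#'
#' @param feature,target Equal-length numeric vectors (n >= 4).
#' @param fspec,cspec Kernel specifications for the feature and the target.
#' @return A list with `score` (empirical HSIC) and the bandwidths actually
#'   used.  A constant feature under the rbf kernel scores 0 with a warning
#'   (bandwidth falls back to 1).
#' @export
hsic_score <- function(feature, target, fspec = kernel_spec(),
                       cspec = kernel_spec()) {
  stopifnot(length(feature) == length(target), length(feature) >= 4L)
  ks <- .gram_with_fallback(feature, fspec, "feature")
  ls <- .gram_with_fallback(target, cspec, "target")
  list(score = empirical_hsic(ks$gram, ls$gram),
       bandwidth_feature = ks$bandwidth, bandwidth_target = ls$bandwidth)
}

.gram_with_fallback <- function(v, spec, what) {
  bw <- NA_real_
  if (spec$kind == "rbf") {
    bw <- spec$bandwidth
    if (identical(bw, "median")) {
      bw <- tryCatch(median_bandwidth(v), error = function(e) {
        warning("constant ", what, ": rbf bandwidth fallback 1, HSIC will be 0")
        1
      })
    }
    spec <- kernel_spec("rbf", bw)
  }
  list(gram = gram_matrix(v, spec), bandwidth = bw)
}

#' Permutation p-value for HSIC independence
#'
#' Tests independence of `feature` and `target` by comparing the observed
#' HSIC score with its null distribution under random permutation of the
#' target.  `p = (1 + #{permuted score >= observed}) / (n_perm + 1)`.
#'
#' @param feature,target Equal-length numeric vectors.
#' @param fspec,cspec Kernel specifications.
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed making the draw reproducible.
#' @return A list with `p_value`, `score`, and the vector of permuted
#'   `null_scores`.
#' @export
permutation_pvalue <- function(feature, target, fspec = kernel_spec(),
                               cspec = kernel_spec(), n_perm = 999L,
                               seed = 1L) {
  stopifnot(length(feature) == length(target), n_perm >= 19L)
  n <- length(feature)
  K <- .gram_with_fallback(feature, fspec, "feature")$gram
  L <- .gram_with_fallback(target, cspec, "target")$gram
  Lc <- .centre_gram(L)
  obs <- sum(K * Lc) / (n - 1)^2
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  null_scores <- .hsic_perm_stats(K, Lc, P)
  list(p_value = (1 + sum(null_scores >= obs)) / (n_perm + 1),
       score = obs, null_scores = null_scores)
}

#' Rank features by HSIC and apply the confidence filter
#'
#' Stage 1 of the selection pipeline: every (non-constant) column of the
#' feature matrix is scored against the target with empirical HSIC, features
#' are ranked by descending score (ties broken by original column order),
#' and the filter retains either the features whose permutation p-value is
#' at most `alpha` (the default, `alpha = 0.20`, mirrors an 80% confidence
#' screen) or the `top_k` best-scoring features.
#'
#' One shared set of `n_perm` target permutations (drawn from `seed`) is
#' used for every feature, so p-values are comparable across features and
#' the whole scan costs one permutation draw.
#'
#' @param fm A `biafs_features` matrix (z-scored recommended; constant
#'   columns are excluded from scoring).
#' @param target Numeric target vector (length = rows of `fm`).
#' @param fspec,cspec Kernel specifications.
#' @param alpha Retain features with `p <= alpha`; used when `top_k` is
#'   `NULL`.
#' @param top_k Retain the `top_k` best-scoring features instead of the
#'   p-value rule.
#' @param n_perm,seed Permutation-test settings.
#' @return An object of class `hsic_filter`: a data frame with columns
#'   `feature`, `hsic`, `p_value`, `rank`, `kept`, ordered by rank, plus
#'   attributes recording the settings.  The stage-1 survivor set F' is
#'   `x$feature[x$kept]`.
#' @export
rank_and_filter <- function(fm, target, fspec = kernel_spec(),
                            cspec = kernel_spec(), alpha = 0.20,
                            top_k = NULL, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(fm, "biafs_features"))
  v <- fm$values
  stopifnot(length(target) == nrow(v))
  if (is.null(top_k)) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
      stop("alpha must be in (0, 1]")
    }
  } else {
    stopifnot(top_k >= 1L)
  }
  usable <- which(!fm$constant)
  if (length(usable) == 0L) stop("no non-constant features to score")
  n <- nrow(v)
  L <- .gram_with_fallback(target, cspec, "target")$gram
  Lc <- .centre_gram(L)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  score <- p_value <- rep(NA_real_, ncol(v))
  for (j in usable) {
    K <- .gram_with_fallback(v[, j], fspec, colnames(v)[j])$gram
    score[j] <- sum(K * Lc) / (n - 1)^2
    null_scores <- .hsic_perm_stats(K, Lc, P)
    p_value[j] <- (1 + sum(null_scores >= score[j])) / (n_perm + 1)
  }
  ord <- order(-score[usable], usable)
  idx <- usable[ord]
  res <- data.frame(feature = colnames(v)[idx], hsic = score[idx],
                    p_value = p_value[idx], rank = seq_along(idx),
                    stringsAsFactors = FALSE)
  res$kept <- if (is.null(top_k)) {
    res$p_value <= alpha
  } else {
    res$rank <= top_k
  }
  if (!any(res$kept)) {
    stop("no features survive the filter; increase alpha or use top_k")
  }
  structure(res, class = c("hsic_filter", "data.frame"),
            alpha = if (is.null(top_k)) alpha else NA_real_,
            top_k = if (is.null(top_k)) NA_integer_ else as.integer(top_k),
            n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Write an HSIC score table to CSV
#'
#' Machine-readable form of the per-feature relevance bars: one row per
#' feature with `feature`, `hsic`, `p_value`, `rank`, `kept`.
#'
#' @param scores An `hsic_filter` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
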