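#' Deterministic train/test split in file order
#'
#' The evaluation protocol trains on the first `n_train` subjects in table
#' order and tests on the remainder (for a 100-subject cohort with the
#' default `n_train = 80`: first 80 train, last 20 test).
#'
#' @param table A sample table (data frame).
#' @param n_train Number of training rows (default 80); `nrow(table)` must
#'   exceed it.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, n_train = 80L) {
  n <- nrow(table)
  if (n <= n_train) {
    stop("need more than n_train = ", n_train, " rows, got ", n)
  }
  list(train = table[seq_len(n_train), , drop = FALSE],
       test = table[(n_train + 1L):n, , drop = FALSE])
}

#' Ordinary least-squares fit with model summary
#'
#' Fits `y ~ X` with an intercept by QR least squares and reports the
#' summary statistics used to compare candidate feature sets: the multiple
#' correlation `R = sqrt(R^2)`, `R^2`, adjusted `R^2 = 1 - (1 - R^2)(n - 1)
#' / (n - p - 1)`, and the standard error of estimate `SEE =
#' sqrt(RSS / (n - p - 1))`.
#'
#' @param X n x p numeric matrix of predictors (column names kept).
#' @param y Numeric response vector.
#' @return A `biafs_ols` object: `intercept`, `coefficients` (named),
#'   `r`, `r2`, `adj_r2`, `see`, `n`, `p`, `fitted`, `residuals`.
#'   Rank-deficient predictor sets are an error naming a minimal dependent
#'   column set.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1L) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dep <- setdiff(colnames(Xi), colnames(Xi)[qx$pivot[seq_len(qx$rank)]])
    stop("predictor matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- lm.fit(Xi, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(intercept = unname(fit$coefficients[1L]),
                 coefficients = fit$coefficients[-1L],
                 r = sqrt(max(r2, 0)), r2 = r2, adj_r2 = adj_r2,
                 see = sqrt(rss / (n - p - 1)), n = n, p = p,
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "biafs_ols")
}

#' @export
print.biafs_ols <- function(x, digits = 4, ...) {
  cat("OLS fit: n =", x$n, ", p =", x$p, "\n")
  cat(sprintf("  R = %.*f  R2 = %.*f  adj R2 = %.*f  SEE = %.*f\n",
              digits, x$r, digits, x$r2, digits, x$adj_r2, digits, x$see))
  invisible(x)
}

#' Predict from an OLS fit (or a printed prediction equation)
#'
#' @param object A `biafs_ols`.
#' @param newdata Matrix or data frame containing every predictor column.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.biafs_ols <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata, check.names = FALSE))
  missing_cols <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(missing_cols) > 0L) {
    stop("missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  drop(newdata[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients) + object$intercept
}

#' Held-out relative prediction errors
#'
#' `|prediction - actual| / |actual|` per test subject.  Subjects with a
#' zero actual value are flagged `NA` and excluded from the reported
#' maximum and mean.
#'
#' @param model A `biafs_ols`.
#' @param X_test Test predictor matrix (must contain the model's columns).
#' @param y_test Actual target values.
#' @return Numeric vector of relative errors with attributes `max` and
#'   `mean` (computed over the non-flagged entries).
#' @export
relative_errors <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)
  stopifnot(length(pred) == length(y_test))
  rel <- abs(pred - y_test) / abs(y_test)
  rel[y_test == 0] <- NA_real_
  if (anyNA(rel)) {
    message("relative_errors: ", sum(is.na(rel)),
            " zero actual value(s) excluded")
  }
  structure(rel, max = max(rel, na.rm = TRUE), mean = mean(rel, na.rm = TRUE))
}

#' Evaluate a feature set on a sample table
#'
#' Convenience wrapper: expand the table's features, split train/test in
#' file order, fit OLS on the selected columns, and report the model
#' summary plus held-out relative errors.
#'
#' @param table A sample table with the target column.
#' @param features Character vector of expanded-feature names to use.
#' @param target Target column name (default `"BFM"`).
#' @param n_train Training rows (default 80).
#' @return List with `model` (`biafs_ols`), `relative_errors`,
#'   `max_relative_error`, `mean_relative_error`.
#' @export
evaluate_features <- function(table, features, target = "BFM",
                              n_train = 80L) {
  stopifnot(target %in% names(table))
  fm <- expand_features(table)
  missing_cols <- setdiff(features, colnames(fm$values))
  if (length(missing_cols) > 0L) {
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  idx <- split_train_test(data.frame(i = seq_len(n)), n_train)
  Xall <- fm$values[, features, drop = FALSE]
  y <- table[[target]]
  model <- fit_ols(Xall[idx$train$i, , drop = FALSE], y[idx$train$i])
  rel <- relative_errors(model, Xall[idx$test$i, , drop = FALSE],
                         y[idx$test$i])
  list(model = model, relative_errors = rel,
       max_relative_error = attr(rel, "max"),
       mean_relative_error = attr(rel, "mean"))
}

#' The published BFM prediction equations
#'
#' The three printed body-fat prediction equations (one per candidate
#' feature set) ship as fixtures so they can be applied to new tables.  The
#' sex indicator is named `G` here (the source tables use `S` and `G`
#' interchangeably for the same binary column).  Coefficients are applied
#' to raw (unstandardized) feature values as printed; `BFM3` has no
#' constant term.
#'
#' @return Named list of equations; each has `intercept` and a named
#'   `coefficients` vector over expanded-feature names.
#' @export
printed_bfm_models <- function() {
  list(
    BFM1 = list(intercept = -8.56, coefficients = c(
      W = 0.041, G = 0.126, A = 0.523, R3 = -0.212, `1/R1` = 0.171,
      `1/R2` = 0.126, `1/R3` = 0.179, `R4^2` = 1.132, R4R5 = 0.13,
      `R5^2` = 0.127)),
    BFM2 = list(intercept = 5.674, coefficients = c(
      W = 0.313, G = -0.044, `1/R3` = -0.125, `1/R1` = 0.108,
      `R4^2` = 0.016, `R2^2` = -0.01, `R5^2` = 0.071, R4R5 = 0.072,
      R5 = -0.526)),
    BFM3 = list(intercept = 0, coefficients = c(
      A = 0.464, H = -0.15, W = 0.122, R5 = -0.143, R1R2 = 0.129,
      R2R3 = 0.122, R4R5 = -0.134, `1/R5` = 0.145, `R2^2` = 0.129,
      `R5^2` = -0.141))
  )
}

#' Apply a fixed prediction equation to feature rows
#'
#' @param equation A list with `intercept` and named `coefficients`
#'   (e.g. one element of [printed_bfm_models()]).
#' @param row A named numeric vector, or a matrix/data frame of expanded
#'   features, containing every referenced feature.
#' @return Numeric prediction(s): intercept + dot product.
#' @export
apply_printed_model <- function(equation, row) {
  stopifnot(is.list(equation), !is.null(equation$coefficients))
  cf <- equation$coefficients
  if (is.null(dim(row))) {
    missing_cols <- setdiff(names(cf), names(row))
    if (length(missing_cols) > 0L) {
      stop("missing feature(s): ", paste(missing_cols, collapse = ", "))
    }
    return(sum(cf * unlist(row)[names(cf)]) + equation$intercept)
  }
  row <- as.matrix(as.data.frame(row, check.names = FALSE))
  missing_cols <- setdiff(names(cf), colnames(row))
  if (length(missing_cols) > 0L) {
    stop("missing feature(s): ", paste(missing_cols, collapse = ", "))
  }
  drop(row[, names(cf), drop = FALSE] %*% cf) + equation$intercept
}

#' Export model summaries as a CSV table
#'
#' One row per fitted model with the columns R, R2, adjusted R2, SEE.
#'
#' @param models Named list of `biafs_ols` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_summary_csv <- function(models, path) {
  tab <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(model = nm, r = m$r, r2 = m$r2, adj_r2 = m$adj_r2,
               see = m$see, n = m$n, p = m$p, stringsAsFactors = FALSE)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
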