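#' Canonical column names of a bioimpedance sample table
#'
#' A sample table holds one row per subject: the five segmental impedances
#' `R1`..`R5` (left arm, right arm, trunk, left leg, right leg; ohms, one
#' frequency band per table), age `A` (years), height `H` (cm), weight `W`
#' (kg), optionally the binary sex indicator `G`, and one or more continuous
#' body-composition targets (`BFM`, `TBW`, ... in kg).
#'
#' @keywords internal
#' @name sample_table
NULL

.impedance_cols <- c("R1", "R2", "R3", "R4", "R5")
.required_cols  <- c(.impedance_cols, "A", "H", "W")

#' Read and validate a bioimpedance sample table
#'
#' Reads a delimited text file (or, optionally, an XLSX workbook) into a
#' validated sample table.  Rows with missing or non-numeric required values,
#' or with a non-positive impedance (reciprocal features must exist), are
#' dropped with a message reporting the count.
#'
#' @param path Path to the input file.
#' @param format `"csv"` (comma-separated, header row, UTF-8; the canonical
#'   interchange format) or `"xlsx"` (requires the `readxl` package).
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(R1 = "LA_imp", BFM = "bodyfat")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param band Frequency-band label attached to the table (e.g. `"250kHz"`);
#'   purely descriptive.
#' @param sheet Sheet name or index for XLSX input (default: first sheet).
#'
#' @return A `data.frame` with columns `subject_id`, `R1`..`R5`, `A`, `H`,
#'   `W`, optionally `G`, and any remaining numeric columns kept as targets.
#'   Attributes: `band`, `n_dropped` (rows rejected during ingest).
#' @export
read_sample_table <- function(path, format = c("csv", "xlsx"),
                              column_map = NULL, band = NULL, sheet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  raw <- switch(format,
    csv = read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(
        if (is.null(sheet)) readxl::read_excel(path)
        else readxl::read_excel(path, sheet = sheet),
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
  )
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(raw)) {
        stop("mapped column not found in file: ", src, " (for ", canonical, ")")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_sample_table(raw, band = band)
}

#' Validate an in-memory sample table
#'
#' Enforces the sample-table invariants: required columns present and
#' numeric, impedances strictly positive, no missing values in required
#' fields, at least two rows surviving.  Offending rows are dropped (with a
#' message); structural problems are fatal.
#'
#' @param df A data frame with the columns described in
#'   [read_sample_table()].
#' @param band Optional frequency-band label.
#' @return The validated data frame (attributes `band`, `n_dropped`).
#' @export
validate_sample_table <- function(df, band = NULL) {
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_cols <- c(.required_cols, intersect("G", names(df)))
  num <- df
  for (cl in check_cols) {
    num[[cl]] <- suppressWarnings(as.numeric(as.character(df[[cl]])))
  }
  bad_numeric <- Reduce(`|`, lapply(check_cols, function(cl) is.na(num[[cl]])))
  bad_imped <- Reduce(`|`, lapply(.impedance_cols, function(cl) {
    !is.na(num[[cl]]) & num[[cl]] <= 0
  }))
  drop <- bad_numeric | bad_imped
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message("read_sample_table: dropped ", n_dropped,
            " row(s) with missing/non-numeric fields or non-positive impedance")
  }
  out <- num[!drop, , drop = FALSE]
  if (nrow(out) < 2L) {
    stop("fewer than 2 valid rows after ingest (", nrow(out), ")")
  }
  if (!"subject_id" %in% names(out)) {
    out <- cbind(subject_id = paste0("S", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
  }
  if ("G" %in% names(out) && !all(out$G %in% c(0, 1))) {
    stop("sex column G must be binary 0/1")
  }
  rownames(out) <- NULL
  attr(out, "band") <- band
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Expanded feature names in canonical order
#'
#' @param include_sex Include the binary sex indicator `G`.
#' @return Character vector of 29 (or 28) feature names: `R1..R5, A, H, W,
#'   [G]`, the five reciprocals `1/Ri`, the ten pairwise products `RiRj`
#'   (i < j), and the five squares `Ri^2`.
#' @export
feature_names_expanded <- function(include_sex = TRUE) {
  prods <- combn(5L, 2L)
  c(.impedance_cols, "A", "H", "W", if (include_sex) "G",
    paste0("1/", .impedance_cols),
    paste0("R", prods[1L, ], "R", prods[2L, ]),
    paste0(.impedance_cols, "^2"))
}

#' Build the expanded bioimpedance feature matrix
#'
#' Expands a sample table into the standard 29-column candidate feature set:
#' the primary measurements (`R1`..`R5`, `A`, `H`, `W`, and `G` when
#' present), the reciprocal of each segmental impedance `1/Ri`, every
#' pairwise impedance product `RiRj`, and each square `Ri^2`.  Column order
#' is fixed and documented in [feature_names_expanded()].
#'
#' @param table A validated sample table (see [read_sample_table()]).
#' @param include_sex Include `G` as a primary feature (default: yes, when
#'   the column is present).
#' @return An object of class `biafs_features`: list with `values`
#'   (n x m numeric matrix with column names), `kind` (per-column label in
#'   `primary`, `reciprocal`, `product`, `square`), `normalization`
#'   (`"none"` or `"zscore"`), and, after z-scoring, `center`, `scale`, and
#'   the logical `constant` flag.
#' @export
expand_features <- function(table, include_sex = "G" %in% names(table)) {
  if (include_sex && !"G" %in% names(table)) {
    stop("include_sex = TRUE but table has no column G")
  }
  missing_cols <- setdiff(.required_cols, names(table))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  R <- as.matrix(table[, .impedance_cols, drop = FALSE])
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("impedances must be finite and strictly positive")
  }
  prods <- combn(5L, 2L)
  values <- cbind(
    R,
    A = table$A, H = table$H, W = table$W,
    if (include_sex) matrix(table$G, ncol = 1L, dimnames = list(NULL, "G")),
    1 / R,
    R[, prods[1L, ], drop = FALSE] * R[, prods[2L, ], drop = FALSE],
    R * R
  )
  colnames(values) <- feature_names_expanded(include_sex)
  kind <- c(rep("primary", 8L + include_sex),
            rep("reciprocal", 5L), rep("product", 10L), rep("square", 5L))
  names(kind) <- colnames(values)
  structure(list(values = values, kind = kind, normalization = "none",
                 center = NULL, scale = NULL,
                 constant = setNames(rep(FALSE, ncol(values)),
                                     colnames(values))),
            class = "biafs_features")
}

#' @export
print.biafs_features <- function(x, ...) {
  cat("biafs feature matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", x$normalization, ")\n", sep = "")
  if (any(x$constant)) {
    cat("constant columns:", paste(names(which(x$constant)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Z-score a feature matrix
#'
#' Centres every column to mean 0 and scales it to unit sample standard
#' deviation (n - 1 denominator).  Constant columns are flagged, left
#' unscaled (sd recorded as 0), and excluded from downstream scoring; the
#' stored per-column mean/sd make the transform exactly invertible via
#' [zscore_denormalize()].
#'
#' @param fm A `biafs_features` object with `normalization == "none"`.
#' @return The normalized `biafs_features` object.
#' @export
zscore_normalize <- function(fm) {
  stopifnot(inherits(fm, "biafs_features"))
  if (fm$normalization != "none") {
    stop("feature matrix is already normalized")
  }
  v <- fm$values
  if (nrow(v) < 2L) stop("z-scoring needs at least 2 samples")
  mu <- colMeans(v)
  sig <- apply(v, 2L, sd)
  constant <- !is.finite(sig) | sig < .EPS * pmax(1, abs(mu))
  if (any(constant)) {
    warning("constant column(s) flagged and left unscaled: ",
            paste(colnames(v)[constant], collapse = ", "))
    sig[constant] <- 0
  }
  out <- v
  keep <- !constant
  out[, keep] <- sweep(sweep(v[, keep, drop = FALSE], 2L, mu[keep], "-"),
                       2L, sig[keep], "/")
  fm$values <- out
  fm$normalization <- "zscore"
  fm$center <- mu
  fm$scale <- sig
  fm$constant <- constant
  fm
}

#' Invert a z-score normalization
#'
#' @param fm A z-scored `biafs_features` object.
#' @return The feature matrix on its original scale.
#' @export
zscore_denormalize <- function(fm) {
  stopifnot(inherits(fm, "biafs_features"))
  if (fm$normalization != "zscore") stop("feature matrix is not z-scored")
  v <- fm$values
  keep <- !fm$constant
  v[, keep] <- sweep(sweep(v[, keep, drop = FALSE], 2L, fm$scale[keep], "*"),
                     2L, fm$center[keep], "+")
  fm$values <- v
  fm$normalization <- "none"
  fm$center <- NULL
  fm$scale <- NULL
  fm
}
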