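#' Read an expression matrix from a tab-delimited file
#'
#' Expression matrices are plain numeric matrices: genes in rows (unique
#' identifiers as rownames), arrays in columns (unique identifiers as
#' colnames). The on-disk dialect is tab-delimited text with array
#' identifiers in the first (header) row and gene identifiers in the first
#' column; empty cells and the token `NA` denote missing values.
#'
#' @param path Path to a tab-delimited file.
#' @param role Either `"knowledge"` (a large compendium used to learn
#'   coexpression structure) or `"dataset"` (per-replicate log expression
#'   ratios of the experiment of interest). The role is attached as an
#'   attribute and does not change parsing.
#' @return A numeric matrix with gene rownames and array colnames; missing
#'   cells are `NA`.
#' @seealso [write_expression_matrix()] for the paired writer.
#' @export
read_expression_matrix <- function(path, role = c("knowledge", "dataset")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    blank.lines.skip = FALSE)
  if (ncol(raw) < 2L) {
    stop("malformed header in ", path,
         ": expected a gene-identifier column followed by array columns",
         call. = FALSE)
  }
  array_ids <- colnames(raw)[-1L]
  if (anyDuplicated(array_ids)) {
    stop("duplicate array identifier(s): ",
         paste(unique(array_ids[duplicated(array_ids)]), collapse = ", "),
         call. = FALSE)
  }
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing <- cells == "" | cells == "NA"
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !missing, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell at gene '", gene_ids[bad[1L, 1L]],
         "', array '", array_ids[bad[1L, 2L]], "': \"",
         cells[bad[1L, , drop = FALSE]], "\"", call. = FALSE)
  }
  values[missing] <- NA_real_
  dimnames(values) <- list(gene_ids, array_ids)
  attr(values, "role") <- role
  values
}

#' Write an expression matrix as tab-delimited text
#'
#' Emits the same dialect that [read_expression_matrix()] consumes, with
#' full double precision so that a write/read round trip reproduces the
#' matrix exactly.
#'
#' @param x Numeric matrix with gene rownames and array colnames.
#' @param path Output file path.
#' @param na Token used for missing values (`"NA"` or `""`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, na = "NA") {
  x <- validate_expression_matrix(x, allow_missing = TRUE)
  chr <- sprintf("%.17g", x)
  chr[is.na(x)] <- na
  dim(chr) <- dim(x)
  lines <- c(
    paste(c("gene_id", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], chr[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

validate_expression_matrix <- function(x, allow_missing = TRUE,
                                       arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`", arg, "` must have gene rownames and array colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers in `", arg, "`", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate array identifiers in `", arg, "`", call. = FALSE)
  }
  if (!allow_missing && anyNA(x)) {
    stop("`", arg, "` contains missing values; run complete_matrix() first",
         call. = FALSE)
  }
  x
}

#' Log-transform and quantile normalize arrays
#'
#' Puts all arrays on the same scale: after an optional log2 step, each
#' column is replaced by the cross-column means of the order statistics, so
#' every complete column carries the identical multiset of values. Tied
#' values receive the mean of their ranks' pooled means, and missing entries
#' are excluded from rank pooling and remain missing.
#'
#' @param x Expression matrix (genes x arrays).
#' @param log2_transform If `TRUE` (default) the values are log2-transformed
#'   first; all values must then be strictly positive. Set to `FALSE` for
#'   data already on a log scale.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
normalize_arrays <- function(x, log2_transform = TRUE) {
  x <- validate_expression_matrix(x)
  if (log2_transform) {
    if (any(x <= 0, na.rm = TRUE)) {
      stop("non-positive values present; cannot log-transform ",
           "(set log2_transform = FALSE for pre-logged data)", call. = FALSE)
    }
    x <- log2(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Complete an expression matrix with missing values
#'
#' Missing data are handled the way large compendia are prepared for SVD:
#' when fewer than `max_incomplete_frac` of the arrays contain any missing
#' value, those arrays are simply dropped; otherwise every missing entry is
#' imputed as the unweighted mean of the `k` nearest genes (Euclidean
#' distance over the columns where both genes are observed) that are
#' observed at that array.
#'
#' @param x Expression matrix, possibly with `NA` entries.
#' @param max_incomplete_frac Fraction of incomplete arrays below which the
#'   exclusion branch is taken (default 0.10).
#' @param k Number of neighbor genes for imputation (default 10).
#' @param seed Optional integer seed; only used to break exact distance ties
#'   reproducibly.
#' @return A matrix with no missing entries. Retained values are never
#'   altered by the exclusion branch.
#' @export
complete_matrix <- function(x, max_incomplete_frac = 0.10, k = 10,
                            seed = NULL) {
  x <- validate_expression_matrix(x)
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("gene(s) missing in all arrays: ",
         paste(head(rownames(x)[all_missing], 5), collapse = ", "),
         call. = FALSE)
  }
  incomplete <- colSums(is.na(x)) > 0L
  if (!any(incomplete)) {
    return(x)
  }
  if (mean(incomplete) < max_incomplete_frac) {
    return(x[, !incomplete, drop = FALSE])
  }
  knn_impute(x, k = k, seed = seed)
}

# Unweighted k-nearest-gene mean imputation. Distances are mean squared
# differences over shared observed columns, so genes with different
# missingness patterns remain comparable.
knn_impute <- function(x, k, seed = NULL) {
  complete_genes <- rowSums(is.na(x)) == 0L
  if (sum(complete_genes) < k) {
    stop("k = ", k, " exceeds the ", sum(complete_genes),
         " genes with complete data", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tie_noise <- runif(nrow(x), 0, 1e-9)
  out <- x
  for (i in which(rowSums(is.na(x)) > 0L)) {
    obs_i <- !is.na(x[i, ])
    diffs <- sweep(x[, obs_i, drop = FALSE], 2, x[i, obs_i], "-")
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[i] <- Inf
    for (j in which(is.na(x[i, ]))) {
      candidates <- which(!is.na(x[, j]) & is.finite(d2))
      if (length(candidates) < k) {
        stop("fewer than k = ", k, " candidate neighbors for gene '",
             rownames(x)[i], "' at array '", colnames(x)[j], "'",
             call. = FALSE)
      }
      nn <- candidates[order(d2[candidates] + tie_noise[candidates])[seq_len(k)]]
      out[i, j] <- mean(x[nn, j])
    }
  }
  out
}

#' Center and scale the rows of a complete expression matrix
#'
#' Every gene is brought to mean 0 and sample standard deviation 1, the
#' standardization applied before singular value decomposition of a
#' knowledge compendium. Idempotent up to numerical tolerance.
#'
#' @param x Complete expression matrix.
#' @return The row-standardized matrix.
#' @export
standardize_rows <- function(x) {
  x <- validate_expression_matrix(x, allow_missing = FALSE)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    stop("constant row(s), cannot standardize: ",
         paste(head(rownames(x)[s == 0], 5), collapse = ", "), call. = FALSE)
  }
  (x - mu) / s
}

#' Prepare a knowledge compendium for decomposition
#'
#' Convenience pipeline fixing the preprocessing order: missing-data
#' handling, then log/quantile normalization, then row standardization.
#'
#' @inheritParams complete_matrix
#' @inheritParams normalize_arrays
#' @return A complete, normalized, row-standardized matrix ready for
#'   [sagat_decompose()].
#' @export
prepare_knowledge <- function(x, log2_transform = TRUE,
                              max_incomplete_frac = 0.10, k = 10,
                              seed = NULL) {
  x |>
    complete_matrix(max_incomplete_frac = max_incomplete_frac, k = k,
                    seed = seed) |>
    normalize_arrays(log2_transform = log2_transform) |>
    standardize_rows()
}
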