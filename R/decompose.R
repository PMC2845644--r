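#' Singular value decomposition of a knowledge compendium
#'
#' Decomposes a preprocessed (complete, row-standardized) genes x arrays
#' matrix `X` into `X = U diag(S) V'`. Columns of `U` are eigenarrays,
#' columns of `V` are eigengenes, and `diag(S) V'` is the scaled
#' eigengenes x arrays representation of the knowledge. The sign of each
#' singular-vector pair is fixed so that the largest-magnitude entry of each
#' column of `U` is positive, making the decomposition reproducible.
#'
#' @param x Complete, row-standardized expression matrix with at least two
#'   rows and two columns.
#' @return An object of class `sagat_decomposition` with elements `u`, `d`
#'   (nonincreasing singular values), `v`, `gene_ids`, `array_ids`.
#' @export
sagat_decompose <- function(x) {
  x <- validate_expression_matrix(x, allow_missing = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 genes and 2 arrays to decompose", call. = FALSE)
  }
  sv <- svd(x)
  # sign convention: largest-magnitude entry of each left singular vector > 0
  flip <- vapply(seq_len(ncol(sv$u)), function(j) {
    col <- sv$u[, j]
    sign(col[which.max(abs(col))]) < 0
  }, logical(1))
  sv$u[, flip] <- -sv$u[, flip]
  sv$v[, flip] <- -sv$v[, flip]
  structure(
    list(u = sv$u, d = sv$d, v = sv$v,
         gene_ids = rownames(x), array_ids = colnames(x)),
    class = "sagat_decomposition"
  )
}

#' @export
print.sagat_decomposition <- function(x, ...) {
  cat("<sagat_decomposition> ", length(x$gene_ids), " genes x ",
      length(x$array_ids), " arrays, ", length(x$d),
      " singular values\n", sep = "")
  invisible(x)
}

#' @describeIn sagat_decompose One row per component: singular value and
#'   fraction of variance explained.
#' @param object,x A `sagat_decomposition`, for the `tidy()`, `glance()`
#'   and `autoplot()` methods.
#' @param ... Unused, for method consistency.
#' @export
tidy.sagat_decomposition <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$d),
    singular_value = x$d,
    variance_explained = x$d^2 / sum(x$d^2)
  )
}

#' @describeIn sagat_decompose One-row summary of the decomposition.
#' @export
glance.sagat_decomposition <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_arrays = length(x$array_ids),
    n_components = length(x$d),
    numeric_rank = sum(x$d > max(dim2(x)) * .Machine$double.eps * x$d[1]),
    default_m = choose_m_default(length(x$array_ids))
  )
}

dim2 <- function(d) c(length(d$gene_ids), length(d$array_ids))

#' @describeIn sagat_decompose Scree plot of variance explained per
#'   component.
#' @export
autoplot.sagat_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "eigengene component",
                  y = "fraction of variance explained") +
    ggplot2::theme_minimal()
}

#' Default eigengene count
#'
#' The default number of eigengenes is approximately half the number of
#' arrays in the compendium (rounded half up, minimum 1), the value found to
#' be near-optimal across platforms.
#'
#' @param n_arrays Number of arrays in the compendium (>= 2).
#' @return An integer eigengene count.
#' @examples
#' choose_m_default(4440) # 2220
#' @export
choose_m_default <- function(n_arrays) {
  if (!is.numeric(n_arrays) || length(n_arrays) != 1L || n_arrays < 2) {
    stop("`n_arrays` must be a single number >= 2", call. = FALSE)
  }
  max(1L, as.integer(floor(n_arrays / 2 + 0.5)))
}

#' Extract the truncated weight matrix W
#'
#' `W` is the matrix of the first `m` columns of `U` (the `m` most
#' significant eigenarrays); it maps genes to eigengenes and has orthonormal
#' columns, so projection of a dataset into eigengene space is `W' D`
#' (equivalently, projection by the pseudoinverse of `W`).
#'
#' @param decomposition A [sagat_decompose()] result.
#' @param m Eigengene count, `1 <= m <= ncol(U)`. Defaults to
#'   [choose_m_default()] of the compendium's array count.
#' @return An object of class `sagat_weights`: list with `w` (genes x `m`
#'   matrix, gene rownames), `m`, and `gene_ids`.
#' @export
weight_matrix <- function(decomposition, m = NULL) {
  stopifnot(inherits(decomposition, "sagat_decomposition"))
  if (is.null(m)) m <- choose_m_default(length(decomposition$array_ids))
  if (!is.numeric(m) || length(m) != 1L || m < 1 ||
      m > ncol(decomposition$u) || m != as.integer(m)) {
    stop("`m` must be an integer in [1, ", ncol(decomposition$u), "]",
         call. = FALSE)
  }
  w <- decomposition$u[, seq_len(m), drop = FALSE]
  rownames(w) <- decomposition$gene_ids
  structure(list(w = w, m = as.integer(m),
                 gene_ids = decomposition$gene_ids),
            class = "sagat_weights")
}

#' @export
print.sagat_weights <- function(x, ...) {
  cat("<sagat_weights> ", length(x$gene_ids), " genes x ", x$m,
      " eigengenes\n", sep = "")
  invisible(x)
}

#' Save or load a decomposition
#'
#' Persists the factors (or just the truncated weight matrix, to save
#' space) to a single-file RDS container.
#'
#' @param decomposition A `sagat_decomposition` or `sagat_weights` object.
#' @param path File path (conventionally `.rds`).
#' @return `save_decomposition()` returns `path` invisibly;
#'   `load_decomposition()` returns the stored object.
#' @export
save_decomposition <- function(decomposition, path) {
  stopifnot(inherits(decomposition, c("sagat_decomposition", "sagat_weights")))
  saveRDS(decomposition, path)
  invisible(path)
}

#' @rdname save_decomposition
#' @export
load_decomposition <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("sagat_decomposition", "sagat_weights"))) {
    stop("file does not contain a decomposition or weight matrix",
         call. = FALSE)
  }
  obj
}

#' Tune the eigengene count on labeled data subsets
#'
#' Evaluates SAGAT across a grid of eigengene counts `m` on one or more
#' small data subsets against a gold standard, and returns the grid value
#' maximizing the mean ROC AUC (ties resolved toward the smallest `m`)
#' together with the full AUC curve.
#'
#' @param data_subsets A list of dataset expression matrices (genes x
#'   replicates), gene identifiers matching the decomposition.
#' @param gold Named binary vector of gold-standard DE labels covering the
#'   score-able genes.
#' @param decomposition A [sagat_decompose()] result for the compendium.
#' @param grid Integer vector of candidate `m` values; default multiples of
#'   5 from 5 to the number of compendium components.
#' @return An object of class `sagat_tune_m`: list with `best_m` and
#'   `curve`, a tibble with columns `m` and `mean_auc`.
#' @export
tune_m <- function(data_subsets, gold, decomposition, grid = NULL) {
  stopifnot(inherits(decomposition, "sagat_decomposition"))
  if (is.matrix(data_subsets)) data_subsets <- list(data_subsets)
  if (is.null(grid)) {
    grid <- seq(5L, ncol(decomposition$u), by = 5L)
  }
  if (length(grid) == 0L) {
    stop("`grid` must contain at least one eigengene count", call. = FALSE)
  }
  mean_auc <- vapply(grid, function(m) {
    w <- weight_matrix(decomposition, m)
    mean(vapply(data_subsets, function(d) {
      tab <- sagat_score(d, w)
      roc_auc(setNames(tab$score, tab$gene_id), gold)
    }, numeric(1)))
  }, numeric(1))
  curve <- tibble::tibble(m = as.integer(grid), mean_auc = mean_auc)
  structure(list(best_m = curve$m[which.max(curve$mean_auc)], curve = curve),
            class = "sagat_tune_m")
}

#' @export
print.sagat_tune_m <- function(x, ...) {
  cat("<sagat_tune_m> best m =", x$best_m, "over", nrow(x$curve),
      "grid values\n")
  invisible(x)
}

#' @describeIn tune_m AUC versus eigengene count, best value marked.
#' @param object A `sagat_tune_m` object.
#' @param ... Unused.
#' @export
autoplot.sagat_tune_m <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$m, .data$mean_auc)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_vline(xintercept = object$best_m, color = "darkgreen",
                        linetype = "dashed") +
    ggplot2::labs(x = "number of eigengenes (M)", y = "mean ROC AUC") +
    ggplot2::theme_minimal()
}
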