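#' Binarized gene-gene covariance matrix
#'
#' Computes the gene-gene sample covariance across arrays (pairwise
#' complete observations, so missing values are ignored) and discretizes
#' it: entries whose absolute value exceeds `threshold` are set to one,
#' everything else to zero, and the diagonal is set to one.
#'
#' @param x Expression matrix (genes x arrays) with at least two arrays;
#'   log-normalized but not row-standardized values (row standardization
#'   would turn covariance into correlation).
#' @param threshold Covariance cutoff (default 0.25).
#' @return A symmetric genes x genes integer 0/1 matrix with unit diagonal.
#' @export
binarize_covariance <- function(x, threshold = 0.25) {
  x <- validate_expression_matrix(x)
  if (ncol(x) < 2L) {
    stop("covariance needs at least two arrays", call. = FALSE)
  }
  cv <- if (anyNA(x)) {
    cov(t(x), use = "pairwise.complete.obs")
  } else {
    xc <- x - rowMeans(x)
    tcrossprod(xc) / (ncol(x) - 1L)
  }
  b <- (abs(cv) > threshold)
  diag(b) <- TRUE
  storage.mode(b) <- "integer"
  dimnames(b) <- list(rownames(x), rownames(x))
  b
}

# Pairwise distances between rows of a binary matrix.
# jaccard: 1 - |intersection| / |union| (asymmetric binary, as dist("binary"));
# hamming: proportion of disagreeing entries.
binary_row_dist <- function(b, distance = c("jaccard", "hamming")) {
  distance <- match.arg(distance)
  if (distance == "hamming") {
    return(dist(b, method = "manhattan") / ncol(b))
  }
  inter <- tcrossprod(b)
  ones <- rowSums(b)
  un <- outer(ones, ones, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  as.dist(d)
}

#' Hierarchical biclustering order of a binary covariance matrix
#'
#' Orders genes by agglomerative clustering of the rows of the binarized
#' covariance matrix (complete linkage on a binary row distance); the same
#' permutation is applied to rows and columns, making coordinated groups
#' appear as diagonal blocks. Deterministic for a fixed input.
#'
#' @param b Symmetric binary matrix from [binarize_covariance()].
#' @param distance Binary row distance: `"jaccard"` (default) or
#'   `"hamming"`.
#' @return An integer permutation of the gene indices (dendrogram leaf
#'   order).
#' @export
bicluster_order <- function(b, distance = c("jaccard", "hamming")) {
  stopifnot(is.matrix(b))
  hclust(binary_row_dist(b, distance), method = "complete")$order
}

#' Extract expression modules from an ordered binary matrix
#'
#' An expression module is a group of genes whose pairwise binarized
#' covariances are all nonzero, appearing as an all-ones diagonal block
#' after biclustering. The reordered matrix is scanned left to right for
#' maximal contiguous diagonal runs in which every pairwise entry is one;
#' after a run shorter than `min_size` the scan advances by a single
#' position (so a module is still found when a chance-connected neighbor
#' precedes it), and accepted runs are disjoint and maximal.
#'
#' @param b Symmetric binary matrix.
#' @param order Gene permutation, typically from [bicluster_order()].
#' @param min_size Minimum module size (15 at compendium scale, relaxed to 5
#'   for 1000-gene subsets).
#' @param threshold Covariance cutoff used to build `b`, recorded in the
#'   result.
#' @return An object of class `module_set`: list with `modules` (list of
#'   gene-id character vectors), `min_size`, `ordering`, and `threshold`.
#' @export
extract_modules <- function(b, order, min_size, threshold = NA_real_) {
  stopifnot(is.matrix(b), length(order) == nrow(b))
  gene_ids <- rownames(b)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(b)))
  bo <- b[order, order, drop = FALSE]
  n <- nrow(bo)
  modules <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && all(bo[i:(j + 1L), j + 1L] == 1L)) j <- j + 1L
    if (j - i + 1L >= min_size) {
      modules[[length(modules) + 1L]] <- gene_ids[order[i:j]]
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(modules = modules, min_size = min_size, ordering = order,
                 threshold = threshold),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set> ", length(x$modules), " modules of size >= ",
      x$min_size, if (length(x$modules)) paste0(
        " (sizes ", paste(lengths(x$modules), collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn extract_modules One row per gene in a module.
#' @param x,... A `module_set` and unused arguments.
#' @export
tidy.module_set <- function(x, ...) {
  if (length(x$modules) == 0L) {
    return(tibble::tibble(module = integer(), gene_id = character()))
  }
  tibble::tibble(
    module = rep(seq_along(x$modules), lengths(x$modules)),
    gene_id = unlist(x$modules, use.names = FALSE)
  )
}

#' Detect coexpression modules in an expression matrix
#'
#' Full pipeline: binarize the covariance matrix, bicluster, and extract
#' all-ones diagonal blocks.
#'
#' @inheritParams binarize_covariance
#' @inheritParams bicluster_order
#' @inheritParams extract_modules
#' @return A `module_set` (see [extract_modules()]).
#' @export
find_modules <- function(x, threshold = 0.25, min_size = 15,
                         distance = c("jaccard", "hamming")) {
  b <- binarize_covariance(x, threshold)
  ord <- bicluster_order(b, distance)
  extract_modules(b, ord, min_size, threshold = threshold)
}

#' Permutation null for module detection
#'
#' Tests whether observed modularity could arise by chance: the columns of
#' each row are permuted independently of the other rows, destroying
#' gene-gene covariance while preserving marginal distributions, and the
#' full binarize/bicluster/extract pipeline is rerun on each permuted
#' matrix.
#'
#' @inheritParams find_modules
#' @param n_perm Number of permuted matrices (default 100).
#' @param seed Integer seed.
#' @return A tibble with one row per permutation: `perm`, `n_modules`
#'   (modules of size >= `min_size`), and `max_block` (largest all-ones
#'   diagonal run of size >= 2, or 1 if none).
#' @export
permutation_null <- function(x, n_perm = 100, min_size = 15,
                             threshold = 0.25, seed = 1L,
                             distance = c("jaccard", "hamming")) {
  x <- validate_expression_matrix(x)
  distance <- match.arg(distance)
  stopifnot(n_perm >= 1)
  set.seed(seed)
  res <- lapply(seq_len(n_perm), function(p) {
    xp <- x
    for (i in seq_len(nrow(xp))) xp[i, ] <- xp[i, sample(ncol(xp))]
    b <- binarize_covariance(xp, threshold)
    ord <- bicluster_order(b, distance)
    ms <- extract_modules(b, ord, min_size, threshold)
    runs <- extract_modules(b, ord, 2L, threshold)
    tibble::tibble(
      perm = p,
      n_modules = length(ms$modules),
      max_block = if (length(runs$modules)) max(lengths(runs$modules)) else 1L
    )
  })
  dplyr::bind_rows(res)
}

#' Module membership statistics
#'
#' Summarizes a module set against per-gene DE labels: mean module size and
#' the proportions of DE and non-DE genes found inside modules.
#'
#' @param module_set A `module_set` from [extract_modules()] or
#'   [find_modules()].
#' @param de_labels Named binary vector (1 = DE) covering at least the
#'   module genes.
#' @return A one-row tibble: `n_modules`, `mean_module_size`,
#'   `prop_de_in_modules`, `prop_nonde_in_modules` (proportions of each
#'   label class; 0 when a class is absent).
#' @export
module_membership_stats <- function(module_set, de_labels) {
  stopifnot(inherits(module_set, "module_set"))
  in_mod <- unlist(module_set$modules, use.names = FALSE)
  if (length(in_mod) > 0L && anyNA(de_labels[in_mod])) {
    stop("`de_labels` must cover all module genes", call. = FALSE)
  }
  de_genes <- names(de_labels)[de_labels == 1]
  nonde_genes <- names(de_labels)[de_labels == 0]
  prop <- function(class_genes) {
    if (length(class_genes) == 0L) 0 else mean(class_genes %in% in_mod)
  }
  tibble::tibble(
    n_modules = length(module_set$modules),
    mean_module_size = if (length(module_set$modules)) {
      mean(lengths(module_set$modules))
    } else 0,
    prop_de_in_modules = prop(de_genes),
    prop_nonde_in_modules = prop(nonde_genes)
  )
}
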