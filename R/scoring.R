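#' Align a dataset with a weight matrix
#'
#' Restricts and reorders both objects to their common gene identifiers
#' (in the weight matrix's order) and reports genes present on only one
#' side. Genes absent from the weight matrix are never silently scored.
#'
#' @param dataset Dataset expression matrix (genes x replicates).
#' @param weights A [weight_matrix()] result.
#' @return A list with `dataset`, `weights`, and `dropped` (a list with
#'   `dataset_only` and `weights_only` identifier vectors).
#' @export
align_genes <- function(dataset, weights) {
  dataset <- validate_expression_matrix(dataset)
  stopifnot(inherits(weights, "sagat_weights"))
  common <- intersect(weights$gene_ids, rownames(dataset))
  if (length(common) == 0L) {
    stop("no gene identifiers shared between dataset and weight matrix",
         call. = FALSE)
  }
  dropped <- list(
    dataset_only = setdiff(rownames(dataset), common),
    weights_only = setdiff(weights$gene_ids, common)
  )
  w <- weights$w[common, , drop = FALSE]
  list(
    dataset = dataset[common, , drop = FALSE],
    weights = structure(list(w = w, m = weights$m, gene_ids = common),
                        class = "sagat_weights"),
    dropped = dropped
  )
}

#' Project a dataset into eigengene space
#'
#' Computes the pseudoinverse projection `Ehat = W' D` of a dataset of
#' per-replicate log expression ratios, the least-squares-optimal
#' representation of the dataset in the compendium's eigengene space, plus
#' per-eigengene mean log ratios and (for two or more replicates) sample
#' variances.
#'
#' @param dataset Complete dataset matrix, genes already aligned to the
#'   weight matrix (see [align_genes()]).
#' @param weights A [weight_matrix()] result with matching gene order.
#' @return An object of class `sagat_projection`: list with `ehat` (`m` x
#'   replicates), `eigengene_means`, `raw_variances` (`NULL` when there is a
#'   single replicate), and `m_replicates`.
#' @export
project_dataset <- function(dataset, weights) {
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  stopifnot(inherits(weights, "sagat_weights"))
  if (ncol(dataset) == 0L) {
    stop("dataset has no replicate columns", call. = FALSE)
  }
  if (!identical(rownames(dataset), weights$gene_ids)) {
    stop("dataset genes do not match the weight matrix; ",
         "run align_genes() first", call. = FALSE)
  }
  ehat <- crossprod(weights$w, dataset)
  m <- ncol(dataset)
  structure(
    list(
      ehat = ehat,
      eigengene_means = rowMeans(ehat),
      raw_variances = if (m > 1L) apply(ehat, 1, var) else NULL,
      m_replicates = m
    ),
    class = "sagat_projection"
  )
}

#' @export
print.sagat_projection <- function(x, ...) {
  cat("<sagat_projection> ", nrow(x$ehat), " eigengenes x ",
      x$m_replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes moderation of eigengene variances
#'
#' Shrinks raw sample variances toward a prior fitted across units by the
#' standard moderated-t machinery: a scaled inverse-chi-square prior
#' `(d0, s0^2)` is estimated by moment matching on the log variances
#' (trigamma inversion, via [limma::squeezeVar()]), and each variance is
#' replaced by the posterior mean `(d0 s0^2 + df s^2) / (d0 + df)`.
#'
#' @param raw Numeric vector of raw sample variances.
#' @param df Residual degrees of freedom of each variance (replicates minus
#'   one).
#' @param d0 Optional override of the prior degrees of freedom. `d0 = 0`
#'   disables shrinkage; a finite positive value requires `s0_sq`;
#'   `Inf` shrinks completely to `s0_sq` (estimated if not given).
#' @param s0_sq Optional override of the prior variance.
#' @return An object of class `sagat_moderated`: list with `s_tilde_sq`,
#'   `d0`, `s0_sq`, and `df`.
#' @export
moderate_variances <- function(raw, df, d0 = NULL, s0_sq = NULL) {
  if (!is.numeric(raw) || length(raw) < 2L) {
    stop("`raw` must contain at least 2 variances", call. = FALSE)
  }
  if (any(raw < 0)) stop("negative variance supplied", call. = FALSE)
  if (all(raw == 0)) {
    stop("all raw variances are zero; nothing to moderate", call. = FALSE)
  }
  if (is.null(d0)) {
    sq <- limma::squeezeVar(raw, df = df)
    d0 <- sq$df.prior
    s0_sq <- sq$var.prior
    post <- sq$var.post
  } else {
    if (d0 == 0) {
      if (is.null(s0_sq)) s0_sq <- NA_real_
      post <- raw
    } else {
      if (is.null(s0_sq)) {
        s0_sq <- limma::squeezeVar(raw, df = df)$var.prior
      }
      post <- if (is.infinite(d0)) rep(s0_sq, length(raw)) else {
        (d0 * s0_sq + df * raw) / (d0 + df)
      }
    }
  }
  structure(list(s_tilde_sq = unname(post), d0 = unname(d0),
                 s0_sq = unname(s0_sq), df = df),
            class = "sagat_moderated")
}

#' @export
print.sagat_moderated <- function(x, ...) {
  cat("<sagat_moderated> ", length(x$s_tilde_sq), " variances, d0 = ",
      format(x$d0, digits = 4), ", s0^2 = ", format(x$s0_sq, digits = 4),
      "\n", sep = "")
  invisible(x)
}

score_table <- function(gene_ids, score, metric) {
  tibble::tibble(
    gene_id = gene_ids,
    score = unname(score),
    rank = rank(-abs(score), ties.method = "average")
  ) |>
    structure(metric = metric)
}

#' SAGAT scores for a replicated dataset
#'
#' The SAGAT score for gene `i` is a one-sample t-like statistic
#' `T_i = dbar_i / sqrt( (1/m) * sum_j w_ij^2 s~_j^2 )`, where `dbar_i` is
#' the gene's mean log ratio over `m` replicates, `w_ij` its eigengene
#' weights, and `s~_j^2` the moderated eigengene variances. Because the
#' standard error pools variances of shared eigengenes, coexpressed genes
#' borrow expression-variability information from one another.
#'
#' @param dataset Complete dataset matrix with at least two replicate
#'   columns, aligned to `weights`.
#' @param weights A [weight_matrix()] result.
#' @param moderated Optional [moderate_variances()] result; computed from
#'   the projection's raw eigengene variances when omitted.
#' @return A tibble with columns `gene_id`, `score`, and `rank`
#'   (by decreasing `|score|`, average ranks for ties).
#' @seealso [sagat_score()] for automatic dispatch on the replicate count,
#'   [sagat_scores_single()] for single-replicate data.
#' @export
sagat_scores <- function(dataset, weights, moderated = NULL) {
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  if (ncol(dataset) < 2L) {
    stop("sagat_scores() needs m >= 2 replicates; ",
         "use sagat_scores_single() for one replicate", call. = FALSE)
  }
  proj <- project_dataset(dataset, weights)
  if (is.null(moderated)) {
    moderated <- moderate_variances(proj$raw_variances,
                                    df = proj$m_replicates - 1L)
  }
  stopifnot(inherits(moderated, "sagat_moderated"))
  m <- proj$m_replicates
  se2 <- as.vector(weights$w^2 %*% moderated$s_tilde_sq) / m
  if (any(se2 <= 0)) {
    stop("zero SAGAT standard error for gene(s): ",
         paste(head(weights$gene_ids[se2 <= 0], 5), collapse = ", "),
         call. = FALSE)
  }
  score_table(weights$gene_ids, rowMeans(dataset) / sqrt(se2), "sagat")
}

#' SAGAT scores for a single-replicate dataset
#'
#' With one replicate, eigengene sample variances are undefined and the
#' single eigengene log ratios stand in for them:
#' `T_i = d_i / sqrt( sum_j w_ij^2 |e_j| )`, with `e = W'd` the dataset in
#' eigengene space. The variance surrogate is kept behind a named strategy
#' so alternatives can be swapped in.
#'
#' @param dataset Complete dataset matrix with exactly one column.
#' @param weights A [weight_matrix()] result.
#' @param variance_surrogate Strategy for the per-eigengene variance
#'   surrogate: `"abs_e"` (default) uses `|e_j|`.
#' @return A tibble with columns `gene_id`, `score`, and `rank`.
#' @export
sagat_scores_single <- function(dataset, weights,
                                variance_surrogate = c("abs_e")) {
  variance_surrogate <- match.arg(variance_surrogate)
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  if (ncol(dataset) != 1L) {
    stop("sagat_scores_single() is for exactly one replicate", call. = FALSE)
  }
  proj <- project_dataset(dataset, weights)
  surrogate <- abs(proj$ehat[, 1L])
  se2 <- as.vector(weights$w^2 %*% surrogate)
  if (any(se2 <= 0)) {
    stop("zero SAGAT standard error for gene(s): ",
         paste(head(weights$gene_ids[se2 <= 0], 5), collapse = ", "),
         call. = FALSE)
  }
  score_table(weights$gene_ids, dataset[, 1L] / sqrt(se2), "sagat")
}

#' @describeIn sagat_scores Dispatches to [sagat_scores()] or
#'   [sagat_scores_single()] based on the replicate count.
#' @export
sagat_score <- function(dataset, weights, moderated = NULL) {
  if (ncol(dataset) == 1L) {
    sagat_scores_single(dataset, weights)
  } else {
    sagat_scores(dataset, weights, moderated = moderated)
  }
}

#' Fold-change scores
#'
#' The comparison baseline: each gene's mean log expression ratio across
#' replicates.
#'
#' @param dataset Complete dataset matrix (genes x replicates).
#' @return A tibble with columns `gene_id`, `score`, and `rank`.
#' @export
fold_change_scores <- function(dataset) {
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  score_table(rownames(dataset), rowMeans(dataset), "fold_change")
}

#' One-sample moderated t scores
#'
#' Gene-level empirical-Bayes moderated t statistic
#' `dbar_i / sqrt(s~_i^2 / m)`, the same moderation machinery as
#' [moderate_variances()] applied to per-gene variances. Requires two or
#' more replicates.
#'
#' @param dataset Complete dataset matrix with at least two replicates.
#' @param d0,s0_sq Optional prior overrides passed to
#'   [moderate_variances()]; `d0 = 0` yields the ordinary one-sample t.
#' @return A tibble with columns `gene_id`, `score`, and `rank`.
#' @export
moderated_t_scores <- function(dataset, d0 = NULL, s0_sq = NULL) {
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  m <- ncol(dataset)
  if (m < 2L) {
    stop("the moderated t requires two or more replicates", call. = FALSE)
  }
  s2 <- apply(dataset, 1, var)
  mod <- moderate_variances(s2, df = m - 1L, d0 = d0, s0_sq = s0_sq)
  score_table(rownames(dataset), rowMeans(dataset) / sqrt(mod$s_tilde_sq / m),
              "moderated_t")
}

#' Permutation p-values for SAGAT scores
#'
#' The null distribution of the SAGAT score is complex, so significance is
#' assessed by data permutation: replicate columns are sign-flipped at
#' random, scores recomputed, and each gene's p-value is the fraction of
#' permutations (plus-one corrected) whose absolute score meets or exceeds
#' the observed one.
#'
#' @param dataset Complete dataset matrix with at least two replicates
#'   (single-replicate sign flips leave `|T|` unchanged).
#' @param weights A [weight_matrix()] result.
#' @param n_perm Number of sign-flip permutations (default 100).
#' @param seed Integer seed.
#' @return The [sagat_scores()] tibble with an additional `perm_p` column.
#' @export
sagat_perm_pvalues <- function(dataset, weights, n_perm = 100, seed = 1L) {
  dataset <- validate_expression_matrix(dataset, allow_missing = FALSE)
  m <- ncol(dataset)
  if (m < 2L) {
    stop("permutation p-values require two or more replicates", call. = FALSE)
  }
  observed <- sagat_scores(dataset, weights)
  set.seed(seed)
  exceed <- numeric(nrow(observed))
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), m, replace = TRUE)
    perm <- sweep(dataset, 2, flips, "*")
    exceed <- exceed +
      (abs(sagat_scores(perm, weights)$score) >= abs(observed$score))
  }
  observed$perm_p <- (1 + exceed) / (1 + n_perm)
  observed
}
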