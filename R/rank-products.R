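#' Rank products across platforms
#'
#' Integrates per-platform gene scores by the rank-products statistic: on
#' each platform genes are ranked by signed score (rank 1 = most
#' upregulated for `direction = "up"`, most downregulated for `"down"`,
#' average ranks for ties), and each gene's RP is the geometric mean of its
#' ranks across the `K` platforms. Up- and downregulation are analyzed as
#' separate lists. A small RP marks a gene consistently extreme on all
#' platforms.
#'
#' @param score_tables List (>= 2) of per-platform score tables: tibbles or
#'   data frames with columns `gene_id` and `score`. The gene universe is
#'   the identifier intersection; dropped genes are reported via the
#'   `dropped` attribute.
#' @param direction `"up"` or `"down"`.
#' @return A tibble with columns `gene_id`, `direction`, and `rp`
#'   (in `[1, n_genes]`), attribute `n_platforms`.
#' @export
rank_products <- function(score_tables, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.list(score_tables) || length(score_tables) < 2L) {
    stop("need score tables from at least two platforms", call. = FALSE)
  }
  ids <- lapply(score_tables, function(t) t$gene_id)
  common <- Reduce(intersect, ids)
  if (length(common) == 0L) {
    stop("no gene identifiers shared across all platforms", call. = FALSE)
  }
  dropped <- unique(unlist(lapply(ids, setdiff, common)))
  ranks <- vapply(score_tables, function(t) {
    s <- t$score[match(common, t$gene_id)]
    if (direction == "up") rank(-s, ties.method = "average")
    else rank(s, ties.method = "average")
  }, numeric(length(common)))
  out <- tibble::tibble(
    gene_id = common,
    direction = direction,
    rp = exp(rowMeans(log(ranks)))
  )
  attr(out, "n_platforms") <- length(score_tables)
  attr(out, "dropped") <- dropped
  out
}

#' Permutation-based per-family error rate for rank products
#'
#' Controls the expected number of false positives (PFER), a multiplicity
#' correction stricter than the FDR: under the null, each platform's ranks
#' are independently and uniformly permuted, null RPs computed, and
#' `PFER(g)` is the mean count per permutation of null RPs at or below the
#' observed `RP(g)`. Genes are typically called significant at
#' `PFER <= 0.05`.
#'
#' @param observed_rp Numeric vector of observed rank products.
#' @param n_genes Number of genes in the rank-product universe.
#' @param n_platforms Number of platforms (`K`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble with columns `rp` and `pfer` (expected false-positive
#'   count; nonnegative, up to `n_genes`).
#' @export
pfer <- function(observed_rp, n_genes, n_platforms, n_perm = 1000,
                 seed = 1L) {
  stopifnot(n_perm >= 1, n_platforms >= 1, n_genes >= 1)
  set.seed(seed)
  # all null RPs pooled; PFER(g) = (#null <= RP(g)) / n_perm
  null_log_rp <- numeric(n_perm * n_genes)
  for (b in seq_len(n_perm)) {
    lr <- rowMeans(vapply(seq_len(n_platforms),
                          function(k) log(sample(n_genes)),
                          numeric(n_genes)))
    null_log_rp[((b - 1L) * n_genes + 1L):(b * n_genes)] <- lr
  }
  null_sorted <- sort(null_log_rp)
  counts <- findInterval(log(observed_rp) + 1e-12, null_sorted)
  tibble::tibble(rp = observed_rp, pfer = counts / n_perm)
}

#' Two-direction rank-products analysis with PFER control
#'
#' Runs [rank_products()] in both directions, attaches permutation PFERs,
#' and flags genes significant in both directions as inconsistent.
#'
#' @inheritParams rank_products
#' @inheritParams pfer
#' @param alpha PFER significance cutoff (default 0.05).
#' @return A tibble with columns `gene_id`, `direction`, `rp`, `pfer`,
#'   `significant`, and `inconsistent`.
#' @export
rank_products_analysis <- function(score_tables, n_perm = 1000, seed = 1L,
                                   alpha = 0.05) {
  res <- dplyr::bind_rows(lapply(c("up", "down"), function(dir) {
    rp <- rank_products(score_tables, dir)
    pf <- pfer(rp$rp, n_genes = nrow(rp),
               n_platforms = attr(rp, "n_platforms"),
               n_perm = n_perm, seed = derive_seed(seed, match(dir, c("up", "down"))))
    rp$pfer <- pf$pfer
    rp
  }))
  res$significant <- res$pfer <= alpha
  both <- res |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n == 2L)
  res$inconsistent <- res$gene_id %in% both$gene_id & res$significant
  res
}
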