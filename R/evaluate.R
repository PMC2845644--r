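#' ROC AUC of an absolute-score ranking
#'
#' Area under the ROC curve of the `|score|` ranking against binary labels,
#' computed by the Wilcoxon rank-sum identity with average ranks for ties
#' (equal to the concordant-pair-counting definition).
#'
#' @param scores Numeric per-gene scores; genes are ranked by absolute
#'   value, so DE calls are irrespective of sign. If `scores` and `labels`
#'   are both named they are matched by name.
#' @param labels Binary labels (1 = positive); both classes must be
#'   present.
#' @return The AUC, a number in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  al <- align_scores_labels(scores, labels)
  r <- rank(abs(al$scores), ties.method = "average")
  n_pos <- sum(al$labels == 1)
  n_neg <- sum(al$labels == 0)
  (sum(r[al$labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' True positive rate at a fixed false positive rate
#'
#' Sweeps the `|score|` thresholds and returns the largest TPR attainable
#' with FPR at or below `fpr_level` (step-function convention).
#'
#' @inheritParams roc_auc
#' @param fpr_level Maximum allowed FPR (default 0.05).
#' @return The TPR, a number in `[0, 1]`.
#' @export
tpr_at_fpr <- function(scores, labels, fpr_level = 0.05) {
  al <- align_scores_labels(scores, labels)
  ord <- order(abs(al$scores), decreasing = TRUE)
  lab <- al$labels[ord]
  abs_sorted <- abs(al$scores)[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # only cutpoints between distinct |score| values are valid thresholds
  cut_ok <- c(abs_sorted[-1] != abs_sorted[-length(abs_sorted)], TRUE)
  tpr <- tp[cut_ok] / sum(lab == 1)
  fpr <- fp[cut_ok] / sum(lab == 0)
  feasible <- fpr <= fpr_level
  if (!any(feasible)) 0 else max(tpr[feasible])
}

align_scores_labels <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    common <- intersect(names(scores), names(labels))
    if (length(common) == 0L) {
      stop("no shared gene identifiers between scores and labels",
           call. = FALSE)
    }
    scores <- scores[common]
    labels <- labels[common]
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length and are not both named",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("missing values in scores or labels", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both label classes must be present", call. = FALSE)
  }
  list(scores = scores, labels = labels)
}

#' Derive a gold standard from a highly replicated dataset
#'
#' Defines the "truly DE" genes of a full dataset: the number of DE genes
#' `n_top` is the count of genes whose moderated t statistic passes a
#' Benjamini-Hochberg FDR cutoff (two-sided p from the moderated-t null
#' with `d0 + m - 1` degrees of freedom), and the labels are the `n_top`
#' genes with the largest `|score|` of the chosen metric.
#'
#' @param full_dataset Complete dataset matrix with many replicates.
#' @param method Metric whose ranking defines the labels: `"fc"` (mean fold
#'   change) or `"modt"` (moderated t).
#' @param fdr FDR cutoff determining `n_top` (default 0.05).
#' @return A tibble with columns `gene_id`, `score` (of the chosen
#'   method), and `gold` (0/1), with attribute `n_top`.
#' @export
build_gold_standard <- function(full_dataset, method = c("fc", "modt"),
                                fdr = 0.05) {
  method <- match.arg(method)
  full_dataset <- validate_expression_matrix(full_dataset,
                                             allow_missing = FALSE)
  m <- ncol(full_dataset)
  if (m < 2L) {
    stop("a gold standard needs a replicated dataset (m >= 2)",
         call. = FALSE)
  }
  s2 <- apply(full_dataset, 1, var)
  mod <- moderate_variances(s2, df = m - 1L)
  t_stat <- rowMeans(full_dataset) / sqrt(mod$s_tilde_sq / m)
  df_total <- mod$d0 + m - 1
  pvals <- 2 * pt(-abs(t_stat), df = df_total)
  n_top <- sum(p.adjust(pvals, method = "BH") < fdr)
  if (n_top == 0L) {
    stop("no genes significant at FDR ", fdr,
         "; relax the threshold or supply more replicates", call. = FALSE)
  }
  score <- if (method == "fc") rowMeans(full_dataset) else t_stat
  gold <- integer(nrow(full_dataset))
  gold[order(abs(score), decreasing = TRUE)[seq_len(n_top)]] <- 1L
  out <- tibble::tibble(gene_id = rownames(full_dataset),
                        score = unname(score), gold = gold)
  attr(out, "n_top") <- n_top
  out
}

#' Standard curve of AUC versus sample size
#'
#' Stores (number of arrays, mean reference AUC) pairs for converting an
#' observed AUC into an effective number of arrays. AUCs are made
#' nondecreasing in `n` by isotonic regression so that the curve can be
#' inverted.
#'
#' @param n_arrays Strictly increasing integer sample sizes (>= 2 points).
#' @param auc Mean reference (fold-change) AUC at each size.
#' @return An object of class `standard_curve`: tibble with columns `n`,
#'   `auc`, and `auc_iso` (the isotonic fit).
#' @export
standard_curve <- function(n_arrays, auc) {
  if (length(n_arrays) < 2L || length(auc) != length(n_arrays)) {
    stop("need at least two (n, AUC) points of equal length", call. = FALSE)
  }
  if (any(diff(n_arrays) <= 0)) {
    stop("`n_arrays` must be strictly increasing", call. = FALSE)
  }
  iso <- isoreg(n_arrays, auc)$yf
  structure(
    tibble::tibble(n = n_arrays, auc = auc, auc_iso = iso),
    class = c("standard_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Effective number of arrays for an observed AUC
#'
#' Inverts a [standard_curve()] by monotone piecewise-linear interpolation:
#' the effective number of arrays is the sample size at which the reference
#' metric attains the observed AUC. Observations outside the curve's AUC
#' range are clamped to the nearest endpoint and flagged.
#'
#' @param observed_auc Numeric vector of observed AUCs.
#' @param curve A [standard_curve()].
#' @return A tibble with columns `observed_auc`, `effective_n`, and
#'   `out_of_range`.
#' @export
effective_arrays <- function(observed_auc, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  # collapse isotonic plateaus so the inverse is well defined
  keep <- !duplicated(curve$auc_iso)
  xs <- curve$auc_iso[keep]
  ys <- curve$n[keep]
  lo <- min(xs)
  hi <- max(xs)
  clamped <- pmin(pmax(observed_auc, lo), hi)
  eff <- if (length(xs) == 1L) {
    rep(ys, length(clamped))
  } else {
    approx(xs, ys, xout = clamped, ties = "ordered")$y
  }
  tibble::tibble(
    observed_auc = observed_auc,
    effective_n = eff,
    out_of_range = observed_auc < lo | observed_auc > hi
  )
}

#' Evaluate scoring metrics on replicate subsets
#'
#' Forms the maximal number of non-overlapping replicate subsets of each
#' requested size (after a seeded shuffle of the replicate columns), scores
#' each subset with each applicable metric, and evaluates against a gold
#' standard. The moderated t is skipped (with a notice) for single-replicate
#' subsets.
#'
#' @param full_dataset Complete dataset matrix.
#' @param subset_sizes Integer vector of replicate-subset sizes (e.g.
#'   `c(1, 2, 5, 15)`).
#' @param weights A [weight_matrix()] result for SAGAT scoring (genes are
#'   aligned automatically).
#' @param gold Named binary gold-standard labels (e.g. from
#'   [build_gold_standard()]'s `gold` column, named by `gene_id`).
#' @param metrics Metrics to run: subset of `"sagat"`, `"fc"`, `"modt"`.
#' @param seed Integer seed for the replicate shuffle.
#' @param fpr_level FPR at which TPR is evaluated (default 0.05).
#' @return A tibble with one row per size/subset/metric: `size`, `subset`,
#'   `metric`, `auc`, `tpr`, `n_pos`, `n_neg`.
#' @export
subset_evaluation <- function(full_dataset, subset_sizes, weights, gold,
                              metrics = c("sagat", "fc", "modt"),
                              seed = 1L, fpr_level = 0.05) {
  full_dataset <- validate_expression_matrix(full_dataset,
                                             allow_missing = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  m_total <- ncol(full_dataset)
  if (any(subset_sizes > m_total)) {
    stop("subset sizes exceed the dataset's replicate count", call. = FALSE)
  }
  aligned <- if ("sagat" %in% metrics) {
    align_genes(full_dataset, weights)
  } else {
    NULL
  }
  set.seed(seed)
  shuffled <- sample(m_total)
  rows <- list()
  for (size in subset_sizes) {
    n_subsets <- floor(m_total / size)
    for (s in seq_len(n_subsets)) {
      cols <- shuffled[((s - 1L) * size + 1L):(s * size)]
      sub <- full_dataset[, cols, drop = FALSE]
      for (metric in metrics) {
        if (metric == "modt" && size == 1L) {
          if (s == 1L) {
            message("moderated t skipped at subset size 1 ",
                    "(requires two or more replicates)")
          }
          next
        }
        tab <- switch(metric,
          sagat = sagat_score(aligned$dataset[, cols, drop = FALSE],
                              aligned$weights),
          fc = fold_change_scores(sub),
          modt = moderated_t_scores(sub)
        )
        sc <- setNames(tab$score, tab$gene_id)
        al <- align_scores_labels(sc, gold)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size = size, subset = s, metric = metric,
          auc = roc_auc(sc, gold),
          tpr = tpr_at_fpr(sc, gold, fpr_level),
          n_pos = sum(al$labels == 1), n_neg = sum(al$labels == 0)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
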