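# Small fixtures shared across test files; everything is generated in code.

named_matrix <- function(values, n_genes, n_arrays,
                         genes = sprintf("g%02d", seq_len(n_genes)),
                         arrays = sprintf("a%02d", seq_len(n_arrays))) {
  matrix(values, n_genes, n_arrays, dimnames = list(genes, arrays))
}

random_dataset <- function(n_genes, m, seed = 1, sd = 1, mu = 0) {
  set.seed(seed)
  named_matrix(mu + rnorm(n_genes * m, sd = sd), n_genes, m,
               arrays = sprintf("r%02d", seq_len(m)))
}

# identity weight matrix over a gene set (eigengenes == genes)
identity_weights <- function(gene_ids) {
  w <- diag(length(gene_ids))
  rownames(w) <- gene_ids
  structure(list(w = w, m = length(gene_ids), gene_ids = gene_ids),
            class = "sagat_weights")
}

# brute-force AUC by pair counting (concordant + half ties)
pair_count_auc <- function(scores, labels) {
  s <- abs(scores)
  pos <- s[labels == 1]
  neg <- s[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force TPR at FPR by exhaustive threshold sweep
sweep_tpr_at_fpr <- function(scores, labels, level) {
  s <- abs(scores)
  best <- 0
  for (thr in sort(unique(c(s, Inf)))) {
    calls <- s >= thr
    fpr <- sum(calls & labels == 0) / sum(labels == 0)
    tpr <- sum(calls & labels == 1) / sum(labels == 1)
    if (fpr <= level) best <- max(best, tpr)
  }
  best
}
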