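# sagat

Knowledge-augmented differential expression (DE) analysis for
transcriptomics. Small experiments — one to a handful of replicate
arrays — cannot estimate per-gene variances well, so simple scores like
the mean log fold change leave information on the table. `sagat`
implements the SVD Augmented Gene expression Analysis Tool: it learns
coexpression structure from a large *knowledge compendium* of prior
arrays on the same platform and lets coexpressed genes share variance
information when scoring a new, small dataset. The package is aimed at
computational biologists who have (or can simulate) a gene-level
expression compendium and want better-ranked DE candidates from
under-replicated experiments.

## The score

The preprocessed compendium `X` (genes × arrays, rows standardized) is
decomposed as `X = U diag(S) Vᵀ`. The weight matrix `W` — the first `M`
columns of `U`, with `M ≈ P/2` for `P` compendium arrays — maps genes to
eigengenes. A dataset `D` (genes × m replicates of log ratios) is carried
into eigengene space by pseudoinverse projection, `Ê = Wᵀ D`, and each
gene is scored with

    T_i = d̄_i / sqrt( (1/m) Σ_j w_ij² s̃_j² )

where `d̄_i` is the gene's mean log ratio and `s̃_j²` are empirical-Bayes
moderated variances of the eigengene log ratios. Genes sharing an
eigengene share its variance estimate — the "borrowing" that gives module
genes more precise standard errors. With `m = 1` the magnitudes of the
single eigengene log ratios stand in for the variances
(`T_i = d_i / sqrt(Σ_j w_ij² |e_j|)`). With `W` the identity, `T`
reduces exactly to the one-sample moderated t.

Alongside the scoring core, the package ships the full study apparatus:
a block-covariance synthetic generator for compendia and DE-spiked
datasets (`sim_config()`, `simulate_knowledge()`, `simulate_dataset()`,
`run_simulation_study()`), coexpression-module characterization on
binarized covariance matrices with a permutation null (`find_modules()`,
`permutation_null()`), ROC-based evaluation including gold standards
from highly replicated data and effective-number-of-arrays standard
curves (`roc_auc()`, `tpr_at_fpr()`, `build_gold_standard()`,
`standard_curve()`, `effective_arrays()`, `subset_evaluation()`), and
rank-products meta-analysis across platforms with permutation PFER
control (`rank_products()`, `pfer()`, `rank_products_analysis()`).

## Worked example

```r
library(sagat)

# a synthetic study: 1000-gene compendium with four 15-gene DE modules
cfg <- sim_config(n_de_modules = 4, m = 2, seed = 9)
sim <- simulate_knowledge(cfg)

# decompose the standardized compendium and keep M = half the arrays
dec <- sagat_decompose(standardize_rows(sim$knowledge))
w   <- weight_matrix(dec)   # M = 100 eigengenes
#> <sagat_weights> 1000 genes x 100 eigengenes

# score a 2-replicate dataset with SAGAT
d  <- simulate_dataset(cfg, sim$truth)
sg <- sagat_score(d, w)
head(sg, 3)
#> # A tibble: 3 × 3
#>   gene_id score  rank
#>   <chr>   <dbl> <dbl>
#> 1 g0001    4.80    99
#> 2 g0002   -1.95   522
#> 3 g0003   -4.99    88

# compare with fold change against the planted DE labels
labels <- setNames(sim$truth$de, sim$truth$gene_id)
fc <- fold_change_scores(d)
c(sagat = roc_auc(setNames(sg$score, sg$gene_id), labels),
  fold_change = roc_auc(setNames(fc$score, fc$gene_id), labels))
#>       sagat fold_change
#>   0.5697667   0.5212667

# the full paired study over 50 datasets
run_simulation_study(cfg, n_datasets = 50, seed = 9)[
  , c("mean_auc_sagat", "mean_auc_fc", "mean_delta_auc", "se_delta_auc")]
#> # A tibble: 1 × 4
#>   mean_auc_sagat mean_auc_fc mean_delta_auc se_delta_auc
#>            <dbl>       <dbl>          <dbl>        <dbl>
#> 1          0.600       0.560         0.0408      0.00136
```

Gene `g0001` sits in a DE module: its score (rank 99 of 1000) reflects
both its fold change and the small standard error it inherits from its
module's pooled eigengene variance. Over 50 datasets, SAGAT's mean AUC
improvement of ~0.04 over fold change is roughly thirty standard errors
from zero — knowledge of coexpression converts into measurably better DE
rankings at this replicate count.

Scoring real data follows the same calls: read the compendium and
dataset with `read_expression_matrix()`, preprocess with
`prepare_knowledge()`, align with `align_genes()`, and score. A thin
command-line wrapper with `simulate` / `decompose` / `score` / `modules` /
`evaluate` / `rankprod` subcommands is installed at
`system.file("cli", "sagat.R", package = "sagat")`; every run writes a
JSON provenance record beside its outputs.

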