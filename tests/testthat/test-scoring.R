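test_that("gene alignment restricts and reorders both sides", {
  w <- identity_weights(c("g03", "g01", "g02"))
  d <- random_dataset(4, 2, seed = 3)  # g01..g04
  al <- align_genes(d, w)
  expect_identical(rownames(al$dataset), c("g03", "g01", "g02"))
  expect_identical(al$weights$gene_ids, c("g03", "g01", "g02"))
  expect_identical(al$dropped$dataset_only, "g04")
  expect_identical(al$dropped$weights_only, character(0))
  # values follow identifiers through the reordering
  expect_identical(al$dataset["g02", ], d["g02", ])

  w2 <- identity_weights(c("x1", "x2"))
  expect_error(align_genes(d, w2), "no gene identifiers shared")
})

test_that("projection is W'D with row means and sample variances", {
  d <- named_matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                    arrays = c("r01", "r02"))
  w <- identity_weights(rownames(d))
  p <- project_dataset(d, w)
  expect_equal(unname(p$ehat), unname(d))
  expect_equal(unname(p$eigengene_means), unname(rowMeans(d)))
  expect_equal(unname(p$raw_variances), apply(d, 1, var), ignore_attr = TRUE)

  # explicit 3-gene, 2-eigengene hand product
  wmat <- matrix(c(0.5, 0.5, 0, 0, 0.6, 0.8), 3, 2,
                 dimnames = list(rownames(d), NULL))
  w2 <- structure(list(w = wmat, m = 2L, gene_ids = rownames(d)),
                  class = "sagat_weights")
  p2 <- project_dataset(d, w2)
  expect_equal(unname(p2$ehat),
               rbind(c(0.5 * 1 + 0.5 * 2, 0.5 * 4 + 0.5 * 5),
                     c(0.6 * 2 + 0.8 * 3, 0.6 * 5 + 0.8 * 6)))

  z <- named_matrix(0, 3, 2)
  pz <- project_dataset(z, w)
  expect_true(all(pz$eigengene_means == 0) && all(pz$raw_variances == 0))

  expect_error(project_dataset(d[3:1, ], w), "align_genes")
})

test_that("variance moderation shrinks toward a fitted prior", {
  # constant variances: complete shrinkage, no change
  mv <- moderate_variances(rep(2.5, 30), df = 3)
  expect_equal(mv$s_tilde_sq, rep(2.5, 30))

  # d0 = 0 override disables shrinkage
  set.seed(6)
  raw <- rchisq(40, df = 3) / 3
  expect_equal(moderate_variances(raw, df = 3, d0 = 0)$s_tilde_sq, raw)

  # posterior lies between raw and prior variance
  mv2 <- moderate_variances(raw, df = 3)
  expect_true(all(
    mv2$s_tilde_sq >= pmin(raw, mv2$s0_sq) - 1e-12 &
      mv2$s_tilde_sq <= pmax(raw, mv2$s0_sq) + 1e-12
  ))
  expect_error(moderate_variances(rep(0, 10), df = 3), "zero")
})

test_that("moderation recovers a known scaled inverse-chi-square prior", {
  # true prior: d0 = 4, s0^2 = 2; observed s^2 | sigma^2 ~ sigma^2 chi^2_df/df
  set.seed(77)
  d0_true <- 4
  s0_true <- 2
  df_obs <- 10
  n <- 200
  sigma2 <- d0_true * s0_true / rchisq(n, df = d0_true)
  s2 <- sigma2 * rchisq(n, df = df_obs) / df_obs
  mv <- moderate_variances(s2, df = df_obs)
  expect_lt(abs(mv$d0 - d0_true) / d0_true, 0.5)
  expect_lt(abs(mv$s0_sq - s0_true) / s0_true, 0.5)
})

test_that("the SAGAT score matches its closed form on a hand example", {
  # 2 genes, 1 eigengene: w = (0.6, 0.8), s~^2 = 1, m = 4, dbar = (1, -1)
  d <- named_matrix(c(1, -1, 1, -1, 1, -1, 1, -1), 2, 4,
                    genes = c("gA", "gB"))
  wmat <- matrix(c(0.6, 0.8), 2, 1, dimnames = list(c("gA", "gB"), NULL))
  w <- structure(list(w = wmat, m = 1L, gene_ids = c("gA", "gB")),
                 class = "sagat_weights")
  mv <- structure(list(s_tilde_sq = 1, d0 = Inf, s0_sq = 1, df = 3),
                  class = "sagat_moderated")
  tab <- sagat_scores(d, w, moderated = mv)
  expect_equal(tab$score, c(1 / sqrt(0.36 / 4), -1 / sqrt(0.64 / 4)))
  expect_equal(tab$score, c(10 / 3, -2.5))
})

test_that("with identity weights SAGAT reduces to the moderated t", {
  d <- random_dataset(200, 4, seed = 15, mu = rep(c(1, 0), c(20, 180)))
  w <- identity_weights(rownames(d))
  sg <- sagat_scores(d, w)
  mt <- moderated_t_scores(d)
  expect_lt(max(abs(sg$score - mt$score)), 1e-10)
  expect_identical(sg$rank, mt$rank)
})

test_that("null numerators, antisymmetry, and scale behavior hold", {
  set.seed(19)
  cfg <- sim_config(n_genes = 200, n_de = 30, n_de_modules = 2,
                    n_arrays = 80, m = 3, seed = 19)
  sim <- simulate_knowledge(cfg)
  dec <- sagat_decompose(standardize_rows(sim$knowledge))
  w <- weight_matrix(dec, 40)
  d <- simulate_dataset(cfg, sim$truth)

  tab <- sagat_scores(d, w)
  tab_neg <- sagat_scores(-d, w)
  expect_equal(tab_neg$score, -tab$score, tolerance = 1e-12)
  expect_equal(fold_change_scores(-d)$score, -fold_change_scores(d)$score)
  expect_equal(moderated_t_scores(-d)$score, -moderated_t_scores(d)$score)

  # m > 1: scores invariant to positive rescaling of the data
  tab_scaled <- sagat_scores(3.7 * d, w)
  expect_lt(max(abs(tab_scaled$score - tab$score)), 1e-8)

  # m = 1 variant: scores scale by sqrt(c)
  d1 <- d[, 1, drop = FALSE]
  t1 <- sagat_scores_single(d1, w)
  t1c <- sagat_scores_single(4 * d1, w)
  expect_equal(t1c$score, 2 * t1$score, tolerance = 1e-10)
  expect_equal(sagat_scores_single(-d1, w)$score, -t1$score)

  # null data give null scores
  z <- named_matrix(0, 200, 3, genes = rownames(d))
  mv <- structure(list(s_tilde_sq = rep(1, 40), d0 = Inf, s0_sq = 1, df = 2),
                  class = "sagat_moderated")
  expect_true(all(sagat_scores(z, w, moderated = mv)$score == 0))
})

test_that("the single-replicate score evaluates its closed form", {
  d <- named_matrix(4, 1, 1, genes = "gA", arrays = "r01")
  w <- identity_weights("gA")
  tab <- sagat_scores_single(d, w)
  expect_equal(tab$score, 4 / sqrt(4))  # e = 4, T = d / sqrt(|e|) = 2
  z <- named_matrix(c(0, 0), 2, 1)
  wz <- structure(list(w = matrix(c(0.6, 0.8), 2, 1,
                                  dimnames = list(rownames(z), NULL)),
                       m = 1L, gene_ids = rownames(z)),
                  class = "sagat_weights")
  expect_error(sagat_scores_single(z, wz), "zero SAGAT standard error")
})

test_that("fold change and moderated t behave as documented", {
  d <- named_matrix(c(1, 5, 3, 7), 2, 2)
  expect_equal(fold_change_scores(d)$score, c(2, 6))
  expect_equal(fold_change_scores(d[, 2:1])$score, c(2, 6))
  d1 <- d[, 1, drop = FALSE]
  expect_equal(fold_change_scores(d1)$score, unname(d1[, 1]))
  expect_error(moderated_t_scores(d1), "two or more replicates")

  # equal gene variances: moderated-t ordering equals fold-change ordering
  set.seed(23)
  mu <- rnorm(50)
  deq <- named_matrix(c(mu + 1, mu - 1), 50, 2)  # every row has variance 2
  expect_identical(moderated_t_scores(deq)$rank, fold_change_scores(deq)$rank)

  # d0 = 0 override recovers the ordinary one-sample t
  d4 <- random_dataset(30, 4, seed = 29)
  plain_t <- rowMeans(d4) / sqrt(apply(d4, 1, var) / 4)
  expect_equal(moderated_t_scores(d4, d0 = 0)$score, unname(plain_t))
})

test_that("permutation p-values are reproducible and calibrated at null", {
  d <- random_dataset(60, 4, seed = 31)
  w <- identity_weights(rownames(d))
  p1 <- sagat_perm_pvalues(d, w, n_perm = 50, seed = 7)
  p2 <- sagat_perm_pvalues(d, w, n_perm = 50, seed = 7)
  expect_identical(p1$perm_p, p2$perm_p)
  expect_true(all(p1$perm_p > 0 & p1$perm_p <= 1))
  # null data: p-values should not concentrate near 0
  expect_gt(mean(p1$perm_p), 0.25)
})

test_that("module genes borrow variance information (smaller standard errors)", {
  # DE genes inside modules vs identical-effect isolated DE genes
  cfg <- sim_config(n_genes = 400, n_de = 60, n_de_modules = 2,
                    n_arrays = 150, m = 2, seed = 47)
  sim <- simulate_knowledge(cfg)
  dec <- sagat_decompose(standardize_rows(sim$knowledge))
  w <- weight_matrix(dec, 75)
  in_module <- !is.na(sim$truth$module) & sim$truth$de == 1
  isolated <- is.na(sim$truth$module) & sim$truth$de == 1
  se_mod <- se_iso <- numeric(50)
  for (b in 1:50) {
    d <- simulate_dataset(cfg, sim$truth, seed = 500 + b)
    proj <- project_dataset(d, w)
    mv <- moderate_variances(proj$raw_variances, df = 1)
    se2 <- as.vector(w$w^2 %*% mv$s_tilde_sq) / 2
    se_mod[b] <- mean(sqrt(se2[in_module]))
    se_iso[b] <- mean(sqrt(se2[isolated]))
  }
  expect_lt(mean(se_mod), mean(se_iso))
  expect_gt(mean(se_iso - se_mod) / (sd(se_iso - se_mod) / sqrt(50)), 3)
})
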