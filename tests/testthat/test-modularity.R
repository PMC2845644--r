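test_that("covariance binarization applies the absolute threshold with unit diagonal", {
  # two perfectly covarying genes, cov chosen around the 0.25 cutoff
  base <- c(-1, 1, -1, 1) / 2               # var = 1/3
  x <- named_matrix(c(base * 0.95,           # cov(g1,g2) ~ 0.30 > 0.25
                      base,
                      -base,                 # negative covariance, |.| rule
                      rep(c(0.1, -0.1), 2)), 4, 4, genes = paste0("g", 1:4))
  x <- t(x)  # genes x arrays
  rownames(x) <- paste0("g", 1:4)
  colnames(x) <- paste0("a", 1:4)
  cv <- cov(t(x))
  b <- binarize_covariance(x, threshold = 0.25)
  expect_true(isSymmetric(b))
  expect_true(all(diag(b) == 1L))
  expect_identical(b[upper.tri(b)] == 1L,
                   abs(cv[upper.tri(cv)]) > 0.25)
  expect_gt(abs(cv["g1", "g3"]), 0.25)  # negative covariance still counts
  expect_identical(b["g1", "g3"], 1L)
  expect_error(binarize_covariance(x[, 1, drop = FALSE]), "two arrays")
})

test_that("pairwise-complete covariance tolerates missing values", {
  set.seed(12)
  x <- named_matrix(rnorm(60), 6, 10)
  x[2, 4] <- NA
  b <- binarize_covariance(x, threshold = 0.1)
  expect_false(anyNA(b))
  expect_true(isSymmetric(b))
})

test_that("biclustering makes planted blocks contiguous", {
  # two 6-gene cliques plus background, scrambled
  n <- 20
  b <- diag(n)
  b[1:6, 1:6] <- 1
  b[7:12, 7:12] <- 1
  perm <- c(15, 3, 8, 1, 19, 10, 5, 12, 17, 2, 7, 20, 4, 9, 16, 6, 11, 13, 18, 14)
  bp <- b[perm, perm]
  rownames(bp) <- colnames(bp) <- paste0("g", perm)
  storage.mode(bp) <- "integer"
  ord <- bicluster_order(bp)
  members1 <- which(perm %in% 1:6)
  members2 <- which(perm %in% 7:12)
  pos1 <- sort(match(members1, ord))
  pos2 <- sort(match(members2, ord))
  expect_true(all(diff(pos1) == 1))
  expect_true(all(diff(pos2) == 1))
  # identity matrix: ordering completes and yields no modules downstream
  id <- diag(10L)
  rownames(id) <- colnames(id) <- paste0("g", 1:10)
  ord_id <- bicluster_order(id)
  expect_identical(sort(ord_id), 1:10)
  ms <- extract_modules(id, ord_id, min_size = 2)
  expect_identical(length(ms$modules), 0L)
})

test_that("module extraction keeps only maximal all-ones runs above min_size", {
  n <- 30
  b <- diag(n)
  b[1:15, 1:15] <- 1   # size-15 block
  b[16:25, 16:25] <- 1 # size-10 block
  storage.mode(b) <- "integer"
  rownames(b) <- colnames(b) <- sprintf("g%02d", 1:n)
  ms <- extract_modules(b, 1:n, min_size = 15)
  expect_identical(length(ms$modules), 1L)
  expect_identical(ms$modules[[1]], sprintf("g%02d", 1:15))
  ms5 <- extract_modules(b, 1:n, min_size = 5)
  expect_identical(lengths(ms5$modules), c(15L, 10L))

  # all-ones matrix is a single module
  all1 <- matrix(1L, 20, 20, dimnames = list(sprintf("g%02d", 1:20),
                                             sprintf("g%02d", 1:20)))
  ms_all <- extract_modules(all1, 1:20, min_size = 15)
  expect_identical(lengths(ms_all$modules), 20L)

  # a module is found even when a chance neighbor connects to its start
  b2 <- diag(10L)
  b2[3:8, 3:8] <- 1L
  b2[2, 3] <- b2[3, 2] <- 1L  # neighbor links into the block's first gene
  rownames(b2) <- colnames(b2) <- paste0("g", 1:10)
  ms2 <- extract_modules(b2, 1:10, min_size = 5)
  expect_identical(ms2$modules, list(paste0("g", 3:8)))

  expect_identical(nrow(tidy(ms5)), 25L)
})

test_that("planted modules are recovered from a synthetic compendium", {
  cfg <- sim_config(n_genes = 300, n_de = 60, n_de_modules = 4,
                    n_nonde_modules = 8, n_arrays = 3000, seed = 61)
  sim <- simulate_knowledge(cfg)
  ms <- find_modules(sim$knowledge, threshold = 0.25, min_size = 15)
  planted <- sim$truth$gene_id[!is.na(sim$truth$module)]
  recovered <- unlist(ms$modules)
  expect_gte(mean(planted %in% recovered), 0.9)
  # and essentially nothing outside the planted modules is called
  expect_lte(length(setdiff(recovered, planted)), 10)
})

test_that("independent row permutations destroy modularity", {
  cfg <- sim_config(n_genes = 120, n_de = 30, n_de_modules = 2,
                    n_nonde_modules = 2, module_size = 10, n_arrays = 1000,
                    seed = 71)
  sim <- simulate_knowledge(cfg)
  # the intact compendium has modules at this scale
  expect_gte(length(find_modules(sim$knowledge, min_size = 5)$modules), 2L)
  pn <- permutation_null(sim$knowledge, n_perm = 20, min_size = 5,
                         threshold = 0.25, seed = 5)
  expect_identical(nrow(pn), 20L)
  expect_gte(mean(pn$n_modules == 0), 0.9)

  pn_same <- permutation_null(sim$knowledge, n_perm = 3, min_size = 5,
                              threshold = 0.25, seed = 9)
  pn_rep <- permutation_null(sim$knowledge, n_perm = 3, min_size = 5,
                             threshold = 0.25, seed = 9)
  expect_identical(pn_same, pn_rep)
})

test_that("pure-noise compendia produce no modules", {
  set.seed(55)
  x <- named_matrix(rnorm(150 * 120), 150, 120,
                    genes = sprintf("g%03d", 1:150))
  pn <- permutation_null(x, n_perm = 10, min_size = 5, threshold = 0.25,
                         seed = 3)
  expect_gte(mean(pn$n_modules == 0), 0.9)
})

test_that("module membership statistics count label classes correctly", {
  ms <- structure(list(modules = list(paste0("g", 1:10)), min_size = 5,
                       ordering = 1:30, threshold = 0.25),
                  class = "module_set")
  labels <- setNames(c(rep(1, 20), rep(0, 10)), paste0("g", 1:30))
  st <- module_membership_stats(ms, labels)
  expect_equal(st$prop_de_in_modules, 0.5)  # 10 of 20 DE genes in modules
  expect_equal(st$prop_nonde_in_modules, 0)
  expect_equal(st$mean_module_size, 10)

  empty <- structure(list(modules = list(), min_size = 5, ordering = 1:30,
                          threshold = 0.25), class = "module_set")
  st0 <- module_membership_stats(empty, labels)
  expect_true(all(c(st0$prop_de_in_modules, st0$prop_nonde_in_modules,
                    st0$mean_module_size) == 0))

  expect_error(module_membership_stats(ms, labels[1:5]), "cover")
})
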