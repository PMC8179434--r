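test_that("property_importance matches the brute-force oracle", {
  set.seed(17)
  m <- matrix(runif(200, 0, 100), 25, 8,
              dimnames = list(NULL, paste0("mold_", 1:8)))
  model <- fit_pca(m)
  tab <- property_importance(model, m, n_pcs = 5)
  oracle <- oracle_importance(m, model$coefficients, 5)
  names(oracle) <- colnames(m)
  expect_equal(tab$importance, unname(oracle[tab$column]),
               tolerance = 1e-10)
  # ranking is descending
  expect_true(all(diff(tab$importance) <= 1e-12))
  expect_error(property_importance(model, m, n_pcs = 99), "exceeds")
})

test_that("degenerate loadings: variance-on-one-PC and constant columns", {
  set.seed(2)
  x <- rnorm(30)
  m <- cbind(mold_1 = x, mold_2 = rep(3, 30))
  model <- fit_pca(m)
  tab <- property_importance(model, m, n_pcs = 1)
  # a variable loading entirely on PC1 has importance = its variance
  v1 <- sum((x - mean(x))^2) / 30
  expect_equal(tab$importance[tab$column == "mold_1"], v1,
               tolerance = 1e-10)
  expect_equal(tab$importance[tab$column == "mold_2"], 0)
})

test_that("total importance over all PCs conserves total variance", {
  set.seed(23)
  m <- matrix(runif(300, 0, 100), 30, 10,
              dimnames = list(NULL, paste0("mold_", 1:10)))
  model <- fit_pca(m)
  tab <- property_importance(model, m, n_pcs = ncol(model$coefficients))
  expect_equal(sum(tab$importance), sum(tab$variance), tolerance = 1e-8)
})

test_that("column permutation permutes but never changes importances", {
  set.seed(29)
  m <- matrix(runif(200, 0, 100), 20, 10,
              dimnames = list(NULL, paste0("mold_", 1:10)))
  perm <- sample(10)
  t1 <- property_importance(fit_pca(m), m, 5)
  m2 <- m[, perm]
  t2 <- property_importance(fit_pca(m2), m2, 5)
  i1 <- stats::setNames(t1$importance, t1$column)
  i2 <- stats::setNames(t2$importance, t2$column)
  expect_equal(i2[names(i1)], i1, tolerance = 1e-8)
})

test_that("prune_redundant keeps one survivor per correlated cluster", {
  set.seed(41)
  n <- 60
  base1 <- rnorm(n); base2 <- rnorm(n)
  m <- cbind(mold_1 = base1,
             mold_2 = base1 + rnorm(n, sd = 0.01),   # block 1 copy
             mold_3 = base2,
             mold_4 = base2 * 2 + rnorm(n, sd = 0.01),  # block 2 copy
             mold_5 = rnorm(n), mold_6 = rnorm(n))
  model <- fit_pca(m)
  tab <- property_importance(model, m, n_pcs = 6)
  kept <- prune_redundant(tab, m, top_n = 6, r_threshold = 0.8)
  # exactly one survivor per planted block, and it is the block leader
  b1 <- intersect(kept, c("mold_1", "mold_2"))
  b2 <- intersect(kept, c("mold_3", "mold_4"))
  expect_length(b1, 1L); expect_length(b2, 1L)
  expect_equal(b1, intersect(tab$column, c("mold_1", "mold_2"))[1])
  expect_equal(b2, intersect(tab$column, c("mold_3", "mold_4"))[1])
  expect_true(all(c("mold_5", "mold_6") %in% kept))
  # mutually uncorrelated set: everything retained
  m2 <- m[, c("mold_3", "mold_5", "mold_6")]
  model2 <- fit_pca(m2)
  tab2 <- property_importance(model2, m2, 3)
  expect_setequal(prune_redundant(tab2, m2, top_n = 3), colnames(m2))
})
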