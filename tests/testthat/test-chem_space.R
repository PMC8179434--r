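rand_scaled <- function(n = 30, p = 12, seed = 4) {
  set.seed(seed)
  m <- matrix(runif(n * p, 0, 100), n, p,
              dimnames = list(NULL, paste0("mold_", seq_len(p))))
  m
}

test_that("fit_pca is self-consistent", {
  m <- rand_scaled()
  model <- fit_pca(m)
  # training projection reproduces fitted scores
  expect_equal(project(model, m), model$scores, tolerance = 1e-8)
  # full-rank reconstruction
  rec <- model$scores %*% t(model$coefficients)
  expect_equal(rec, sweep(m, 2, model$column_means), tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained variance: fractions sum to 1, non-increasing
  expect_equal(sum(model$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(model$explained_variance) <= 1e-12))
  # orthonormal loadings
  expect_equal(t(model$coefficients) %*% model$coefficients,
               diag(ncol(model$coefficients)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(m[1, , drop = FALSE]), "at least 2")
})

test_that("collinear data loads on one PC; constant columns are harmless", {
  set.seed(9)
  x <- runif(40)
  m <- cbind(mold_1 = x, mold_2 = 3 * x, mold_3 = 0)
  model <- fit_pca(m)
  expect_equal(model$explained_variance[1], 1, tolerance = 1e-10)
})

test_that("project centers with training means", {
  m <- rand_scaled()
  model <- fit_pca(m)
  expect_equal(as.numeric(project(model, model$column_means)),
               rep(0, ncol(m)), tolerance = 1e-10)
  # oracle: explicit centered matrix multiply on a random row
  set.seed(11); row <- runif(ncol(m), 0, 100)
  names(row) <- colnames(m)
  oracle <- (row - model$column_means) %*% model$coefficients
  expect_equal(as.numeric(project(model, row)), as.numeric(oracle),
               tolerance = 1e-10)
  expect_error(project(model, m[, 1:3]), "mismatch")
})

test_that("hyperellipsoid volume follows the closed form", {
  # d = 10, all semi-axes 1 -> pi^5 / 120
  sc <- matrix(rep(c(-1, 1), each = 10), 2, 10, byrow = FALSE)
  sc <- rbind(matrix(-1, 1, 10), matrix(1, 1, 10))
  h <- hyperellipsoid(sc, coverage = 1, dims = 10)
  expect_equal(h$semi_axes, rep(1, 10))
  expect_equal(h$volume, pi^5 / 120, tolerance = 1e-12)
  expect_equal(h$volume, 2.5502, tolerance = 1e-4)
  expect_equal(h$avg_radius^10, h$volume, tolerance = 1e-10)
  # zero spread on any axis -> zero volume
  sc0 <- cbind(sc[, 1:9], 5)
  expect_equal(hyperellipsoid(sc0, coverage = 1, dims = 10)$volume, 0)
  # doubling every range multiplies the volume by 2^10
  expect_equal(hyperellipsoid(2 * sc, coverage = 1, dims = 10)$volume,
               1024 * h$volume, tolerance = 1e-9)
  expect_error(hyperellipsoid(sc[0, ]), "empty")
  expect_error(hyperellipsoid(sc, coverage = 0), "coverage")
})

test_that("Monte-Carlo uniform box matches the quantile-derived ellipsoid", {
  set.seed(21)
  n <- 10000
  widths <- seq(1, 10, along.with = 1:10)
  pts <- sapply(widths, function(w) runif(n, 0, w))
  h <- hyperellipsoid(pts, coverage = 0.95, dims = 10)
  analytic <- oracle_ellipsoid_volume(0.95 * widths / 2)
  expect_equal(h$volume, analytic, tolerance = 0.05)
})

test_that("set and compound distances behave as metrics with normalization", {
  m <- rand_scaled(50, 12, seed = 13)
  model <- fit_pca(m)
  uni <- hyperellipsoid(model$scores, coverage = 1, dims = 10)
  a <- model$scores[1:20, ]; b <- model$scores[21:50, ]
  # self-distance is zero
  expect_equal(set_distance(a, a, uni)$distance, 0)
  # 1-PC case: centroids 3 and 7, semi-axis 2 -> 2.0
  uni1 <- list(semi_axes = 2, ranges = 4)
  expect_equal(set_distance(matrix(3), matrix(7), uni1, dims = 1)$distance, 2)
  # 3-4-5 in two PCs with unit semi-axis
  uni2 <- list(semi_axes = c(1, 1), ranges = c(2, 2))
  expect_equal(set_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1),
                            uni2, dims = 2)$distance, 5)
  # oracle match at 1e-10
  expect_equal(set_distance(a, b, uni)$distance,
               oracle_distance(a, b, uni$semi_axes[1], 10),
               tolerance = 1e-10)
  # compound distance: at the centroid -> 0; single-PC offset = a_PC1 -> 1
  expect_equal(compound_distance(colMeans(a), a, uni)$distance, 0,
               tolerance = 1e-10)
  expect_equal(compound_distance(5, matrix(3), uni1, dims = 1)$distance, 1)
  # 10-D random case against the explicit sum-of-squares oracle
  expect_equal(compound_distance(b[1, ], a, uni)$distance,
               oracle_distance(b[1, , drop = FALSE], a, uni$semi_axes[1], 10),
               tolerance = 1e-10)
  # symmetry and triangle inequality on random triples
  cc <- model$scores[sample(1:50, 10), ]
  dab <- set_distance(a, b, uni)$distance
  expect_equal(set_distance(b, a, uni)$distance, dab, tolerance = 1e-12)
  dac <- set_distance(a, cc, uni)$distance
  dcb <- set_distance(cc, b, uni)$distance
  expect_lte(dab, dac + dcb + 1e-12)
  # range normalization mode is exactly half the semi-axis mode's scale
  expect_equal(set_distance(a, b, uni, normalize = "range")$distance,
               dab / 2, tolerance = 1e-10)
})

test_that("rotation invariance: total variance and distances are preserved", {
  m <- rand_scaled(40, 8, seed = 3)
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))   # random orthogonal matrix
  m2 <- m %*% q
  colnames(m2) <- colnames(m)
  f1 <- fit_pca(m); f2 <- fit_pca(m2)
  expect_equal(sum(apply(sweep(m, 2, colMeans(m)), 2, var)),
               sum(apply(sweep(m2, 2, colMeans(m2)), 2, var)),
               tolerance = 1e-8)
  d1 <- sqrt(sum((colMeans(f1$scores[1:20, ]) -
                    colMeans(f1$scores[21:40, ]))^2))
  d2 <- sqrt(sum((colMeans(f2$scores[1:20, ]) -
                    colMeans(f2$scores[21:40, ]))^2))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("model JSON serialization carries the projection", {
  m <- rand_scaled(15, 6)
  model <- fit_pca(m)
  js <- jsonlite::fromJSON(model_to_json(model))
  expect_equal(unlist(js$column_means), model$column_means,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(js$n_pcs_retained, model$n_pcs_retained)
})
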