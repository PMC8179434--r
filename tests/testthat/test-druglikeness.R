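test_that("packaged ranges carry the 13 key properties", {
  rg <- oral_mc_ranges()
  expect_equal(nrow(rg), 13L)
  expect_true(all(rg$lo <= rg$hi))
  expect_equal(attr(rg, "provenance"), "packaged")
  # spot anchors
  expect_equal(rg$hi[rg$name == "SpiroRings"], 0)
  expect_equal(unlist(rg[rg$name == "tPSA", c("lo", "hi")]),
               c(lo = 50, hi = 230))
  expect_equal(unlist(rg[rg$name == "CLogP", c("lo", "hi")]),
               c(lo = 2.40, hi = 6.00))
  expect_equal(unlist(rg[rg$name == "RingHet_over_N", c("lo", "hi")]),
               c(lo = 0.06, hi = 0.31))
})

test_that("derive_ranges follows the modality conventions", {
  # all-identical values give a degenerate range
  expect_equal(derive_ranges(rep(3.2, 10), "A"), c(3.2, 3.2))
  # values 1..10, modality A -> [1.9, 9.1] (linear-interpolation percentiles)
  expect_equal(derive_ranges(1:10, "A"), c(1.9, 9.1), tolerance = 1e-12)
  # values 0..9, modality B-low -> [0, 7.2]
  expect_equal(derive_ranges(0:9, "B-low"), c(0, 7.2), tolerance = 1e-12)
  # B-high anchors at the maximum
  expect_equal(derive_ranges(0:9, "B-high"), c(1.8, 9), tolerance = 1e-12)
  expect_error(derive_ranges(numeric(0), "A"), "empty")
  expect_warning(derive_ranges(1:3, "A"), "fewer than 5")
})

midpoint_vector <- function() {
  rg <- oral_mc_ranges()
  v <- stats::setNames((rg$lo + rg$hi) / 2, paste0("mold_", rg$mold_id))
  v
}

test_that("count_violations and classify implement the truth table", {
  v <- midpoint_vector()
  expect_equal(as.integer(count_violations(v)), 0L)
  # spiro perturbation: midpoints with spiro rings = 1 -> exactly 1
  v1 <- v; v1[["mold_35"]] <- 1
  cv <- count_violations(v1)
  expect_equal(as.integer(cv), 1L)
  expect_equal(attr(cv, "violated"), "SpiroRings")
  # everything outside -> 13
  rg <- oral_mc_ranges()
  vout <- stats::setNames(rg$hi + 1, paste0("mold_", rg$mold_id))
  expect_equal(as.integer(count_violations(vout)), 13L)
  # inclusive bounds are compliant
  vlo <- stats::setNames(rg$lo, paste0("mold_", rg$mold_id))
  expect_equal(as.integer(count_violations(vlo)), 0L)
  # missing descriptor errors with the mold id
  expect_error(count_violations(v[-1]), "mold_35")
  # threshold boundary
  expect_equal(classify_violations(0L), "within")
  expect_equal(classify_violations(4L), "within")
  expect_equal(classify_violations(5L), "outside")
})

test_that("widening a range never increases violation counts", {
  set.seed(7)
  rg <- oral_mc_ranges()
  for (rep in 1:20) {
    v <- midpoint_vector() +
      rnorm(13, sd = (rg$hi - rg$lo + 0.5))
    names(v) <- paste0("mold_", rg$mold_id)
    base <- as.integer(count_violations(v, rg))
    wide <- rg
    j <- sample(13, 1)
    wide$lo[j] <- wide$lo[j] - 1; wide$hi[j] <- wide$hi[j] + 1
    expect_lte(as.integer(count_violations(v, wide)), base)
  }
})

test_that("violation counts rank-correlate with distance from the oral centroid", {
  oral <- generate_library(30, "oral-like", seed = 51)
  sparse <- generate_library(30, "sparse", seed = 52)
  mols <- c(oral$mols, sparse$mols)
  dm <- descriptor_matrix(mols)
  par <- fit_scaling(dm$matrix)
  sc <- apply_scaling(dm$matrix, par)
  model <- fit_pca(sc)
  uni <- hyperellipsoid(model$scores, coverage = 1, dims = 10)
  ref <- model$scores[1:30, ]
  dist <- vapply(seq_len(nrow(sc)), function(i)
    compound_distance(model$scores[i, ], ref, uni)$distance, 0)
  viol <- violation_report(dm$matrix)$violations
  expect_gt(cor(dist, viol, method = "spearman"), 0)
})
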