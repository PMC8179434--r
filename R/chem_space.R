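# Chemical space: PCA, hyperellipsoids, distances ------------------------

#' Fit a PCA chemical-space model
#'
#' PCA by singular value decomposition of the column-mean-centered scaled
#' descriptor matrix, with no Z-scoring (the 0-100 scaling already
#' equalizes descriptor ranges). Loading signs are fixed by forcing each
#' column's largest-magnitude coefficient positive, for reproducibility
#' across linear-algebra backends.
#'
#' @param scaled_matrix numeric matrix (compounds x descriptors) of scaled
#'   values. Constant columns are permitted (zero loadings influence).
#' @param n_pcs_retained number of PCs retained for downstream metrics.
#' @return a `chem_space_model`: `column_means`, `coefficients`
#'   (descriptor x PC loadings, orthonormal columns), `explained_variance`
#'   (fractions summing to 1 over all PCs), `scores` (training scores),
#'   `n_pcs_retained`.
#' @export
fit_pca <- function(scaled_matrix, n_pcs_retained = 10L) {
  if (is.null(dim(scaled_matrix)) || nrow(scaled_matrix) < 2L)
    stop("PCA requires at least 2 compounds")
  mu <- colMeans(scaled_matrix)
  xc <- sweep(scaled_matrix, 2L, mu)
  sv <- svd(xc)
  coef <- sv$v
  # deterministic orientation
  for (j in seq_len(ncol(coef))) {
    k <- which.max(abs(coef[, j]))
    if (coef[k, j] < 0) coef[, j] <- -coef[, j]
  }
  scores <- xc %*% coef
  var_pc <- sv$d^2
  ev <- if (sum(var_pc) > 0) var_pc / sum(var_pc) else var_pc
  rownames(coef) <- colnames(scaled_matrix)
  colnames(coef) <- paste0("PC", seq_len(ncol(coef)))
  colnames(scores) <- colnames(coef)
  structure(list(column_means = mu, coefficients = coef,
                 explained_variance = ev, scores = scores,
                 n_pcs_retained = min(n_pcs_retained, ncol(coef))),
            class = "chem_space_model")
}

#' @export
print.chem_space_model <- function(x, ...) {
  cat(sprintf("<chem_space_model: %d descriptors, %d PCs (%.1f%% var in first %d)>\n",
              nrow(x$coefficients), ncol(x$coefficients),
              100 * sum(x$explained_variance[seq_len(x$n_pcs_retained)]),
              x$n_pcs_retained))
  invisible(x)
}

#' Project scaled descriptor rows into PC space
#'
#' Scores = (data - training column means) x coefficients. Rows must be
#' scaled with the training `scaling_params`.
#'
#' @param model a `chem_space_model`.
#' @param scaled_rows numeric matrix or single named row.
#' @return score matrix (rows x PCs).
#' @export
project <- function(model, scaled_rows) {
  if (is.null(dim(scaled_rows)))
    scaled_rows <- matrix(scaled_rows, nrow = 1,
                          dimnames = list(NULL, names(scaled_rows)))
  if (ncol(scaled_rows) != nrow(model$coefficients))
    stop("column count mismatch with the fitted model")
  sc <- sweep(scaled_rows, 2L, model$column_means) %*% model$coefficients
  colnames(sc) <- colnames(model$coefficients)
  sc
}

#' Axis-aligned hyperellipsoid of a score cloud
#'
#' Per PC axis the range `R_i` spans the middle `coverage` fraction of the
#' compound scores (linear-interpolation quantiles; `coverage = 1` gives
#' the full range). Semi-axes are `R_i / 2` and the volume is the
#' d-dimensional ellipsoid volume
#' `V = pi^(d/2) / Gamma(d/2 + 1) * prod(a_i)`; for d = 10 this is
#' `(pi^5 / 120) * prod(R_i) / 2^10`. The average radius is `V^(1/d)`.
#'
#' @param scores score matrix (rows = compounds).
#' @param coverage fraction of compounds encompassed per axis, default
#'   0.95 (1.0 for a compound-set "universe").
#' @param dims number of leading PCs used, default 10.
#' @return a `hyperellipsoid`: `center`, `ranges`, `semi_axes`,
#'   `coverage`, `dims`, `volume`, `avg_radius`.
#' @export
hyperellipsoid <- function(scores, coverage = 0.95, dims = 10L) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (nrow(scores) == 0L) stop("empty score set")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  dims <- min(dims, ncol(scores))
  s <- scores[, seq_len(dims), drop = FALSE]
  lo <- (1 - coverage) / 2
  hi <- 1 - lo
  ranges <- vapply(seq_len(dims), function(j) {
    q <- stats::quantile(s[, j], c(lo, hi), type = 7, names = FALSE)
    q[2] - q[1]
  }, 0)
  a <- ranges / 2
  vol <- pi^(dims / 2) / gamma(dims / 2 + 1) * prod(a)
  structure(list(center = colMeans(s), ranges = ranges, semi_axes = a,
                 coverage = coverage, dims = dims, volume = vol,
                 avg_radius = vol^(1 / dims)),
            class = "hyperellipsoid")
}

#' @export
print.hyperellipsoid <- function(x, ...) {
  cat(sprintf("<hyperellipsoid d=%d coverage=%.2f volume=%.4g avg_radius=%.4g>\n",
              x$dims, x$coverage, x$volume, x$avg_radius))
  invisible(x)
}

# normalization constant from the universe ellipsoid
.norm_constant <- function(universe, normalize) {
  switch(normalize,
         semi_axis = universe$semi_axes[1],
         range = universe$ranges[1],
         stop("unknown normalization mode"))
}

#' Normalized distance between two compound-set centroids
#'
#' Euclidean distance between the mean score vectors of two sets over the
#' leading `dims` PCs, divided by the PC1 semi-axis of the universe
#' ellipsoid (or its full PC1 range with `normalize = "range"`).
#'
#' @param set_a_scores,set_b_scores score matrices of the two sets.
#' @param universe `hyperellipsoid` fitted at coverage 1 on all compounds.
#' @param dims PCs used (default 10).
#' @param normalize `"semi_axis"` (default) or `"range"`.
#' @return list with `distance` (normalized) and `raw` (unnormalized).
#' @export
set_distance <- function(set_a_scores, set_b_scores, universe, dims = 10L,
                         normalize = c("semi_axis", "range")) {
  normalize <- match.arg(normalize)
  if (is.null(dim(set_a_scores))) set_a_scores <- matrix(set_a_scores, nrow = 1)
  if (is.null(dim(set_b_scores))) set_b_scores <- matrix(set_b_scores, nrow = 1)
  dims <- min(dims, ncol(set_a_scores), ncol(set_b_scores))
  mu_a <- colMeans(set_a_scores[, seq_len(dims), drop = FALSE])
  mu_b <- colMeans(set_b_scores[, seq_len(dims), drop = FALSE])
  raw <- sqrt(sum((mu_a - mu_b)^2))
  list(distance = raw / .norm_constant(universe, normalize), raw = raw)
}

#' Normalized distance of a single compound from a reference centroid
#'
#' @param score_row one compound's score vector.
#' @param reference_set_scores score matrix of the reference set (e.g. the
#'   oral macrocycle drug set).
#' @inheritParams set_distance
#' @return list with `distance` (normalized) and `raw`.
#' @export
compound_distance <- function(score_row, reference_set_scores, universe,
                              dims = 10L,
                              normalize = c("semi_axis", "range")) {
  normalize <- match.arg(normalize)
  set_distance(matrix(score_row, nrow = 1), reference_set_scores, universe,
               dims = dims, normalize = normalize)
}

#' Serialize a chemical-space model (plus scaling) to JSON
#' @param model a `chem_space_model`.
#' @param params optional `scaling_params` stored alongside.
#' @param path output path; `NULL` returns the JSON string.
#' @export
model_to_json <- function(model, params = NULL, path = NULL) {
  obj <- list(column_means = as.list(model$column_means),
              coefficients = model$coefficients,
              explained_variance = model$explained_variance,
              n_pcs_retained = model$n_pcs_retained)
  if (!is.null(params)) obj$scaling <- as.data.frame(params)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
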