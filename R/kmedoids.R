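# PAM k-medoids representative selection --------------------------------

#' Select k representative compounds by k-medoids (PAM)
#'
#' Columns are Z-scored (sample standard deviation; constant columns are
#' dropped with a message) before Euclidean distances are computed. PAM
#' with BUILD initialization and full swap optimization; the swap phase is
#' cost-monotone and the procedure is deterministic given `seed` (the seed
#' only breaks exact cost ties).
#'
#' @param matrix numeric matrix, rows = compounds.
#' @param k number of medoids (default 42, matching the size of the
#'   smallest compound set the method was designed around).
#' @param seed integer seed for tie-breaking.
#' @param zscore Z-score columns first (default TRUE).
#' @return a `selection_result`: `medoid_ids`, `medoid_rows`, `assignment`
#'   (row -> medoid row), `total_cost`, `cost_trace` (per swap iteration),
#'   `seed`.
#' @export
kmedoids_representatives <- function(matrix, k = 42L, seed = 1L,
                                     zscore = TRUE) {
  if (is.null(dim(matrix))) matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (k > n) stop("k exceeds the number of compounds")
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("cpd", seq_len(n))
  x <- matrix
  if (zscore) {
    sds <- apply(x, 2L, stats::sd)
    drop <- !is.finite(sds) | sds == 0
    if (any(drop)) {
      message("dropping ", sum(drop), " constant column(s) before Z-scoring")
      x <- x[, !drop, drop = FALSE]
      sds <- sds[!drop]
    }
    x <- scale(x, center = TRUE, scale = sds)
  }
  d <- as.matrix(stats::dist(x))
  set.seed(seed)
  tie_noise <- stats::runif(n) * 1e-12  # deterministic tie-break perturbation

  # BUILD: greedy initialization
  medoids <- integer(0)
  first <- which.min(colSums(d) + tie_noise)
  medoids <- first
  while (length(medoids) < k) {
    dmin <- apply(d[, medoids, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(dmin - d[, j], 0))
    }, 0)
    medoids <- c(medoids, which.max(gain - tie_noise))
  }

  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1L, min))
  cost <- cost_of(medoids)
  cost_trace <- cost

  # SWAP: steepest-descent swaps until no improvement
  repeat {
    best_delta <- 0; best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (h in nonmed) {
        cand <- medoids; cand[mi] <- h
        delta <- cost_of(cand) - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- cost + best_delta
    cost_trace <- c(cost_trace, cost)
  }
  medoids <- sort(medoids)
  assignment <- medoids[apply(d[, medoids, drop = FALSE], 1L, which.min)]
  structure(list(medoid_ids = ids[medoids], medoid_rows = medoids,
                 assignment = stats::setNames(ids[assignment], ids),
                 total_cost = cost_of(medoids), cost_trace = cost_trace,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d medoids, total cost %.4g>\n",
              length(x$medoid_ids), x$total_cost))
  invisible(x)
}
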