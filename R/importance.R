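# Descriptor importance and redundancy pruning --------------------------

#' Rank descriptor importance over the leading PCs
#'
#' The importance of property p is
#' `I_p = V_p * sum_{i=1..n_pcs} c_{p,i}^2`,
#' the squared loadings of p over the first `n_pcs` PCs weighted by the
#' property's total variance `V_p` (population variance of the scaled
#' values, dividing by n).
#'
#' @param model a `chem_space_model`.
#' @param scaled_matrix the scaled training matrix the model was fitted on.
#' @param n_pcs number of leading PCs (default 10).
#' @return an `importance_table` data.frame sorted by descending
#'   importance: `column`, `importance`, `variance`, `rank`.
#' @export
property_importance <- function(model, scaled_matrix, n_pcs = 10L) {
  if (n_pcs > ncol(model$coefficients))
    stop("n_pcs exceeds the number of fitted PCs")
  n <- nrow(scaled_matrix)
  vp <- apply(scaled_matrix, 2L, function(x) sum((x - mean(x))^2) / n)
  c2 <- rowSums(model$coefficients[, seq_len(n_pcs), drop = FALSE]^2)
  imp <- vp * c2
  out <- data.frame(column = colnames(scaled_matrix), importance = imp,
                    variance = vp, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$column), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' Prune redundant descriptors among the most important
#'
#' The `top_n` descriptors by importance are clustered on
#' `|Pearson correlation| >= r_threshold` (connected components of the
#' threshold graph); within each cluster only the descriptor ranking
#' highest in importance is retained.
#'
#' @param table an `importance_table`.
#' @param scaled_matrix the scaled matrix used for correlation.
#' @param top_n number of top descriptors to consider (default 20).
#' @param r_threshold absolute-correlation threshold (default 0.8).
#' @return character vector of retained column names, in importance order.
#' @export
prune_redundant <- function(table, scaled_matrix, top_n = 20L,
                            r_threshold = 0.8) {
  if (top_n > nrow(table)) stop("top_n exceeds the table size")
  top <- table$column[seq_len(top_n)]
  x <- scaled_matrix[, top, drop = FALSE]
  cc <- suppressWarnings(stats::cor(x))
  cc[is.na(cc)] <- 0
  adjm <- abs(cc) >= r_threshold
  diag(adjm) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
  comp <- igraph::components(g)$membership
  retained <- character(0)
  for (cl in unique(comp)) {
    members <- top[comp == cl]
    # table is importance-sorted, so the first member ranks highest
    retained <- c(retained, members[1])
  }
  retained[order(match(retained, table$column))]
}
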