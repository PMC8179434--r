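# End-to-end chemical-space study ---------------------------------------

#' Run the full macrocycle chemical-space analysis on several compound sets
#'
#' Computes the 90-descriptor matrix for every compound, fits the 0-100
#' scaling and the PCA model over all compounds together, builds per-set
#' 95%-coverage hyperellipsoids plus the all-compound universe ellipsoid,
#' and reports normalized centroid distances of every set from the
#' reference set together with per-compound violation counts against the
#' packaged key-property ranges.
#'
#' @param sets named list; each element a list of `mc_mol` objects.
#' @param reference name of the reference set for distances (default the
#'   first set).
#' @param dims PCs used for volumes/distances (default 10).
#' @param coverage per-set ellipsoid coverage (default 0.95).
#' @param min_ring_size macrocycle threshold.
#' @param ranges property ranges for the violation report.
#' @return an `mc_study` object: `descriptor_matrix`, `set_of` (factor),
#'   `scaling`, `model`, `scores`, `ellipsoids` (per set), `universe`,
#'   `distances` (data.frame set/raw/normalized), `violations`
#'   (per-compound report), `importance` (full importance table).
#' @export
run_study <- function(sets, reference = names(sets)[1], dims = 10L,
                      coverage = 0.95, min_ring_size = 11L,
                      ranges = oral_mc_ranges()) {
  stopifnot(is.list(sets), !is.null(names(sets)), reference %in% names(sets))
  mols <- unlist(sets, recursive = FALSE)
  set_of <- rep(names(sets), vapply(sets, length, 1L))
  dm <- descriptor_matrix(mols, min_ring_size = min_ring_size)
  keep <- dm$ids
  set_of <- set_of[match(keep, vapply(mols, `[[`, "", "id"))]
  sc_par <- fit_scaling(dm$matrix)
  scaled <- apply_scaling(dm$matrix, sc_par)
  model <- fit_pca(scaled, n_pcs_retained = dims)
  scores <- model$scores
  universe <- hyperellipsoid(scores, coverage = 1.0, dims = dims)
  ells <- lapply(split(seq_along(set_of), set_of), function(idx)
    hyperellipsoid(scores[idx, , drop = FALSE], coverage = coverage,
                   dims = dims))
  ref_scores <- scores[set_of == reference, , drop = FALSE]
  dists <- do.call(rbind, lapply(names(ells), function(nm) {
    d <- set_distance(scores[set_of == nm, , drop = FALSE], ref_scores,
                      universe, dims = dims)
    data.frame(set = nm, raw = d$raw, normalized = d$distance,
               stringsAsFactors = FALSE)
  }))
  viol <- violation_report(dm$matrix, ranges)
  viol$set <- set_of
  imp <- property_importance(model, scaled,
                             n_pcs = min(dims, ncol(model$coefficients)))
  structure(list(descriptor_matrix = dm$matrix, set_of = set_of,
                 scaling = sc_par, model = model, scores = scores,
                 ellipsoids = ells, universe = universe,
                 distances = dists, violations = viol, importance = imp,
                 reference = reference, dims = dims, coverage = coverage),
            class = "mc_study")
}

#' @export
print.mc_study <- function(x, ...) {
  cat(sprintf("<mc_study: %d compounds in %d sets, reference '%s'>\n",
              nrow(x$descriptor_matrix), length(x$ellipsoids), x$reference))
  df <- x$distances
  df$volume <- vapply(df$set, function(s) x$ellipsoids[[s]]$volume, 0)
  df$avg_radius <- vapply(df$set, function(s) x$ellipsoids[[s]]$avg_radius, 0)
  print(df, row.names = FALSE)
  invisible(x)
}
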