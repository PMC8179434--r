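# Ring perception --------------------------------------------------------
#
# The macrocycle ring is selected with a two-stage policy:
#   1. compute a minimum cycle basis (Horton candidates + GF(2) greedy
#      selection) per ring system; if the largest basis ring reaches the
#      macrocycle threshold it is the MC ring (so an ortho-fused benzene
#      never promotes the fused envelope over the macrocycle itself);
#   2. otherwise enumerate simple cycles in the ring system under a node
#      budget and take the largest (recovering bridged macrocycles whose
#      large ring is absent from any minimal basis).
# Ties are broken by the lexicographically smallest sorted atom-index tuple.

# ring systems = biconnected components with at least 3 vertices
ring_systems <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(list())
  g <- mol_to_igraph(mol)
  bc <- igraph::biconnected_components(g)
  comps <- lapply(bc$components, function(v) sort(as.integer(v)))
  comps[vapply(comps, length, 1L) >= 3L]
}

# edges of mol as two-column matrix restricted to an atom set
.edges_within <- function(mol, atoms_set) {
  b <- mol$bonds
  keep <- b$a1 %in% atoms_set & b$a2 %in% atoms_set
  cbind(b$a1[keep], b$a2[keep])
}

# Minimum cycle basis of the subgraph induced on `atoms_set`.
# Horton: for each vertex v and edge (x,y), candidate cycle = SP(v,x) +
# SP(v,y) + (x,y) when the two paths are disjoint; greedily select
# candidates independent over GF(2), shortest first.
min_cycle_basis <- function(mol, atoms_set = seq_len(n_atoms(mol))) {
  em <- .edges_within(mol, atoms_set)
  nv <- length(atoms_set)
  ne <- nrow(em)
  dim_cycle <- ne - nv + 1L  # connected ring system
  if (ne == 0L || dim_cycle <= 0L) return(list())
  idx <- stats::setNames(seq_along(atoms_set), atoms_set)
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[as.character(em[, 1])],
                                  idx[as.character(em[, 2])]))
  ekey <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "-")
  emap <- stats::setNames(seq_len(ne), ekey)

  cand <- list()
  sp <- igraph::distances(g)
  paths_from <- lapply(seq_len(nv), function(v)
    igraph::shortest_paths(g, from = v, to = igraph::V(g))$vpath)
  for (v in seq_len(nv)) {
    for (k in seq_len(ne)) {
      x <- idx[as.character(em[k, 1])]; y <- idx[as.character(em[k, 2])]
      px <- as.integer(paths_from[[v]][[x]])
      py <- as.integer(paths_from[[v]][[y]])
      if (length(px) == 0L || length(py) == 0L) next
      if (length(intersect(px[-1], py[-1])) > 0L) next  # share beyond v
      cyc <- unique(c(px, rev(py)))
      if (length(cyc) < 3L) next
      cand[[length(cand) + 1L]] <- cyc
    }
  }
  if (length(cand) == 0L) return(list())
  # deduplicate and sort by length
  keyf <- function(cy) paste(sort(cy), collapse = ",")
  cand <- cand[!duplicated(vapply(cand, keyf, ""))]
  cand <- cand[order(vapply(cand, length, 1L),
                     vapply(cand, keyf, ""))]

  # edge-incidence vector over GF(2) for a vertex cycle (ordered walk)
  evec <- function(cy) {
    v <- logical(ne)
    m <- length(cy)
    verts_old <- atoms_set[cy]
    for (t in seq_len(m)) {
      a <- verts_old[t]; b <- verts_old[if (t == m) 1L else t + 1L]
      kk <- emap[paste(min(a, b), max(a, b), sep = "-")]
      if (is.na(kk)) return(NULL)  # walk uses a non-edge; not a valid cycle
      v[kk] <- TRUE
    }
    v
  }
  basis <- list()
  pivot_vec <- vector("list", ne)  # reduced vector stored under its pivot
  for (cy in cand) {
    if (length(basis) >= dim_cycle) break
    r <- evec(cy)
    if (is.null(r)) next
    # incremental GF(2) elimination keyed by pivot position
    repeat {
      p <- which(r)[1]
      if (is.na(p)) break
      if (is.null(pivot_vec[[p]])) break
      r <- xor(r, pivot_vec[[p]])
    }
    if (any(r)) {
      pivot_vec[[which(r)[1]]] <- r
      basis[[length(basis) + 1L]] <- sort(atoms_set[cy])
    }
  }
  # return ordered atom cycles (original indices, cycle order)
  lapply(basis, function(s) .order_cycle(mol, s))
}

# order a set of atoms known to form a simple cycle into traversal order
.order_cycle <- function(mol, atoms_set) {
  adj <- mol_adjacency(mol)
  s <- as.integer(atoms_set)
  start <- min(s)
  ord <- start
  prev <- NA_integer_
  cur <- start
  repeat {
    nb <- intersect(adj[[cur]], s)
    nb <- nb[is.na(prev) | nb != prev]
    nxt <- if (length(nb) > 1L) min(nb) else nb
    if (nxt == start) break
    ord <- c(ord, nxt)
    prev <- cur
    cur <- nxt
    if (length(ord) > length(s)) stop("atom set is not a simple cycle")
  }
  ord
}

#' Enumerate simple cycles of a ring system
#'
#' Backtracking enumeration restricted to one ring system. Each cycle is
#' reported once with its minimal vertex as anchor. A node budget caps the
#' number of DFS expansions.
#'
#' @param mol an `mc_mol`.
#' @param atoms_set atoms of one ring system.
#' @param budget maximum number of search-tree expansions before a
#'   `mcspace_complexity` error condition is raised.
#' @param min_size discard cycles shorter than this.
#' @return list of ordered atom-index cycles.
#' @export
enumerate_simple_cycles <- function(mol, atoms_set, budget = 2e5L,
                                    min_size = 3L) {
  s <- sort(as.integer(atoms_set))
  adj <- mol_adjacency(mol)
  adj <- lapply(adj, function(x) intersect(x, s))
  cycles <- list()
  expansions <- 0L
  for (start in s) {
    in_path <- logical(n_atoms(mol))
    path <- integer(0)
    dfs <- function(v) {
      expansions <<- expansions + 1L
      if (expansions > budget)
        stop(errorCondition("cycle enumeration budget exceeded",
                            class = "mcspace_complexity"))
      in_path[v] <<- TRUE
      path <<- c(path, v)
      for (w in adj[[v]]) {
        if (w < start) next  # cycles anchored at their minimal vertex
        if (w == start && length(path) >= min_size) {
          # canonical direction: second vertex smaller than last
          if (path[2] < path[length(path)])
            cycles[[length(cycles) + 1L]] <<- path
        } else if (!in_path[w]) {
          dfs(w)
        }
      }
      in_path[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(start)
  }
  cycles
}

#' Find the macrocycle ring of a molecule
#'
#' Applies the two-stage ring-selection policy described above. Returns the
#' ring as an ordered cycle of atom indices starting at the smallest index.
#'
#' @param mol an `mc_mol`.
#' @param min_ring_size smallest ring size that qualifies as a macrocycle.
#' @param budget node budget for the fallback simple-cycle enumeration.
#' @return integer vector of atom indices in cycle order.
#' @export
find_mc_ring <- function(mol, min_ring_size = 11L, budget = 2e5L) {
  lr <- largest_ring(mol, budget = budget)
  if (is.null(lr) || length(lr) < min_ring_size)
    stop(errorCondition(
      sprintf("no ring of >= %d atoms (largest: %d)", min_ring_size,
              if (is.null(lr)) 0L else length(lr)),
      class = "mcspace_no_macrocycle"))
  lr
}

#' Largest ring of a molecule under the selection policy
#'
#' @inheritParams find_mc_ring
#' @return ordered atom cycle, or `NULL` for acyclic molecules.
#' @export
largest_ring <- function(mol, budget = 2e5L) {
  rs <- ring_systems(mol)
  if (length(rs) == 0L) return(NULL)
  best <- NULL
  for (sys in rs) {
    cand <- .largest_in_system(mol, sys, budget)
    if (is.null(best) || .cycle_beats(cand, best)) best <- cand
  }
  best
}

.cycle_beats <- function(a, b) {
  if (length(a) != length(b)) return(length(a) > length(b))
  # deterministic tie-break: smallest lexicographic sorted tuple wins
  sa <- sort(a); sb <- sort(b)
  d <- which(sa != sb)
  if (length(d) == 0L) return(FALSE)
  sa[d[1]] < sb[d[1]]
}

.largest_in_system <- function(mol, sys, budget) {
  basis <- min_cycle_basis(mol, sys)
  nb <- length(basis)
  basis_best <- NULL
  for (cy in basis)
    if (is.null(basis_best) || .cycle_beats(cy, basis_best)) basis_best <- cy
  if (nb <= 1L) return(basis_best)
  all_cyc <- enumerate_simple_cycles(mol, sys, budget = budget)
  enum_best <- NULL
  for (cy in all_cyc)
    if (is.null(enum_best) || .cycle_beats(cy, enum_best)) enum_best <- cy
  if (is.null(enum_best)) return(basis_best)
  .select_policy(basis_best, enum_best, basis)
}

# Choose between the largest minimal-basis ring and the largest enumerated
# simple cycle. An enumerated cycle that contains every atom of some basis
# ring is a fused-system envelope (e.g. benzo-fused macrocycle, naphthalene
# perimeter) and is rejected in favour of the basis ring. A larger cycle
# containing no basis ring entirely only exists as a bridged combination
# (e.g. ansa bridges splitting the macrocycle into two basis rings) and is
# accepted as the macrocycle. Fusions sharing a path of >= 2 bonds fall to
# the bridged branch; such compounds are rare and flagged downstream by the
# multi-fusion detector.
.select_policy <- function(basis_best, enum_best, basis) {
  if (is.null(basis_best)) return(enum_best)
  if (length(enum_best) <= length(basis_best)) return(basis_best)
  eb <- sort(enum_best)
  for (cy in basis) {
    if (length(setdiff(cy, eb)) == 0L) return(basis_best)
  }
  enum_best
}

# bonds (row indices into mol$bonds) that are part of any ring
ring_bond_rows <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(integer(0))
  g <- mol_to_igraph(mol)
  br <- igraph::bridges(g)
  setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
}

# is edge (u,v) of the MC ring shared with another ring?  After deleting
# the edge, u and v sharing a biconnected block that contains a cycle
# means a second, distinct cycle passes through the bond.
edge_in_other_ring <- function(mol, u, v) {
  k <- bond_between(mol, u, v)
  if (is.na(k)) stop("no bond between atoms ", u, " and ", v)
  g <- mol_to_igraph(mol)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
  bc <- igraph::biconnected_components(g2)
  for (comp in bc$components) {
    vv <- as.integer(comp)
    if (length(vv) >= 3L && u %in% vv && v %in% vv) return(TRUE)
  }
  FALSE
}
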