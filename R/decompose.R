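# Macrocycle decomposition ----------------------------------------------
#
# Partition of heavy atoms into three positional classes:
#   ring        -- atoms of the macrocycle ring itself
#   peripheral  -- single heavy atoms appended directly to the ring
#                  (methyl C, hydroxyl O, carbonyl O, halogen, imine N)
#   substituent -- connected groups of >= 2 heavy atoms attached to the
#                  ring, including rings fused or spiro-joined to it
# plus the substituent gap profile and ring-rigidity analysis.

#' Decompose a macrocycle into ring / peripheral / substituent classes
#'
#' @param mol an `mc_mol`.
#' @param min_ring_size macrocycle threshold passed to [find_mc_ring()].
#' @param ring optional pre-computed ring (ordered atom cycle).
#' @param budget cycle-enumeration budget.
#' @return an object of class `mc_decomposition` with fields `ring_atoms`
#'   (ordered cycle), `N` (ring size), `peripheral` (data.frame: atom,
#'   element, ring_atom, bond_order), `substituents` (list; each has
#'   `atoms`, `attachment_ring_atoms`, `fused`, `spiro`, `n_spiro_rings`),
#'   and `multifusion` (logical).
#' @export
decompose <- function(mol, min_ring_size = 11L, ring = NULL, budget = 2e5L) {
  if (is.null(ring)) ring <- find_mc_ring(mol, min_ring_size, budget)
  classify_atoms(mol, ring)
}

#' Classify atoms relative to a macrocycle ring
#'
#' @param mol an `mc_mol`.
#' @param ring ordered atom cycle (from [find_mc_ring()]).
#' @return `mc_decomposition`; see [decompose()].
#' @export
classify_atoms <- function(mol, ring) {
  ring <- as.integer(ring)
  N <- length(ring)
  ring_set <- ring
  adj <- mol_adjacency(mol)
  others <- setdiff(seq_len(n_atoms(mol)), ring_set)

  peripheral <- data.frame(atom = integer(), element = character(),
                           ring_atom = integer(), bond_order = integer(),
                           stringsAsFactors = FALSE)
  substituents <- list()

  if (length(others) > 0L) {
    # connected components of the off-ring atoms
    sub <- mol_subgraph(mol, others)
    comp <- igraph::components(mol_to_igraph(sub$mol))
    groups <- split(sub$old_index, comp$membership)
    bmap <- bond_index_map(mol)
    for (grp in groups) {
      grp <- sort(as.integer(grp))
      ring_nbrs <- sort(unique(unlist(lapply(grp, function(a)
        intersect(adj[[a]], ring_set)))))
      if (length(grp) == 1L && length(ring_nbrs) == 1L) {
        k <- bond_between(mol, grp, ring_nbrs, bmap)
        peripheral <- rbind(peripheral, data.frame(
          atom = grp, element = mol$atoms$element[grp],
          ring_atom = ring_nbrs, bond_order = mol$bonds$order[k],
          stringsAsFactors = FALSE))
      } else {
        # order attachments by position around the ring
        pos <- match(ring_nbrs, ring)
        att <- ring_nbrs[order(pos)]
        fl <- .fusion_flags(mol, grp, att)
        substituents[[length(substituents) + 1L]] <- list(
          atoms = grp, attachment_ring_atoms = att,
          fused = fl$fused, spiro = fl$spiro,
          n_spiro_rings = fl$n_spiro_rings, n_fused_blocks = fl$n_fused_blocks,
          block_max_ring_atoms = fl$block_max_ring_atoms)
      }
    }
  }

  # cycle basis of the macrocycle's ring system, cached for the rigidity
  # descriptors and the multi-fusion detector
  rs <- ring_systems(mol)
  sys <- NULL
  for (s in rs) if (all(ring %in% s)) { sys <- s; break }
  basis <- if (is.null(sys)) list() else min_cycle_basis(mol, sys)
  edge_keys <- function(cy)
    paste(pmin(cy, c(cy[-1], cy[1])), pmax(cy, c(cy[-1], cy[1])), sep = "-")
  ring_key <- paste(sort(ring), collapse = ",")
  fusion_edges <- unique(unlist(lapply(basis, function(cy) {
    if (paste(sort(cy), collapse = ",") == ring_key) character(0)
    else edge_keys(cy)
  })))
  if (is.null(fusion_edges)) fusion_edges <- character(0)

  out <- structure(list(
    ring_atoms = ring, N = N, peripheral = peripheral,
    substituents = substituents, multifusion = FALSE,
    ring_basis = basis, fusion_edges = fusion_edges),
    class = "mc_decomposition")
  out$multifusion <- any(vapply(substituents, function(s)
    s$block_max_ring_atoms >= 3L, TRUE)) ||
    .basis_multifusion_cached(basis, ring)
  out
}

# Complementary multi-fusion detector working on the minimum cycle basis of
# the macrocycle's ring system: two or more non-MC basis rings that each
# share >= 2 atoms with the MC ring and share >= 1 bond with each other.
# Robust to the MC-ring selection made for peri-fused envelopes.
.basis_multifusion_cached <- function(basis, ring) {
  if (length(basis) < 3L) return(FALSE)  # MC + at least two others needed
  ring_set <- sort(ring)
  edge_set <- function(cy) {
    paste(pmin(cy, c(cy[-1], cy[1])), pmax(cy, c(cy[-1], cy[1])), sep = "-")
  }
  fused <- list()
  for (cy in basis) {
    if (identical(sort(cy), ring_set)) next
    if (length(intersect(cy, ring)) >= 2L)
      fused[[length(fused) + 1L]] <- edge_set(cy)
  }
  if (length(fused) < 2L) return(FALSE)
  for (i in seq_len(length(fused) - 1L))
    for (j in (i + 1L):length(fused))
      if (length(intersect(fused[[i]], fused[[j]])) >= 1L) return(TRUE)
  FALSE
}

# fused / spiro analysis of one substituent group: build the subgraph on
# group atoms + attachment ring atoms (with the molecule's bonds restricted
# to those atoms, including ring bonds between adjacent attachments) and
# inspect its biconnected blocks.
.fusion_flags <- function(mol, grp, att) {
  h_atoms <- c(grp, att)
  sub <- mol_subgraph(mol, h_atoms)
  g <- mol_to_igraph(sub$mol)
  bc <- igraph::biconnected_components(g)
  fused <- FALSE; n_spiro <- 0L; n_fused_blocks <- 0L; max_ra <- 0L
  for (comp in bc$components) {
    vv <- sub$old_index[as.integer(comp)]
    if (length(vv) < 3L) next  # acyclic block (single bond)
    n_ring_in_block <- sum(vv %in% att)
    max_ra <- max(max_ra, n_ring_in_block)
    if (n_ring_in_block >= 2L) { fused <- TRUE; n_fused_blocks <- n_fused_blocks + 1L }
    if (n_ring_in_block == 1L) n_spiro <- n_spiro + 1L
  }
  list(fused = fused, spiro = n_spiro > 0L, n_spiro_rings = n_spiro,
       n_fused_blocks = n_fused_blocks, block_max_ring_atoms = max_ra)
}

#' @export
print.mc_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<mc_decomposition: N=%d, %d peripheral, ",
                     "%d substituents%s>\n"),
              x$N, nrow(x$peripheral), length(x$substituents),
              if (x$multifusion) ", MULTIFUSION" else ""))
  invisible(x)
}

#' Detect multi-fusion (peri-fusion) exceptions
#'
#' A compound is a multi-fusion exception when two or more rings are fused
#' to the macrocycle ring and also fused to each other, detected as a
#' biconnected block of a substituent's attachment subgraph containing
#' three or more macrocycle ring atoms.
#'
#' @param decomp an `mc_decomposition`.
#' @param policy `"merge"` treats the peri-fused system as one fused
#'   substituent (the decomposition is kept as computed); `"exception"`
#'   marks the compound for routing to the exceptions output.
#' @return list with `multifusion` (logical) and `action`
#'   (`"none"`, `"merged"` or `"exception"`).
#' @export
detect_multifusion <- function(decomp, policy = c("merge", "exception")) {
  policy <- match.arg(policy)
  mf <- isTRUE(decomp$multifusion)
  action <- if (!mf) "none" else if (policy == "merge") "merged" else "exception"
  list(multifusion = mf, action = action)
}

#' Gap profile of a decomposition
#'
#' A gap is the number of ring atoms between the attachment points of a
#' pair of adjacent substituents, walking once around the macrocycle ring.
#' Attachment points are ring atoms bonded to at least one substituent
#' group; with `include_peripheral = TRUE` ring atoms bearing peripheral
#' groups also delimit gaps (used by the ring-complexity descriptor, never
#' the default). Conventions: one attachment point gives the single gap
#' `N - 1`; zero attachment points give max = min = mean = `N` with zero
#' spread. Zero-length runs between adjacent attachment points count as
#' gaps of size 0, so that `sum(gaps) + n_attachment = N`. The standard
#' deviation is the population form.
#'
#' @param decomp an `mc_decomposition`.
#' @param include_peripheral also treat peripheral-bearing ring atoms as
#'   attachment points.
#' @return list with `gaps`, `attachment_points`, `max_gap`, `min_gap`,
#'   `mean_gap`, `stdev_gap` and the `/N`-normalized variants.
#' @export
compute_gaps <- function(decomp, include_peripheral = FALSE) {
  ring <- decomp$ring_atoms
  N <- decomp$N
  att <- unique(unlist(lapply(decomp$substituents, function(s)
    s$attachment_ring_atoms)))
  if (include_peripheral)
    att <- unique(c(att, decomp$peripheral$ring_atom))
  att_pos <- sort(match(att, ring))
  k <- length(att_pos)
  if (k == 0L) {
    gaps <- integer(0)
    stats <- c(max_gap = N, min_gap = N, mean_gap = N, stdev_gap = 0)
  } else if (k == 1L) {
    gaps <- N - 1L
    stats <- c(max_gap = gaps, min_gap = gaps, mean_gap = gaps, stdev_gap = 0)
  } else {
    nxt <- c(att_pos[-1], att_pos[1] + N)
    gaps <- nxt - att_pos - 1L
    m <- mean(gaps)
    stats <- c(max_gap = max(gaps), min_gap = min(gaps), mean_gap = m,
               stdev_gap = sqrt(mean((gaps - m)^2)))
  }
  c(list(gaps = gaps, attachment_points = ring[att_pos]),
    as.list(stats),
    stats::setNames(as.list(stats / N),
                    paste0(names(stats), "_over_N")))
}

# is bond row k an amide C-N bond (carbonyl on either end)?
.is_amide_bond <- function(mol, k, adj, bmap) {
  b <- mol$bonds[k, ]
  for (swap in 0:1) {
    cC <- if (swap == 0) b$a1 else b$a2
    nN <- if (swap == 0) b$a2 else b$a1
    if (mol$atoms$element[cC] != "C" || mol$atoms$element[nN] != "N") next
    if (b$order != 1L || b$aromatic) next
    for (o in adj[[cC]]) {
      if (mol$atoms$element[o] != "O") next
      ko <- bond_between(mol, cC, o, bmap)
      if (mol$bonds$order[ko] == 2L) return(TRUE)
    }
  }
  FALSE
}

#' Restricted fraction of the macrocycle ring
#'
#' Fraction of ring bonds rigidified beyond ring membership: pi bonds
#' (double, triple or aromatic), amide C-N bonds with the carbonyl on
#' either atom, and bonds shared with another ring (fusions, with or
#' without bridges).
#'
#' @param decomp an `mc_decomposition`.
#' @param mol the corresponding `mc_mol`.
#' @return numeric in `[0, 1]`.
#' @export
restricted_fraction <- function(decomp, mol) {
  ring <- decomp$ring_atoms
  N <- decomp$N
  adj <- mol_adjacency(mol)
  bmap <- bond_index_map(mol)
  restricted <- 0L
  for (t in seq_len(N)) {
    u <- ring[t]; v <- ring[if (t == N) 1L else t + 1L]
    k <- bond_between(mol, u, v, bmap)
    b <- mol$bonds[k, ]
    rigid <- b$aromatic || b$order >= 2L ||
      .is_amide_bond(mol, k, adj, bmap) ||
      paste(min(u, v), max(u, v), sep = "-") %in% decomp$fusion_edges
    if (rigid) restricted <- restricted + 1L
  }
  restricted / N
}

# count of ring amide C-N bonds (used by the peptide character index)
ring_amide_bonds <- function(decomp, mol) {
  ring <- decomp$ring_atoms
  N <- decomp$N
  adj <- mol_adjacency(mol)
  bmap <- bond_index_map(mol)
  n <- 0L
  for (t in seq_len(N)) {
    u <- ring[t]; v <- ring[if (t == N) 1L else t + 1L]
    k <- bond_between(mol, u, v, bmap)
    if (.is_amide_bond(mol, k, adj, bmap)) n <- n + 1L
  }
  n
}

# count of ring double/triple/aromatic bonds
ring_pi_bonds <- function(decomp, mol) {
  ring <- decomp$ring_atoms
  N <- decomp$N
  bmap <- bond_index_map(mol)
  n <- 0L
  for (t in seq_len(N)) {
    u <- ring[t]; v <- ring[if (t == N) 1L else t + 1L]
    k <- bond_between(mol, u, v, bmap)
    if (mol$bonds$aromatic[k] || mol$bonds$order[k] >= 2L) n <- n + 1L
  }
  n
}

# count of ring bonds shared with another ring
ring_fusion_bonds <- function(decomp, mol) {
  ring <- decomp$ring_atoms
  N <- decomp$N
  keys <- paste(pmin(ring, c(ring[-1], ring[1])),
                pmax(ring, c(ring[-1], ring[1])), sep = "-")
  sum(keys %in% decomp$fusion_edges)
}

#' Export a decomposition as JSON
#'
#' @param decomp an `mc_decomposition`.
#' @param path file to write; when `NULL` the JSON string is returned.
#' @return path (invisibly) or JSON string. Atom indices are 0-based in
#'   the export, matching common cheminformatics conventions.
#' @export
decomposition_to_json <- function(decomp, path = NULL) {
  obj <- list(
    ring_atoms = decomp$ring_atoms - 1L,
    N = decomp$N,
    peripheral = lapply(seq_len(nrow(decomp$peripheral)), function(i)
      list(atom = decomp$peripheral$atom[i] - 1L,
           element = decomp$peripheral$element[i],
           ring_atom = decomp$peripheral$ring_atom[i] - 1L)),
    substituents = lapply(decomp$substituents, function(s)
      list(atoms = s$atoms - 1L,
           attachment_ring_atoms = s$attachment_ring_atoms - 1L,
           fused = s$fused, spiro = s$spiro)),
    multifusion = decomp$multifusion)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
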