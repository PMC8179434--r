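# Molecular graph container ----------------------------------------------

#' Construct a molecular graph
#'
#' `mc_mol` is the package's heavy-atom molecular graph: hydrogens are always
#' implicit, and every atom carries element, aromaticity, formal charge,
#' explicit-H override and a stereo flag. It is the common currency between
#' the SMILES/SDF readers, the synthetic generator and the decomposition and
#' descriptor machinery.
#'
#' @param atoms data.frame with columns `element` (character), `aromatic`
#'   (logical), `charge` (integer), `hcount` (integer, `NA` = derive from
#'   standard valence), `chiral` (character: `""`, `"@"` or `"@@"`).
#'   Missing columns are filled with defaults.
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical). Aromatic bonds carry
#'   `order = 1` plus the flag.
#' @param id optional compound identifier.
#' @param source optional provenance string (file and record index).
#' @return an object of class `mc_mol`.
#' @export
mc_mol <- function(atoms, bonds = NULL, id = NA_character_, source = NA_character_) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot("element" %in% names(atoms))
  n <- nrow(atoms)
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$charge))   atoms$charge   <- 0L
  if (is.null(atoms$hcount))   atoms$hcount   <- NA_integer_
  if (is.null(atoms$chiral))   atoms$chiral   <- ""
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$charge   <- as.integer(atoms$charge)
  atoms$hcount   <- as.integer(atoms$hcount)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = integer(), aromatic = logical())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond endpoint out of range")
    if (any(bonds$a1 == bonds$a2)) stop("self-bond not allowed")
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, id = id, source = source),
                   class = "mc_mol")
  mol$atoms$nH <- implicit_hydrogens(mol)
  mol
}

#' @export
print.mc_mol <- function(x, ...) {
  cat(sprintf("<mc_mol %s: %d heavy atoms, %d bonds>\n",
              if (is.na(x$id)) "(unnamed)" else x$id,
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list: integer vectors of neighbor atom indices
mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# bond lookup matrix keyed "i-j" with i<j -> row index in mol$bonds
bond_index_map <- function(mol) {
  b <- mol$bonds
  key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2), sep = "-")
  stats::setNames(seq_len(nrow(b)), key)
}

bond_between <- function(mol, i, j, map = NULL) {
  if (is.null(map)) map <- bond_index_map(mol)
  unname(map[paste(min(i, j), max(i, j), sep = "-")])
}

# Standard organic-subset valences; for N/P/S the smallest standard valence
# that accommodates the explicit bond order sum is used.
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# Bond-order sum per atom; aromatic bonds count 1 here (an aromatic carbon
# with two ring connections then receives one implicit H via the +1 rule
# below, matching the usual SMILES convention).
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  ord <- ifelse(b$aromatic, 1L, b$order)
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + ord[k]
    s[b$a2[k]] <- s[b$a2[k]] + ord[k]
  }
  s
}

implicit_hydrogens <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  bos <- bond_order_sums(mol)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(at$hcount[i])) { out[i] <- at$hcount[i]; next }
    el <- at$element[i]
    vals <- .default_valences[[el]]
    if (is.null(vals)) { out[i] <- 0L; next }
    need <- bos[i]
    # aromatic atoms: carbon gets one valence unit consumed by the
    # delocalized system; unbracketed aromatic N/O/S carry no implicit H
    if (at$aromatic[i]) {
      if (el == "C") need <- need + 1L else { out[i] <- 0L; next }
    }
    # charge adjustment for the common organic cases (e.g. [O-], [N+])
    v <- vals[vals + at$charge[i] >= need]
    if (length(v) == 0L) { out[i] <- 0L; next }
    out[i] <- max(0L, as.integer(v[1] + at$charge[i] - need))
  }
  out
}

element_counts <- function(mol, idx = seq_len(n_atoms(mol))) {
  table(factor(mol$atoms$element[idx],
               levels = c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")))
}

#' Convert a molecule to an igraph graph
#'
#' Vertices carry `element`, `aromatic` and `charge`; edges carry `order`
#' and `aromatic`. Used internally for connectivity, biconnectivity and
#' isomorphism checks.
#' @param mol an `mc_mol`.
#' @return an `igraph` object.
#' @export
mol_to_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
  g <- igraph::set_vertex_attr(g, "aromatic", value = mol$atoms$aromatic)
  g <- igraph::set_vertex_attr(g, "charge", value = mol$atoms$charge)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
    g <- igraph::set_edge_attr(g, "order", value = mol$bonds$order)
    g <- igraph::set_edge_attr(g, "aromatic", value = mol$bonds$aromatic)
  }
  g
}

#' Test whether two molecules have isomorphic labelled graphs
#'
#' VF2 isomorphism with atoms distinguished by element/aromatic/charge and
#' bonds by order/aromatic flag. Used by the SMILES round-trip checks.
#' @param a,b `mc_mol` objects.
#' @return logical.
#' @export
mol_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  code <- function(m) {
    as.integer(factor(paste(m$atoms$element, m$atoms$aromatic, m$atoms$charge),
                      levels = sort(unique(c(
                        paste(a$atoms$element, a$atoms$aromatic, a$atoms$charge),
                        paste(b$atoms$element, b$atoms$aromatic, b$atoms$charge))))))
  }
  ecode <- function(m) as.integer(m$bonds$order + ifelse(m$bonds$aromatic, 10L, 0L))
  ga <- mol_to_igraph(a); gb <- mol_to_igraph(b)
  igraph::isomorphic(ga, gb, method = "vf2",
                     vertex.color1 = code(a), vertex.color2 = code(b),
                     edge.color1 = ecode(a), edge.color2 = ecode(b))
}

# connected components as list of atom-index vectors, largest first
mol_components <- function(mol) {
  g <- mol_to_igraph(mol)
  comp <- igraph::components(g)
  out <- split(seq_len(n_atoms(mol)), comp$membership)
  out[order(vapply(out, length, 1L), decreasing = TRUE)]
}

# induced submolecule on a set of atoms (re-indexed); returns mol + index map
mol_subgraph <- function(mol, atoms_keep) {
  atoms_keep <- sort(unique(as.integer(atoms_keep)))
  map <- stats::setNames(seq_along(atoms_keep), atoms_keep)
  at <- mol$atoms[atoms_keep, , drop = FALSE]
  rownames(at) <- NULL
  b <- mol$bonds
  keep <- b$a1 %in% atoms_keep & b$a2 %in% atoms_keep
  b <- b[keep, , drop = FALSE]
  if (nrow(b) > 0L) {
    b$a1 <- unname(map[as.character(b$a1)])
    b$a2 <- unname(map[as.character(b$a2)])
  }
  newmol <- mc_mol(at[c("element", "aromatic", "charge", "hcount", "chiral")],
                   b, id = mol$id, source = mol$source)
  list(mol = newmol, old_index = atoms_keep)
}
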