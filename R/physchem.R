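# Classic physicochemical descriptors -----------------------------------

.atomic_masses <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, F = 18.998, Cl = 35.45,
                    Br = 79.904, I = 126.904)

#' Molecular weight (average atomic masses, implicit H included)
#' @param mol an `mc_mol`.
#' @return numeric, g/mol.
#' @export
molecular_weight <- function(mol) {
  sum(.atomic_masses[mol$atoms$element]) + sum(mol$atoms$nH) * .atomic_masses[["H"]]
}

# per-atom summary used by tPSA / clogP / hybridization typing
.atom_env <- function(mol) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  b <- mol$bonds
  n_single <- n_double <- n_triple <- n_arom <- integer(n)
  for (k in seq_len(nrow(b))) {
    for (a in c(b$a1[k], b$a2[k])) {
      if (b$aromatic[k]) n_arom[a] <- n_arom[a] + 1L
      else if (b$order[k] == 1L) n_single[a] <- n_single[a] + 1L
      else if (b$order[k] == 2L) n_double[a] <- n_double[a] + 1L
      else n_triple[a] <- n_triple[a] + 1L
    }
  }
  list(adj = adj, n_single = n_single, n_double = n_double,
       n_triple = n_triple, n_arom = n_arom,
       degree = n_single + n_double + n_triple + n_arom)
}

#' Topological polar surface area (Ertl-type fragment contributions)
#'
#' N/O contributions follow the published fragment values; S and P
#' contributions are included, matching common implementations. Values are
#' close to, but not bit-identical with, commercial calculators.
#'
#' @param mol an `mc_mol`.
#' @return numeric, Angstrom^2.
#' @export
tpsa <- function(mol) {
  env <- .atom_env(mol)
  at <- mol$atoms
  total <- 0
  for (i in seq_len(n_atoms(mol))) {
    el <- at$element[i]
    if (!el %in% c("N", "O", "S", "P")) next
    h <- at$nH[i]; q <- at$charge[i]
    s1 <- env$n_single[i]; d <- env$n_double[i]; t <- env$n_triple[i]
    ar <- env$n_arom[i]
    contrib <- if (el == "N") {
      if (ar >= 2L) {                       # aromatic nitrogen
        if (q > 0) { if (h >= 1L) 14.14 else 4.10 }
        else if (h >= 1L) 15.79
        else if (ar == 3L) 4.41
        else if (s1 >= 1L) 4.93
        else if (d >= 1L) 8.39
        else 12.89
      } else if (q > 0) {
        if (h == 3L) 27.64 else if (h == 2L) 16.61
        else if (h == 1L) 4.44 else if (d >= 1L) 3.01 else 0.00
      } else if (h == 0L) {
        if (t >= 1L && d >= 1L) 13.60
        else if (t >= 1L) 23.79
        else if (d >= 2L) 11.68
        else if (d == 1L) 12.36
        else 3.24
      } else if (h == 1L) {
        if (d >= 1L) 23.85 else 12.03
      } else 26.02
    } else if (el == "O") {
      if (ar >= 2L) 13.14
      else if (q < 0) 23.06
      else if (d >= 1L) 17.07
      else if (h >= 1L) 20.23
      else 9.23
    } else if (el == "S") {
      if (ar >= 2L) { if (d >= 1L) 21.70 else 28.24 }
      else if (h >= 1L) 38.80
      else if (d >= 2L) 8.38
      else if (d == 1L) { if (s1 >= 2L) 19.21 else 32.09 }
      else 25.30
    } else {                               # P
      if (d >= 1L && s1 >= 3L) 9.81
      else if (d >= 1L) 34.14
      else if (h >= 1L) 23.47
      else 13.59
    }
    total <- total + contrib
  }
  total
}

#' Computed logP (Crippen-type atomic contributions)
#'
#' Reduced atomic-contribution scheme in the spirit of the Wildman-Crippen
#' parameterization: atoms are typed by element, aromaticity, hybridization
#' and heteroatom attachment, and implicit hydrogens contribute by the
#' element they attach to. Values track commercial clogP implementations
#' qualitatively, not bit-exactly.
#'
#' @param mol an `mc_mol`.
#' @return numeric.
#' @export
clogp <- function(mol) {
  env <- .atom_env(mol)
  at <- mol$atoms
  hetero <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")
  total <- 0
  for (i in seq_len(n_atoms(mol))) {
    el <- at$element[i]
    nbr_el <- at$element[env$adj[[i]]]
    has_het <- any(nbr_el %in% hetero)
    dbl_het <- FALSE
    if (env$n_double[i] > 0L) {
      for (k in seq_len(nrow(mol$bonds))) {
        b <- mol$bonds[k, ]
        if (b$order == 2L && !b$aromatic &&
            (b$a1 == i || b$a2 == i)) {
          other <- if (b$a1 == i) b$a2 else b$a1
          if (at$element[other] %in% hetero) dbl_het <- TRUE
        }
      }
    }
    ac <- if (el == "C") {
      if (at$aromatic[i]) {
        if (at$nH[i] >= 1L) 0.1581 else 0.1360
      } else if (dbl_het) -0.2783
      else if (env$n_double[i] + env$n_triple[i] > 0L) 0.1551
      else if (has_het) { if (env$degree[i] >= 3L) -0.2051 else -0.2035 }
      else { if (env$degree[i] >= 3L) 0.0000 else 0.1441 }
    } else if (el == "N") {
      if (at$aromatic[i]) -0.3239
      else if (at$charge[i] > 0L) -1.0000  # protonated/quaternary N
      else if (env$n_triple[i] > 0L) -0.3396
      else if (.n_has_carbonyl_neighbor(mol, i, env)) -0.4458
      else if (at$nH[i] == 2L) -1.0190
      else if (at$nH[i] == 1L) -0.7096
      else -0.3187
    } else if (el == "O") {
      if (at$aromatic[i]) 0.1552
      else if (at$charge[i] < 0L) -1.3260
      else if (env$n_double[i] > 0L) -0.1526
      else if (at$nH[i] >= 1L) -0.2893
      else -0.0684
    } else if (el == "S") {
      if (at$aromatic[i]) 0.6237 else 0.6482
    } else if (el == "P") 0.8612
    else if (el == "F") 0.4202
    else if (el == "Cl") 0.6895
    else if (el == "Br") 0.8456
    else if (el == "I") 0.8857
    else 0
    hc <- at$nH[i] * switch(el, O = -0.2677, N = 0.2142, S = 0.2142, 0.1230)
    total <- total + ac + hc
  }
  total
}

.n_has_carbonyl_neighbor <- function(mol, i, env) {
  for (j in env$adj[[i]]) {
    if (mol$atoms$element[j] != "C") next
    for (o in env$adj[[j]]) {
      if (mol$atoms$element[o] != "O") next
      k <- bond_between(mol, j, o)
      if (mol$bonds$order[k] == 2L && !mol$bonds$aromatic[k]) return(TRUE)
    }
  }
  FALSE
}

#' Hydrogen-bond donor count (H on N or O)
#' @param mol an `mc_mol`.
#' @return integer.
#' @export
hbd_count <- function(mol) {
  sum(mol$atoms$nH[mol$atoms$element %in% c("N", "O")])
}

#' Hydrogen-bond acceptor count (N plus O atoms)
#' @param mol an `mc_mol`.
#' @return integer.
#' @export
hba_count <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O"))
}

#' Number of rotatable bonds
#'
#' Single, non-ring bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds. Ring sigma bonds -- including every macrocycle ring
#' bond -- are never rotatable under this definition, while substituent
#' rotatables are counted.
#'
#' @param mol an `mc_mol`.
#' @return integer.
#' @export
nrb_count <- function(mol, ring_rows = NULL) {
  if (nrow(mol$bonds) == 0L) return(0L)
  env <- .atom_env(mol)
  bmap <- bond_index_map(mol)
  if (is.null(ring_rows)) ring_rows <- ring_bond_rows(mol)
  in_ring <- logical(nrow(mol$bonds))
  in_ring[ring_rows] <- TRUE
  n <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 1L || b$aromatic || in_ring[k]) next
    if (env$degree[b$a1] < 2L || env$degree[b$a2] < 2L) next
    if (.is_amide_bond(mol, k, env$adj, bmap)) next
    n <- n + 1L
  }
  n
}

# sp3 carbon: non-aromatic C with only single bonds
sp3_carbon_flags <- function(mol, env = .atom_env(mol)) {
  mol$atoms$element == "C" & !mol$atoms$aromatic &
    env$n_double == 0L & env$n_triple == 0L & env$n_arom == 0L
}

#' Fraction of sp3-hybridized carbons
#' @param mol an `mc_mol`.
#' @param idx optional subset of atom indices over which to compute.
#' @return numeric in `[0, 1]`; `NaN` when there are no carbons in scope.
#' @export
fsp3 <- function(mol, idx = seq_len(n_atoms(mol))) {
  env <- .atom_env(mol)
  isC <- mol$atoms$element[idx] == "C"
  if (!any(isC)) return(NaN)
  mean(sp3_carbon_flags(mol, env)[idx][isC])
}

# Morgan-style extended-connectivity ranks used for stereocenter detection
.morgan_ranks <- function(mol) {
  at <- mol$atoms
  adj <- mol_adjacency(mol)
  inv <- as.integer(factor(paste(at$element, at$aromatic, at$charge, at$nH,
                                 vapply(adj, length, 1L))))
  for (iter in seq_len(n_atoms(mol) + 2L)) {
    nxt <- vapply(seq_len(n_atoms(mol)), function(i)
      paste(inv[i], paste(sort(inv[adj[[i]]]), collapse = ","), sep = "|"), "")
    new_inv <- as.integer(factor(nxt))
    if (length(unique(new_inv)) == length(unique(inv))) break
    inv <- new_inv
  }
  inv
}

#' Count chiral centers
#'
#' Assigned stereocenters (SMILES `@`/`@@`) plus unassigned potential
#' stereocenters: sp3 carbons with at most one implicit hydrogen whose
#' heavy neighbors all receive distinct Morgan extended-connectivity ranks
#' (a first-order CIP surrogate; symmetric ring environments are resolved
#' only as far as global rank refinement distinguishes them).
#'
#' @param mol an `mc_mol`.
#' @return integer.
#' @export
chiral_center_count <- function(mol) {
  env <- .atom_env(mol)
  sp3 <- sp3_carbon_flags(mol, env)
  ranks <- .morgan_ranks(mol)
  n <- 0L
  for (i in seq_len(n_atoms(mol))) {
    if (mol$atoms$chiral[i] != "") { n <- n + 1L; next }
    if (!sp3[i]) next
    h <- mol$atoms$nH[i]
    nbrs <- env$adj[[i]]
    if (h + length(nbrs) != 4L || h > 1L) next
    r <- ranks[nbrs]
    if (length(unique(r)) == length(r)) n <- n + 1L
  }
  n
}

# total ring count (cyclomatic number per component = SSSR size)
ring_count <- function(mol) {
  g <- mol_to_igraph(mol)
  comp <- igraph::components(g)
  nrow(mol$bonds) - n_atoms(mol) + comp$no
}

# aromatic ring count from the minimum cycle basis
aromatic_ring_count <- function(mol) {
  rs <- ring_systems(mol)
  n <- 0L
  for (sys in rs) {
    basis <- min_cycle_basis(mol, sys)
    for (cy in basis)
      if (all(mol$atoms$aromatic[cy])) n <- n + 1L
  }
  n
}
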