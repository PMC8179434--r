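# Independent oracles and fixture builders used across the suite.

# compare a decomposition against generator ground truth; returns "" when
# they agree, otherwise a short reason code
compare_decomposition <- function(mol, truth) {
  d <- decompose(mol)
  if (!setequal(d$ring_atoms, truth$ring_atoms)) return("ring")
  if (!setequal(d$peripheral$atom, truth$peripheral_atoms$atom))
    return("peripheral")
  gsets <- lapply(d$substituents, function(s) sort(s$atoms))
  tsets <- lapply(truth$substituent_groups, function(s) sort(s$atoms))
  if (length(gsets) != length(tsets)) return("substituent-count")
  if (!all(vapply(tsets, function(t)
    any(vapply(gsets, identical, TRUE, t)), TRUE)))
    return("substituent-atoms")
  g <- compute_gaps(d)
  if (!isTRUE(all.equal(sort(as.numeric(g$gaps)),
                        sort(as.numeric(truth$gaps))))) return("gaps")
  if (abs(restricted_fraction(d, mol) - truth$restricted_fraction) > 1e-12)
    return("restricted")
  ""
}

# closed-form volume of an axis-aligned d-ellipsoid
oracle_ellipsoid_volume <- function(semi_axes) {
  d <- length(semi_axes)
  pi^(d / 2) / gamma(d / 2 + 1) * prod(semi_axes)
}

# brute-force normalized centroid distance
oracle_distance <- function(a, b, a_pc1, dims) {
  mu_a <- colMeans(a[, seq_len(dims), drop = FALSE])
  mu_b <- colMeans(b[, seq_len(dims), drop = FALSE])
  sqrt(sum((mu_a - mu_b)^2)) / a_pc1
}

# brute-force importance: population variance times summed squared loadings
oracle_importance <- function(scaled, coef, n_pcs) {
  n <- nrow(scaled)
  vapply(seq_len(ncol(scaled)), function(p) {
    v <- sum((scaled[, p] - mean(scaled[, p]))^2) / n
    v * sum(coef[p, seq_len(n_pcs)]^2)
  }, 0)
}

# exhaustive k-medoids optimum over all medoid subsets (small n only)
oracle_kmedoids_cost <- function(x, k) {
  d <- as.matrix(stats::dist(scale(x)))
  combs <- utils::combn(nrow(x), k)
  min(apply(combs, 2L, function(meds)
    sum(apply(d[, meds, drop = FALSE], 1L, min))))
}

# small deterministic molecule set for parser round trips
roundtrip_smiles <- c(
  "C1CCCCCCCCCCC1",
  "CC(=O)NC1CCCCCCCCCC1O",
  "O=C1CCCCCCCCCC(=O)N1",
  "C1CC2(CCCCC2)CCCCCCCCC1",
  "c1ccc2ccccc2c1",
  "CC(C)[C@H](N)C(=O)O",
  "[O-]C(=O)CCC[N+](C)(C)C",
  "O=C1CNC(=O)CNC(=O)CNC(=O)CNC(=O)CNC(=O)CN1",
  "C1CCCCCCCCCc2ccccc2C1",
  "FC1CCCC(Cl)CCCCC(Br)CC1")
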