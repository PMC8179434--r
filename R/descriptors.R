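# Descriptor registry ----------------------------------------------------
#
# 90 molecular descriptors (MolDs) computed from the 2-D structure only:
# 32 classic druglikeness descriptors, 12 descriptors embodying earlier
# macrocycle design guidelines, and 46 macrocycle-specific descriptors
# built on the ring/peripheral/substituent decomposition. Identifiers for
# the descriptors characterized individually downstream (1, 6, 8, 16, 18,
# 22, 35, 46, 49, 64, 72-79, 82, 85, 89) are fixed; the remaining numbers
# are assigned in thematic blocks.

# shared per-molecule computation context
descriptor_context <- function(mol, decomp) {
  env <- .atom_env(mol)
  gaps <- compute_gaps(decomp)
  ring <- decomp$ring_atoms
  peri <- decomp$peripheral$atom
  subst_atoms <- unlist(lapply(decomp$substituents, `[[`, "atoms"))
  if (is.null(subst_atoms)) subst_atoms <- integer(0)
  list(mol = mol, decomp = decomp, env = env, gaps = gaps,
       ring = ring, peri = peri, subst = subst_atoms,
       el = mol$atoms$element,
       sp3 = sp3_carbon_flags(mol, env),
       bmap = bond_index_map(mol),
       ring_rows = ring_bond_rows(mol))
}

# ratio with the zero-denominator convention: 0 + exception flag
.ratio0 <- function(num, den) {
  if (den == 0) structure(0, exception = "zero denominator") else num / den
}

.count_el <- function(ctx, idx, el) sum(ctx$el[idx] %in% el)

.subst_sizes <- function(ctx)
  vapply(ctx$decomp$substituents, function(s) length(s$atoms), 1L)

.pop_sd <- function(x) if (length(x) == 0L) 0 else sqrt(mean((x - mean(x))^2))

# decorated ring atoms: bearing >= 1 peripheral group or substituent
.decorated_ring_atoms <- function(ctx) {
  att_s <- unlist(lapply(ctx$decomp$substituents, `[[`, "attachment_ring_atoms"))
  unique(c(ctx$decomp$peripheral$ring_atom, att_s))
}

# the registry: one entry per MolD
.registry_rows <- function() {
  r <- function(id, name, origin, category, kind = "discrete")
    data.frame(mold_id = id, name = name, origin = origin,
               category = category, scaling_kind = kind,
               stringsAsFactors = FALSE)
  rbind(
    # -- classic (32) --
    r(1,  "MW",                "classic", "classic", "continuous"),
    r(2,  "HeavyAtoms",        "classic", "classic"),
    r(3,  "HBD",               "classic", "classic"),
    r(4,  "HBA",               "classic", "classic"),
    r(5,  "NRB",               "classic", "classic"),
    r(6,  "CLogP",             "classic", "classic", "continuous"),
    r(7,  "RingCount",         "classic", "classic"),
    r(8,  "tPSA",              "classic", "classic", "continuous"),
    r(9,  "Fsp3",              "classic", "classic"),
    r(10, "AromaticRings",     "classic", "classic"),
    r(11, "ChiralCenters",     "classic", "classic"),
    r(12, "Heteroatoms",       "classic", "classic"),
    r(13, "NCount",            "classic", "classic"),
    r(14, "OCount",            "classic", "classic"),
    r(15, "SCount",            "classic", "classic"),
    r(17, "HalogenCount",      "classic", "classic"),
    r(19, "AmideBonds",        "classic", "classic"),
    r(20, "Sp3CarbonCount",    "classic", "classic"),
    r(21, "Sp2CarbonCount",    "classic", "classic"),
    r(23, "AromaticAtoms",     "classic", "classic"),
    r(24, "AbsFormalCharge",   "classic", "classic"),
    r(25, "MeanAtomicMass",    "classic", "classic"),
    r(26, "HBDplusHBA",        "classic", "classic"),
    r(27, "DoubleBonds",       "classic", "classic"),
    r(28, "TripleBonds",       "classic", "classic"),
    r(29, "RingAtomCount",     "classic", "classic"),
    r(30, "RingBondCount",     "classic", "classic"),
    r(31, "tPSAperMW",         "classic", "classic"),
    r(32, "HeteroatomFraction","classic", "classic"),
    r(33, "BondCount",         "classic", "classic"),
    r(34, "BranchPointCount",  "classic", "classic"),
    r(36, "TerminalAtomCount", "classic", "classic"),
    # -- prior design-guideline descriptors (12) --
    r(16, "PeriphNp1_over_PeriphOp1", "guideline", "peripheral"),
    r(18, "ChiralCenters_over_HA",    "guideline", "normalized"),
    r(37, "RingHA",            "guideline", "size-composition"),
    r(38, "PeriphHA",          "guideline", "peripheral"),
    r(39, "SubstHA",           "guideline", "substituent"),
    r(40, "RingHAFraction",    "guideline", "normalized"),
    r(41, "PeriphHAFraction",  "guideline", "normalized"),
    r(42, "SubstHAFraction",   "guideline", "normalized"),
    r(43, "PeriphMethyl",      "guideline", "peripheral"),
    r(44, "PeriphCarbonylO",   "guideline", "peripheral"),
    r(45, "PeriphHydroxylO",   "guideline", "peripheral"),
    r(47, "SubstituentCount",  "guideline", "substituent"),
    # -- macrocycle-specific novel descriptors (46) --
    r(22, "RingHet_over_N",    "novel", "size-composition"),
    r(35, "SpiroRings",        "novel", "substituent"),
    r(46, "PeriphO_over_PeriphHA", "novel", "peripheral"),
    r(48, "PeriphHA_over_N",   "novel", "peripheral"),
    r(49, "PeriphS_over_PeriphHA", "novel", "peripheral"),
    r(50, "PeriphPolarFraction", "novel", "peripheral"),
    r(51, "RingC",             "novel", "size-composition"),
    r(52, "RingN",             "novel", "size-composition"),
    r(53, "RingO",             "novel", "size-composition"),
    r(54, "RingS",             "novel", "size-composition"),
    r(55, "RingHet",           "novel", "size-composition"),
    r(56, "PeriphC",           "novel", "peripheral"),
    r(57, "PeriphN",           "novel", "peripheral"),
    r(58, "PeriphO",           "novel", "peripheral"),
    r(59, "PeriphS",           "novel", "peripheral"),
    r(60, "PeriphHalogen",     "novel", "peripheral"),
    r(61, "SubstC",            "novel", "substituent"),
    r(62, "SubstN",            "novel", "substituent"),
    r(63, "SubstO",            "novel", "substituent"),
    r(64, "SubstFsp3",         "novel", "substituent"),
    r(65, "SubstHet",          "novel", "substituent"),
    r(66, "SubstO_over_SubstHA", "novel", "substituent"),
    r(67, "MaxSubstSize",      "novel", "substituent"),
    r(68, "MinSubstSize",      "novel", "substituent"),
    r(69, "MeanSubstSize",     "novel", "substituent"),
    r(70, "StdevSubstSize",    "novel", "substituent"),
    r(71, "MaxSubstSize_over_N", "novel", "normalized"),
    r(72, "MaxGapSize",        "novel", "gap"),
    r(73, "MinGapSize",        "novel", "gap"),
    r(74, "MeanGapSize",       "novel", "gap"),
    r(75, "StdevGapSize",      "novel", "gap"),
    r(76, "MaxGapSize_over_N", "novel", "normalized"),
    r(77, "MinGapSize_over_N", "novel", "normalized"),
    r(78, "MeanGapSize_over_N","novel", "normalized"),
    r(79, "StdevGapSize_over_N","novel", "normalized"),
    r(80, "AttachmentPoints",  "novel", "gap"),
    r(81, "AttachmentPoints_over_N", "novel", "normalized"),
    r(82, "RestrictedFraction","novel", "rigidity"),
    r(83, "RingPiBonds",       "novel", "rigidity"),
    r(84, "RingFusionBonds",   "novel", "rigidity"),
    r(85, "RingComplexity",    "novel", "other"),
    r(86, "RingAmideBonds",    "novel", "rigidity"),
    r(87, "RingPiFraction",    "novel", "rigidity"),
    r(88, "FusedRingCount",    "novel", "substituent"),
    r(89, "PeptideCharacterIndex", "novel", "other"),
    r(90, "RingFsp3",          "novel", "size-composition")
  )
}

# compute functions keyed by mold id; each takes the descriptor context
.descriptor_funs <- function() {
  halog <- c("F", "Cl", "Br", "I")
  het <- c("N", "O", "S", "P", halog, "B")
  list(
    `1`  = function(c) molecular_weight(c$mol),
    `2`  = function(c) n_atoms(c$mol),
    `3`  = function(c) hbd_count(c$mol),
    `4`  = function(c) hba_count(c$mol),
    `5`  = function(c) nrb_count(c$mol, ring_rows = c$ring_rows),
    `6`  = function(c) clogp(c$mol),
    `7`  = function(c) ring_count(c$mol),
    `8`  = function(c) tpsa(c$mol),
    `9`  = function(c) { v <- fsp3(c$mol); if (is.nan(v)) .ratio0(0, 0) else v },
    `10` = function(c) aromatic_ring_count(c$mol),
    `11` = function(c) chiral_center_count(c$mol),
    `12` = function(c) sum(c$el %in% het),
    `13` = function(c) sum(c$el == "N"),
    `14` = function(c) sum(c$el == "O"),
    `15` = function(c) sum(c$el == "S"),
    `17` = function(c) sum(c$el %in% halog),
    `19` = function(c) {
      sum(vapply(seq_len(nrow(c$mol$bonds)), function(k)
        .is_amide_bond(c$mol, k, c$env$adj, c$bmap), TRUE))
    },
    `20` = function(c) sum(c$sp3),
    `21` = function(c) sum(c$el == "C" &
                             (c$mol$atoms$aromatic | c$env$n_double > 0L) &
                             c$env$n_triple == 0L & !c$sp3),
    `23` = function(c) sum(c$mol$atoms$aromatic),
    `24` = function(c) sum(abs(c$mol$atoms$charge)),
    `25` = function(c) molecular_weight(c$mol) / n_atoms(c$mol),
    `26` = function(c) hbd_count(c$mol) + hba_count(c$mol),
    `27` = function(c) sum(c$mol$bonds$order == 2L & !c$mol$bonds$aromatic),
    `28` = function(c) sum(c$mol$bonds$order == 3L),
    `29` = function(c) length(unique(c(c$mol$bonds$a1[c$ring_rows],
                                       c$mol$bonds$a2[c$ring_rows]))),
    `30` = function(c) length(c$ring_rows),
    `31` = function(c) tpsa(c$mol) / molecular_weight(c$mol),
    `32` = function(c) sum(c$el %in% het) / n_atoms(c$mol),
    `33` = function(c) nrow(c$mol$bonds),
    `34` = function(c) sum(c$env$degree >= 3L),
    `36` = function(c) sum(c$env$degree == 1L),
    # guideline block
    `16` = function(c) (.count_el(c, c$peri, "N") + 1) /
                       (.count_el(c, c$peri, "O") + 1),
    `18` = function(c) chiral_center_count(c$mol) / n_atoms(c$mol),
    `37` = function(c) c$decomp$N,
    `38` = function(c) length(c$peri),
    `39` = function(c) length(c$subst),
    `40` = function(c) c$decomp$N / n_atoms(c$mol),
    `41` = function(c) length(c$peri) / n_atoms(c$mol),
    `42` = function(c) length(c$subst) / n_atoms(c$mol),
    `43` = function(c) sum(c$decomp$peripheral$element == "C" &
                             c$decomp$peripheral$bond_order == 1L),
    `44` = function(c) sum(c$decomp$peripheral$element == "O" &
                             c$decomp$peripheral$bond_order == 2L),
    `45` = function(c) sum(c$decomp$peripheral$element == "O" &
                             c$decomp$peripheral$bond_order == 1L),
    `47` = function(c) length(c$decomp$substituents),
    # novel block
    `22` = function(c) .count_el(c, c$ring, het) / c$decomp$N,
    `35` = function(c) sum(vapply(c$decomp$substituents, `[[`, 1L,
                                  "n_spiro_rings")),
    `46` = function(c) .ratio0(.count_el(c, c$peri, "O"), length(c$peri)),
    `48` = function(c) length(c$peri) / c$decomp$N,
    `49` = function(c) .ratio0(.count_el(c, c$peri, "S"), length(c$peri)),
    `50` = function(c) .ratio0(.count_el(c, c$peri, c("N", "O")),
                               length(c$peri)),
    `51` = function(c) .count_el(c, c$ring, "C"),
    `52` = function(c) .count_el(c, c$ring, "N"),
    `53` = function(c) .count_el(c, c$ring, "O"),
    `54` = function(c) .count_el(c, c$ring, "S"),
    `55` = function(c) .count_el(c, c$ring, het),
    `56` = function(c) .count_el(c, c$peri, "C"),
    `57` = function(c) .count_el(c, c$peri, "N"),
    `58` = function(c) .count_el(c, c$peri, "O"),
    `59` = function(c) .count_el(c, c$peri, "S"),
    `60` = function(c) .count_el(c, c$peri, halog),
    `61` = function(c) .count_el(c, c$subst, "C"),
    `62` = function(c) .count_el(c, c$subst, "N"),
    `63` = function(c) .count_el(c, c$subst, "O"),
    `64` = function(c) {
      isC <- c$el[c$subst] == "C"
      if (!any(isC)) return(.ratio0(0, 0))
      mean(c$sp3[c$subst][isC])
    },
    `65` = function(c) .count_el(c, c$subst, het),
    `66` = function(c) .ratio0(.count_el(c, c$subst, "O"), length(c$subst)),
    `67` = function(c) { s <- .subst_sizes(c); if (length(s)) max(s) else 0L },
    `68` = function(c) { s <- .subst_sizes(c); if (length(s)) min(s) else 0L },
    `69` = function(c) { s <- .subst_sizes(c); if (length(s)) mean(s) else 0 },
    `70` = function(c) .pop_sd(.subst_sizes(c)),
    `71` = function(c) { s <- .subst_sizes(c)
                         (if (length(s)) max(s) else 0) / c$decomp$N },
    `72` = function(c) c$gaps$max_gap,
    `73` = function(c) c$gaps$min_gap,
    `74` = function(c) c$gaps$mean_gap,
    `75` = function(c) c$gaps$stdev_gap,
    `76` = function(c) c$gaps$max_gap_over_N,
    `77` = function(c) c$gaps$min_gap_over_N,
    `78` = function(c) c$gaps$mean_gap_over_N,
    `79` = function(c) c$gaps$stdev_gap_over_N,
    `80` = function(c) length(c$gaps$attachment_points),
    `81` = function(c) length(c$gaps$attachment_points) / c$decomp$N,
    `82` = function(c) restricted_fraction(c$decomp, c$mol),
    `83` = function(c) ring_pi_bonds(c$decomp, c$mol),
    `84` = function(c) ring_fusion_bonds(c$decomp, c$mol),
    `85` = function(c) length(.decorated_ring_atoms(c)) / c$decomp$N,
    `86` = function(c) ring_amide_bonds(c$decomp, c$mol),
    `87` = function(c) ring_pi_bonds(c$decomp, c$mol) / c$decomp$N,
    `88` = function(c) sum(vapply(c$decomp$substituents, `[[`, 1L,
                                  "n_fused_blocks")),
    `89` = function(c) min(1, 3 * ring_amide_bonds(c$decomp, c$mol) /
                                c$decomp$N),
    `90` = function(c) {
      ringC <- c$ring[c$el[c$ring] == "C"]
      if (length(ringC) == 0L) return(.ratio0(0, 0))
      mean(c$sp3[ringC])
    }
  )
}

#' Descriptor registry manifest
#'
#' @return data.frame of the 90 registered descriptors: `mold_id`, `name`,
#'   `origin` (`classic` / `guideline` / `novel`), `mc_specific` (logical,
#'   `TRUE` for the novel macrocycle-specific subset), thematic `category`
#'   and `scaling_kind` (`continuous` for MW, CLogP and tPSA only).
#' @export
registry_manifest <- function() {
  m <- .registry_rows()
  m <- m[order(m$mold_id), ]
  rownames(m) <- NULL
  m$mc_specific <- m$origin == "novel"
  m[, c("mold_id", "name", "origin", "mc_specific", "category",
        "scaling_kind")]
}

#' Compute the descriptor vector of one compound
#'
#' Evaluates every registered descriptor. Individual descriptor failures
#' (for example ratio descriptors with empty denominators) are recorded as
#' exceptions with the zero-denominator convention (value 0) and are never
#' fatal.
#'
#' @param mol an `mc_mol`.
#' @param decomp its `mc_decomposition` (computed via [decompose()] when
#'   omitted).
#' @param min_ring_size macrocycle threshold if `decomp` is computed here.
#' @return object of class `descriptor_vector`: `compound_id`, `values`
#'   (named numeric, names `mold_<id>`), `exceptions` (data.frame with
#'   `mold_id`, `reason`), `multifusion` flag.
#' @export
compute_descriptor_vector <- function(mol, decomp = NULL,
                                      min_ring_size = 11L) {
  if (is.null(decomp)) decomp <- decompose(mol, min_ring_size)
  ctx <- descriptor_context(mol, decomp)
  funs <- .descriptor_funs()
  man <- registry_manifest()
  vals <- numeric(nrow(man))
  names(vals) <- paste0("mold_", man$mold_id)
  exc <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$mold_id[i]
    res <- tryCatch(funs[[as.character(id)]](ctx), error = function(e) {
      structure(0, exception = conditionMessage(e))
    })
    if (!is.null(attr(res, "exception")))
      exc[[length(exc) + 1L]] <- data.frame(mold_id = id,
                                            reason = attr(res, "exception"),
                                            stringsAsFactors = FALSE)
    vals[i] <- as.numeric(res)
  }
  structure(list(
    compound_id = mol$id,
    values = vals,
    exceptions = if (length(exc)) do.call(rbind, exc)
                 else data.frame(mold_id = integer(), reason = character()),
    multifusion = decomp$multifusion), class = "descriptor_vector")
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("<descriptor_vector %s: %d values, %d exceptions%s>\n",
              if (is.na(x$compound_id)) "(unnamed)" else x$compound_id,
              length(x$values), nrow(x$exceptions),
              if (x$multifusion) ", multifusion" else ""))
  invisible(x)
}

#' Compute the descriptor matrix for a list of molecules
#'
#' @param mols list of `mc_mol` (e.g. from [read_structures()]).
#' @param min_ring_size macrocycle threshold.
#' @param multifusion_policy `"merge"` keeps multi-fusion compounds (their
#'   peri-fused system treated as one fused substituent); `"exception"`
#'   drops them from the matrix and reports them separately.
#' @return list with `matrix` (numeric, rows = compounds, columns =
#'   `mold_<id>`), `ids`, `exceptions` (per-compound exception records) and
#'   `excluded` (ids routed to the exceptions output).
#' @export
descriptor_matrix <- function(mols, min_ring_size = 11L,
                              multifusion_policy = c("merge", "exception")) {
  multifusion_policy <- match.arg(multifusion_policy)
  rows <- list(); ids <- character(0)
  excluded <- character(0); exceptions <- list()
  for (mol in mols) {
    dv <- tryCatch(compute_descriptor_vector(mol, min_ring_size = min_ring_size),
                   error = function(e) e)
    if (inherits(dv, "error")) {
      excluded <- c(excluded, mol$id)
      exceptions[[length(exceptions) + 1L]] <-
        data.frame(id = mol$id, mold_id = NA_integer_,
                   reason = conditionMessage(dv), stringsAsFactors = FALSE)
      next
    }
    if (dv$multifusion && multifusion_policy == "exception") {
      excluded <- c(excluded, mol$id)
      exceptions[[length(exceptions) + 1L]] <-
        data.frame(id = mol$id, mold_id = NA_integer_,
                   reason = "multifusion", stringsAsFactors = FALSE)
      next
    }
    if (nrow(dv$exceptions) > 0L)
      exceptions[[length(exceptions) + 1L]] <-
        cbind(id = mol$id, dv$exceptions)
    rows[[length(rows) + 1L]] <- dv$values
    ids <- c(ids, mol$id)
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, 90)
  rownames(mat) <- ids
  list(matrix = mat, ids = ids,
       exceptions = if (length(exceptions)) do.call(rbind, exceptions)
                    else data.frame(id = character(), mold_id = integer(),
                                    reason = character()),
       excluded = excluded)
}
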