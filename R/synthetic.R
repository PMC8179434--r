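# Synthetic macrocycle generator ----------------------------------------
#
# Builds macrocyclic molecules directly as molecular graphs from an
# explicit construction plan, so that the ring / peripheral / substituent
# classification, gap profile and rigidity features are known by
# construction (ground truth independent of the decomposition code). The
# structural vocabulary mirrors what the descriptor set analyses: ether
# and amide units in the ring, ring double bonds, peripheral methyl /
# hydroxyl / carbonyl-O / halogen groups, and chain, phenyl, ortho-fused
# or spiro substituents.

#' Build a macrocycle construction plan
#'
#' Positions are 1-based ring positions. Every consuming feature must land
#' on a plain ring carbon; the constructor validates the plan and reports
#' the violated constraint otherwise.
#'
#' @param ring_size number of ring atoms (>= 11).
#' @param ring_o positions of ring ether oxygens.
#' @param amide_at positions `i` of amide carbonyl carbons (the amide
#'   nitrogen sits at `i + 1`; the carbonyl O is a peripheral atom).
#' @param double_at positions `i` of ring C=C bonds (between `i`, `i+1`).
#' @param peripheral named list: position -> one of `"methyl"`,
#'   `"hydroxyl"`, `"carbonyl"`, `"F"`, `"Cl"`.
#' @param substituents list of lists with `position`, `kind` (`"chain"`,
#'   `"phenyl"`, `"fused"`, `"spiro"`), and for chains `size` (>= 2) and
#'   `n_sp2` (number of sp2 carbon pairs folded into the chain) and `n_o`
#'   (number of chain ether oxygens); for `"fused"`/`"spiro"` `size` is
#'   the fused/spiro ring size (5 or 6).
#' @return a `generator_spec` list.
#' @export
macrocycle_spec <- function(ring_size, ring_o = integer(0),
                            amide_at = integer(0), double_at = integer(0),
                            peripheral = list(), substituents = list()) {
  spec <- list(ring_size = as.integer(ring_size), ring_o = as.integer(ring_o),
               amide_at = as.integer(amide_at),
               double_at = as.integer(double_at),
               peripheral = peripheral, substituents = substituents)
  .validate_spec(spec)
  structure(spec, class = "generator_spec")
}

.wrap_pos <- function(p, N) ((p - 1L) %% N) + 1L

.validate_spec <- function(spec) {
  N <- spec$ring_size
  if (N < 11L) stop("ring_size must be >= 11")
  used <- character(N)  # "", "O", "amideC", "amideN", "dbl"
  claim <- function(pos, what, allow = "") {
    pos <- .wrap_pos(pos, N)
    if (!used[pos] %in% allow)
      stop(sprintf("position %d already used (%s) when placing %s",
                   pos, used[pos], what))
    used[pos] <<- what
  }
  for (p in spec$ring_o) claim(p, "O")
  for (p in spec$amide_at) { claim(p, "amideC"); claim(p + 1L, "amideN") }
  for (p in spec$double_at) { claim(p, "dbl"); claim(p + 1L, "dbl2") }
  deco <- integer(0)
  for (nm in names(spec$peripheral)) {
    p <- .wrap_pos(as.integer(nm), N)
    if (used[p] != "") stop(sprintf(
      "peripheral group at position %d conflicts with ring feature %s",
      p, used[p]))
    if (p %in% deco) stop("two decorations at ring position ", p)
    deco <- c(deco, p)
  }
  for (s in spec$substituents) {
    p <- .wrap_pos(s$position, N)
    if (used[p] != "") stop(sprintf(
      "substituent at position %d conflicts with ring feature %s", p, used[p]))
    if (p %in% deco) stop("two decorations at ring position ", p)
    deco <- c(deco, p)
    if (s$kind == "fused") {
      p2 <- .wrap_pos(s$position + 1L, N)
      if (used[p2] != "" || p2 %in% deco)
        stop("fused ring needs two free adjacent ring carbons at ",
             p, ",", p2)
      deco <- c(deco, p2)
    }
    if (s$kind == "chain" && s$size < 2L) stop("chain substituent size >= 2")
  }
  invisible(TRUE)
}

#' Generate one macrocycle from a construction plan
#'
#' @param spec a `generator_spec` from [macrocycle_spec()].
#' @param id compound identifier.
#' @return list with `mol` (`mc_mol`), `smiles`, and `truth`: the
#'   construction-time ground truth (`ring_atoms`, `peripheral_atoms`,
#'   `substituent_groups`, `attachment_positions`, `gaps`, plus expected
#'   descriptor entries `ring_het_over_N`, `restricted_fraction`,
#'   `peptide_index`, `spiro_rings`, `subst_fsp3`, `periph_O`, `periph_N`,
#'   `periph_HA`, gap statistics).
#' @export
generate_macrocycle <- function(spec, id = "syn1") {
  stopifnot(inherits(spec, "generator_spec"))
  N <- spec$ring_size
  el <- rep("C", N); arom <- rep(FALSE, N)
  bond_order <- rep(1L, N)      # bond i joins ring position i and i+1
  bond_arom <- rep(FALSE, N)
  el[.wrap_pos(spec$ring_o, N)] <- "O"
  for (p in spec$amide_at) el[.wrap_pos(p + 1L, N)] <- "N"
  for (p in spec$double_at) bond_order[.wrap_pos(p, N)] <- 2L

  atoms <- data.frame(element = el, aromatic = arom, charge = 0L,
                      hcount = NA_integer_, chiral = "",
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = seq_len(N), a2 = c(2:N, 1L),
                      order = bond_order, aromatic = bond_arom)
  add_atom <- function(element, aromatic = FALSE) {
    atoms[nrow(atoms) + 1L, ] <<- list(element, aromatic, 0L, NA_integer_, "")
    nrow(atoms)
  }
  add_bond <- function(a1, a2, order = 1L, aromatic = FALSE) {
    bonds[nrow(bonds) + 1L, ] <<- list(a1, a2, order, aromatic)
  }

  periph_atoms <- data.frame(atom = integer(), element = character(),
                             ring_atom = integer(), bond_order = integer(),
                             stringsAsFactors = FALSE)
  # amide carbonyl oxygens are peripheral
  for (p in spec$amide_at) {
    cpos <- .wrap_pos(p, N)
    o <- add_atom("O"); add_bond(cpos, o, 2L)
    periph_atoms[nrow(periph_atoms) + 1L, ] <- list(o, "O", cpos, 2L)
  }
  for (nm in names(spec$peripheral)) {
    p <- .wrap_pos(as.integer(nm), N)
    g <- spec$peripheral[[nm]]
    if (g == "methyl") {
      a <- add_atom("C"); add_bond(p, a, 1L)
      periph_atoms[nrow(periph_atoms) + 1L, ] <- list(a, "C", p, 1L)
    } else if (g == "hydroxyl") {
      a <- add_atom("O"); add_bond(p, a, 1L)
      periph_atoms[nrow(periph_atoms) + 1L, ] <- list(a, "O", p, 1L)
    } else if (g == "carbonyl") {
      a <- add_atom("O"); add_bond(p, a, 2L)
      periph_atoms[nrow(periph_atoms) + 1L, ] <- list(a, "O", p, 2L)
    } else if (g %in% c("F", "Cl")) {
      a <- add_atom(g); add_bond(p, a, 1L)
      periph_atoms[nrow(periph_atoms) + 1L, ] <- list(a, g, p, 1L)
    } else stop("unknown peripheral group: ", g)
  }

  subst_groups <- list()
  n_spiro <- 0L; n_fused <- 0L
  subst_sp3_c <- 0L; subst_c <- 0L
  attach_pos <- integer(0)
  for (s in spec$substituents) {
    p <- .wrap_pos(s$position, N)
    grp <- integer(0)
    if (s$kind == "chain") {
      n_sp2 <- if (is.null(s$n_sp2)) 0L else s$n_sp2
      n_o <- if (is.null(s$n_o)) 0L else s$n_o
      if (2L * n_sp2 + n_o > s$size)
        stop("chain substituent over-specified (size too small)")
      prev <- p
      placed_sp2 <- 0L; placed_o <- 0L
      for (t in seq_len(s$size)) {
        # lay out sp2 pairs first, then ethers, then sp3 carbons
        if (placed_sp2 < 2L * n_sp2) {
          a <- add_atom("C")
          ord <- if (placed_sp2 %% 2L == 1L) 2L else 1L
          add_bond(prev, a, ord)
          placed_sp2 <- placed_sp2 + 1L
          subst_c <- subst_c + 1L
        } else if (placed_o < n_o) {
          a <- add_atom("O"); add_bond(prev, a, 1L)
          placed_o <- placed_o + 1L
        } else {
          a <- add_atom("C"); add_bond(prev, a, 1L)
          subst_c <- subst_c + 1L; subst_sp3_c <- subst_sp3_c + 1L
        }
        grp <- c(grp, a); prev <- a
      }
      subst_groups[[length(subst_groups) + 1L]] <-
        list(atoms = grp, attachments = p, fused = FALSE, spiro = FALSE)
      attach_pos <- c(attach_pos, p)
    } else if (s$kind == "phenyl") {
      ph <- vapply(1:6, function(i) add_atom("C", aromatic = TRUE), 1L)
      add_bond(p, ph[1], 1L)
      for (i in 1:5) add_bond(ph[i], ph[i + 1], 1L, aromatic = TRUE)
      add_bond(ph[6], ph[1], 1L, aromatic = TRUE)
      subst_c <- subst_c + 6L
      subst_groups[[length(subst_groups) + 1L]] <-
        list(atoms = ph, attachments = p, fused = FALSE, spiro = FALSE)
      attach_pos <- c(attach_pos, p)
    } else if (s$kind == "fused") {
      # benzene ortho-fused across ring bond (p, p+1): the two shared ring
      # atoms become aromatic and the shared bond aromatic
      p2 <- .wrap_pos(s$position + 1L, N)
      atoms$aromatic[c(p, p2)] <- TRUE
      kb <- which((bonds$a1 == p & bonds$a2 == p2) |
                  (bonds$a1 == p2 & bonds$a2 == p))[1]
      bonds$aromatic[kb] <- TRUE
      ph <- vapply(1:4, function(i) add_atom("C", aromatic = TRUE), 1L)
      add_bond(p2, ph[1], 1L, aromatic = TRUE)
      for (i in 1:3) add_bond(ph[i], ph[i + 1], 1L, aromatic = TRUE)
      add_bond(ph[4], p, 1L, aromatic = TRUE)
      subst_c <- subst_c + 4L
      n_fused <- n_fused + 1L
      subst_groups[[length(subst_groups) + 1L]] <-
        list(atoms = ph, attachments = c(p, p2), fused = TRUE, spiro = FALSE)
      attach_pos <- c(attach_pos, p, p2)
    } else if (s$kind == "spiro") {
      m <- if (is.null(s$size)) 6L else s$size
      ring2 <- vapply(seq_len(m - 1L), function(i) add_atom("C"), 1L)
      add_bond(p, ring2[1], 1L)
      for (i in seq_len(m - 2L)) add_bond(ring2[i], ring2[i + 1], 1L)
      add_bond(ring2[m - 1L], p, 1L)
      subst_c <- subst_c + (m - 1L)
      subst_sp3_c <- subst_sp3_c + (m - 1L)
      n_spiro <- n_spiro + 1L
      subst_groups[[length(subst_groups) + 1L]] <-
        list(atoms = ring2, attachments = p, fused = FALSE, spiro = TRUE)
      attach_pos <- c(attach_pos, p)
    } else stop("unknown substituent kind: ", s$kind)
  }

  mol <- mc_mol(atoms, bonds, id = id, source = "generator")

  # ground-truth gap profile over substituent attachment positions
  att <- sort(unique(attach_pos))
  k <- length(att)
  gaps <- if (k == 0L) integer(0)
          else if (k == 1L) N - 1L
          else { nxt <- c(att[-1], att[1] + N); nxt - att - 1L }
  gap_stats <- if (k == 0L)
    list(max_gap = N, min_gap = N, mean_gap = N, stdev_gap = 0)
  else list(max_gap = max(gaps), min_gap = min(gaps), mean_gap = mean(gaps),
            stdev_gap = sqrt(mean((gaps - mean(gaps))^2)))

  n_amide <- length(spec$amide_at)
  restricted <- (n_amide + length(spec$double_at) + n_fused) / N
  ring_het <- sum(el %in% c("N", "O", "S"))
  truth <- list(
    N = N,
    ring_atoms = seq_len(N),
    peripheral_atoms = periph_atoms,
    substituent_groups = subst_groups,
    attachment_positions = att,
    gaps = gaps,
    ring_het = ring_het,
    ring_het_over_N = ring_het / N,
    restricted_fraction = restricted,
    peptide_index = min(1, 3 * n_amide / N),
    spiro_rings = n_spiro,
    fused_rings = n_fused,
    periph_O = sum(periph_atoms$element == "O"),
    periph_N = sum(periph_atoms$element == "N"),
    periph_HA = nrow(periph_atoms),
    subst_fsp3 = if (subst_c > 0L) subst_sp3_c / subst_c else NA_real_,
    max_gap = gap_stats$max_gap, min_gap = gap_stats$min_gap,
    mean_gap = gap_stats$mean_gap, stdev_gap = gap_stats$stdev_gap)
  list(mol = mol, smiles = write_smiles(mol), truth = truth)
}

# choose k attachment positions realizing a gap pattern with one tight
# pair (small min gap) and the rest spread; returns sorted positions
.attachment_positions <- function(N, k, min_gap) {
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  gaps <- rep((N - k - min_gap) %/% (k - 1L), k - 1L)
  gaps <- c(min_gap, gaps)
  gaps[length(gaps)] <- N - k - sum(gaps[-length(gaps)])
  pos <- 1L + cumsum(c(0L, gaps[-length(gaps)] + 1L))
  pos
}

# free ring-carbon positions given a partial plan
.free_positions <- function(N, spec_parts) {
  used <- logical(N)
  used[.wrap_pos(spec_parts$ring_o, N)] <- TRUE
  for (p in spec_parts$amide_at)
    used[.wrap_pos(c(p, p + 1L), N)] <- TRUE
  for (p in spec_parts$double_at)
    used[.wrap_pos(c(p, p + 1L), N)] <- TRUE
  for (p in spec_parts$deco) used[.wrap_pos(p, N)] <- TRUE
  which(!used)
}

#' Generate a synthetic macrocycle library
#'
#' Profiles state the world each library emulates:
#' * `"oral-like"` draws its 13 key-descriptor targets inside the packaged
#'   oral-macrocycle ranges: moderately heteroatom-containing rings,
#'   2-3 mostly-sp3 chain substituents placed with one tight gap, polar
#'   peripheral decoration dominated by oxygen, no spiro rings.
#' * `"sparse"` is the opposite: bare carbocyclic rings, a single sp2
#'   substituent, little or no peripheral decoration, occasional spiro
#'   rings and heavily unsaturated rings.
#' * `"kinase-like"` emulates small rigid aromatic-fused macrocycles.
#' * `"random"` mixes features uniformly.
#'
#' @param n number of compounds (>= 1).
#' @param profile `"oral-like"`, `"sparse"`, `"kinase-like"` or
#'   `"random"`.
#' @param seed integer seed; generation is deterministic given
#'   `(n, profile, seed)`.
#' @param prefix id prefix.
#' @return list with `mols` (list of `mc_mol`), `smiles` (character),
#'   `truth` (list of per-compound ground-truth lists) and `truth_table`
#'   (data.frame of the scalar ground-truth entries).
#' @export
generate_library <- function(n, profile = c("oral-like", "sparse",
                                            "kinase-like", "random"),
                             seed = 1L, prefix = NULL) {
  profile <- match.arg(profile)
  if (n < 1L) stop("n must be >= 1")
  if (is.null(prefix)) prefix <- sub("-like$", "", profile)
  set.seed(seed)
  mols <- list(); truths <- list(); smiles <- character(n)
  for (i in seq_len(n)) {
    spec <- switch(profile,
      "oral-like" = .sample_oral_spec(),
      "sparse" = .sample_sparse_spec(),
      "kinase-like" = .sample_kinase_spec(),
      "random" = switch(sample.int(3L, 1L), .sample_oral_spec(),
                        .sample_sparse_spec(), .sample_kinase_spec()))
    g <- generate_macrocycle(spec, id = sprintf("%s%03d", prefix, i))
    mols[[i]] <- g$mol; truths[[i]] <- g$truth; smiles[i] <- g$smiles
  }
  scalar_cols <- c("N", "ring_het", "ring_het_over_N", "restricted_fraction",
                   "peptide_index", "spiro_rings", "fused_rings", "periph_O",
                   "periph_N", "periph_HA", "subst_fsp3", "max_gap",
                   "min_gap", "mean_gap", "stdev_gap")
  tt <- do.call(rbind, lapply(seq_len(n), function(i) {
    row <- truths[[i]][scalar_cols]
    row$id <- mols[[i]]$id
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  list(mols = mols, smiles = smiles, truth = truths,
       truth_table = tt[, c("id", scalar_cols)])
}

# -- profile samplers (called under the library seed) --------------------

.sample_oral_spec <- function() {
  repeat {
    N <- sample(c(12L, 14L, 15L, 16L, 18L), 1L)
    k <- sample(2:3, 1L)
    min_gap <- sample(0:1, 1L)
    att <- .attachment_positions(N, k, min_gap)
    n_amide <- sample(0:min(1L, floor(0.13 * N)), 1L)
    n_o_ring <- sample(1:max(1L, round(N * stats::runif(1, 0.07, 0.2))), 1L)
    n_dbl <- sample(0:1, 1L)
    parts <- list(ring_o = integer(0), amide_at = integer(0),
                  double_at = integer(0), deco = att)
    ok <- TRUE
    place_pair <- function(parts) {
      free <- .free_positions(N, parts)
      pairs <- free[(free %% N) + 1L %in% free &
                      !((free %% N) + 1L %in% parts$deco)]
      pairs <- Filter(function(p) {
        p2 <- .wrap_pos(p + 1L, N)
        p2 %in% free
      }, free)
      if (length(pairs) == 0L) return(NULL)
      if (length(pairs) == 1L) pairs else sample(pairs, 1L)
    }
    for (j in seq_len(n_amide)) {
      p <- place_pair(parts)
      if (is.null(p)) { ok <- FALSE; break }
      parts$amide_at <- c(parts$amide_at, p)
    }
    if (ok) for (j in seq_len(n_dbl)) {
      p <- place_pair(parts)
      if (is.null(p)) { ok <- FALSE; break }
      parts$double_at <- c(parts$double_at, p)
    }
    if (ok) {
      free <- .free_positions(N, parts)
      if (length(free) < n_o_ring) ok <- FALSE
      else {
        parts$ring_o <- if (length(free) == 1L) free
                        else sample(free, n_o_ring)
      }
    }
    if (!ok) next
    # peripheral decoration: oxygens (hydroxyl/carbonyl) + methyls so that
    # PeriphO/PeriphHA lands around 0.35-0.6 and (PeriphN+1)/(PeriphO+1)
    # in 0.14-0.5 (no peripheral nitrogens, 1-6 oxygens)
    free <- .free_positions(N, parts)
    n_po <- sample(2:3, 1L)
    n_me <- sample(2:3, 1L)
    n_needed <- n_po + n_me
    if (length(free) < n_needed) next
    peri_pos <- if (length(free) == n_needed) free
                else sample(free, n_needed)
    # a carbonyl-O on a carbon adjacent to an amide nitrogen would create
    # an unplanned extra amide bond; those positions get hydroxyls instead
    amide_n <- .wrap_pos(parts$amide_at + 1L, N)
    no_carbonyl <- unique(.wrap_pos(c(amide_n - 1L, amide_n + 1L), N))
    peripheral <- list()
    for (t in seq_along(peri_pos)) {
      g <- if (t <= n_po) {
        if (peri_pos[t] %in% no_carbonyl) "hydroxyl"
        else sample(c("hydroxyl", "carbonyl"), 1L)
      } else "methyl"
      peripheral[[as.character(peri_pos[t])]] <- g
    }
    substituents <- lapply(seq_along(att), function(t)
      list(position = att[t], kind = "chain",
           size = sample(2:5, 1L), n_sp2 = 0L,
           n_o = sample(0:1, 1L)))
    spec <- tryCatch(macrocycle_spec(N, ring_o = parts$ring_o,
                                     amide_at = parts$amide_at,
                                     double_at = parts$double_at,
                                     peripheral = peripheral,
                                     substituents = substituents),
                     error = function(e) NULL)
    if (!is.null(spec)) return(spec)
  }
}

.sample_sparse_spec <- function() {
  repeat {
    N <- sample(c(14L, 15L, 16L, 18L), 1L)
    n_dbl <- sample(c(0L, round(0.5 * N / 2)), 1L)  # none, or heavily rigid
    with_spiro <- stats::runif(1) < 0.5
    subst <- list(list(position = 1L, kind = "phenyl"))
    if (with_spiro) subst <- c(subst, list(list(position = 1L + N %/% 2L,
                                                kind = "spiro", size = 6L)))
    parts <- list(ring_o = integer(0), amide_at = integer(0),
                  double_at = integer(0),
                  deco = vapply(subst, function(s) s$position, 1L))
    ok <- TRUE
    for (j in seq_len(n_dbl)) {
      free <- .free_positions(N, parts)
      cand <- Filter(function(p) .wrap_pos(p + 1L, N) %in% free, free)
      if (length(cand) == 0L) { ok <- FALSE; break }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      parts$double_at <- c(parts$double_at, p)
    }
    if (!ok) next
    peripheral <- list()
    if (stats::runif(1) < 0.5) {
      free <- .free_positions(N, parts)
      if (length(free) > 0L) {
        p <- if (length(free) == 1L) free else sample(free, 1L)
        peripheral[[as.character(p)]] <- "methyl"
      }
    }
    spec <- tryCatch(macrocycle_spec(N, double_at = parts$double_at,
                                     peripheral = peripheral,
                                     substituents = subst),
                     error = function(e) NULL)
    if (!is.null(spec)) return(spec)
  }
}

.sample_kinase_spec <- function() {
  repeat {
    N <- sample(c(13L, 14L, 15L), 1L)
    subst <- list(list(position = 1L, kind = "fused"))
    if (stats::runif(1) < 0.5)
      subst <- c(subst, list(list(position = 5L, kind = "phenyl")))
    parts <- list(ring_o = integer(0), amide_at = integer(0),
                  double_at = integer(0),
                  deco = c(1L, 2L, vapply(subst[-1],
                                          function(s) s$position, 1L)))
    free <- .free_positions(N, parts)
    n_amide <- sample(0:1, 1L)
    ok <- TRUE
    for (j in seq_len(n_amide)) {
      cand <- Filter(function(p) .wrap_pos(p + 1L, N) %in% free, free)
      if (length(cand) == 0L) { ok <- FALSE; break }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      parts$amide_at <- c(parts$amide_at, p)
      free <- .free_positions(N, parts)
    }
    if (!ok) next
    peripheral <- list()
    if (length(free) > 0L && stats::runif(1) < 0.7) {
      p <- if (length(free) == 1L) free else sample(free, 1L)
      peripheral[[as.character(p)]] <- "methyl"
    }
    spec <- tryCatch(macrocycle_spec(N, amide_at = parts$amide_at,
                                     peripheral = peripheral,
                                     substituents = subst),
                     error = function(e) NULL)
    if (!is.null(spec)) return(spec)
  }
}

#' Write a generated library to disk
#'
#' @param lib result of [generate_library()].
#' @param smi_path SMILES output path.
#' @param truth_path ground-truth CSV path.
#' @return invisible list of the two paths.
#' @export
write_library <- function(lib, smi_path, truth_path) {
  writeLines(paste(lib$smiles, vapply(lib$mols, `[[`, "", "id")), smi_path)
  utils::write.csv(lib$truth_table, truth_path, row.names = FALSE)
  invisible(list(smi = smi_path, truth = truth_path))
}
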