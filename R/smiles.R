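# SMILES reading and writing --------------------------------------------
#
# Purpose-built for the structural vocabulary this package analyses:
# organic-subset elements (B C N O P S F Cl Br I), aromatic lowercase atoms,
# bracket atoms with isotope/chirality/H-count/charge, branches, ring-bond
# closures (including %nn), and bond symbols - = # : / \. Stereo bond
# slashes are read as single bonds (2-D analysis only). Not a general
# SMILES engine: no wildcards, no reaction or disconnected-selection syntax
# beyond '.' component splitting handled by the caller.

.organic_two <- c("Cl", "Br")
.organic_one <- c("B", "C", "N", "O", "P", "S", "F", "I")
.aromatic_el <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string
#'
#' @param smiles character scalar.
#' @param id compound identifier carried on the result.
#' @param source provenance string.
#' @return an `mc_mol`. Multi-component strings (containing `.`) are
#'   returned whole; use [largest_component()] to strip salts.
#' @export
parse_smiles <- function(smiles, id = NA_character_, source = NA_character_) {
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, aromatic, charge, hcount, chiral)
  bonds <- list()   # each: c(a1, a2, order, aromatic)
  prev_stack <- integer(0)       # branch stack
  prev <- NA_integer_            # previous atom index
  pending_bond <- NULL           # bond symbol awaiting next atom
  ring_open <- list()            # closure number -> list(atom, bond)

  add_atom <- function(el, aromatic, charge = 0L, hcount = NA_integer_,
                       chiral = "") {
    atoms[[length(atoms) + 1L]] <<- list(element = el, aromatic = aromatic,
                                         charge = charge, hcount = hcount,
                                         chiral = chiral)
    idx <- length(atoms)
    if (!is.na(prev)) {
      b <- resolve_bond(pending_bond, prev, idx)
      bonds[[length(bonds) + 1L]] <<- b
    }
    pending_bond <<- NULL
    prev <<- idx
    idx
  }

  resolve_bond <- function(sym, i, j) {
    if (is.null(sym)) {
      arom <- atoms[[i]]$aromatic && atoms[[j]]$aromatic
      list(a1 = i, a2 = j, order = 1L, aromatic = arom)
    } else if (sym %in% c("-", "/", "\\")) {
      list(a1 = i, a2 = j, order = 1L, aromatic = FALSE)
    } else if (sym == "=") {
      list(a1 = i, a2 = j, order = 2L, aromatic = FALSE)
    } else if (sym == "#") {
      list(a1 = i, a2 = j, order = 3L, aromatic = FALSE)
    } else if (sym == ":") {
      list(a1 = i, a2 = j, order = 1L, aromatic = TRUE)
    } else stop("unknown bond symbol: ", sym)
  }

  close_ring <- function(num) {
    if (!is.null(ring_open[[as.character(num)]])) {
      op <- ring_open[[as.character(num)]]
      sym <- if (!is.null(pending_bond)) pending_bond else op$bond
      b <- resolve_bond(sym, op$atom, prev)
      bonds[[length(bonds) + 1L]] <<- b
      ring_open[[as.character(num)]] <<- NULL
      pending_bond <<- NULL
    } else {
      ring_open[[as.character(num)]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", s)
      spec <- substr(s, i + 1L, j - 1L)
      m <- regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\+\\+|--)?$",
        spec)[[1]]
      if (m[1] == -1) stop("unparsable bracket atom [", spec, "]")
      parts <- regmatches(spec, list(m))[[1]]
      sym <- parts[3]
      aromatic <- sym %in% .aromatic_el
      el <- if (aromatic) paste0(toupper(substr(sym, 1, 1)),
                                 substr(sym, 2, nchar(sym))) else sym
      chiral <- parts[4]
      hc <- parts[5]
      hcount <- if (hc == "") 0L
                else if (hc == "H") 1L
                else as.integer(substr(hc, 2, nchar(hc)))
      chs <- parts[6]
      charge <- if (chs == "") 0L
                else if (chs == "++") 2L
                else if (chs == "--") -2L
                else if (chs %in% c("+", "-")) as.integer(paste0(chs, "1"))
                else as.integer(chs)
      add_atom(el, aromatic, charge, hcount, chiral)
      i <- j + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch with no preceding atom")
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop("unbalanced ')' in SMILES")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "%") {
      num <- as.integer(substr(s, i + 1L, i + 2L))
      close_ring(num)
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
      i <- i + 1L
    } else {
      # organic subset atom, possibly two characters (Cl, Br)
      two <- substr(s, i, i + 1L)
      if (two %in% .organic_two) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else if (ch %in% .organic_one) {
        add_atom(ch, FALSE)
        i <- i + 1L
      } else if (ch %in% .aromatic_el) {
        el <- toupper(ch)
        add_atom(el, TRUE)
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMILES: ", s)
      }
    }
  }
  if (length(prev_stack) > 0L) stop("unbalanced '(' in SMILES")
  if (length(ring_open) > 0L && any(!vapply(ring_open, is.null, TRUE)))
    stop("unclosed ring bond in SMILES: ", s)

  at <- do.call(rbind, lapply(atoms, function(a)
    data.frame(element = a$element, aromatic = a$aromatic, charge = a$charge,
               hcount = a$hcount, chiral = a$chiral,
               stringsAsFactors = FALSE)))
  bd <- if (length(bonds)) do.call(rbind, lapply(bonds, as.data.frame)) else NULL
  mc_mol(at, bd, id = id, source = source)
}

#' Keep only the largest covalent component
#'
#' @param mol an `mc_mol`.
#' @return list with `mol` (largest component, re-indexed) and `stripped`
#'   (number of atoms removed).
#' @export
largest_component <- function(mol) {
  comps <- mol_components(mol)
  if (length(comps) <= 1L) return(list(mol = mol, stripped = 0L))
  keep <- comps[[1]]
  sub <- mol_subgraph(mol, keep)
  list(mol = sub$mol, stripped = n_atoms(mol) - length(keep))
}

#' Write a molecule as SMILES
#'
#' Depth-first traversal with ring-closure digits. Output is valid SMILES
#' for the structural subset the package handles, not a canonical form;
#' round-trips preserve the labelled graph up to isomorphism.
#' @param mol an `mc_mol`.
#' @return character scalar.
#' @export
write_smiles <- function(mol) {
  nA <- n_atoms(mol)
  if (nA == 0L) stop("empty molecule")
  adj <- mol_adjacency(mol)
  bmap <- bond_index_map(mol)
  visited <- rep(FALSE, nA)
  ring_bond_digit <- list()  # bond row -> digit
  next_digit <- 0L
  # identify ring-closure bonds via DFS spanning tree
  tree_edge <- rep(FALSE, nrow(mol$bonds))
  parent <- rep(NA_integer_, nA)
  order_seen <- integer(0)
  for (root in seq_len(nA)) {
    if (visited[root]) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[v]) next
      visited[v] <- TRUE
      order_seen <- c(order_seen, v)
      for (w in sort(adj[[v]], decreasing = TRUE)) {
        if (!visited[w]) {
          if (is.na(parent[w])) parent[w] <- v
          stack <- c(stack, w)
        }
      }
    }
  }
  # recompute tree by BFS parents (robust: mark edges on parent links)
  for (v in seq_len(nA)) {
    if (!is.na(parent[v])) {
      k <- bond_between(mol, v, parent[v], bmap)
      if (!is.na(k)) tree_edge[k] <- TRUE
    }
  }
  # note: iterative DFS above may set parent to a vertex later revisited;
  # rebuild tree properly with a recursive-style DFS below instead.
  tree_edge[] <- FALSE
  visited[] <- FALSE
  atom_closures <- vector("list", nA)
  emit <- character(0)

  bond_sym <- function(k) {
    b <- mol$bonds[k, ]
    if (b$aromatic) "" else if (b$order == 2L) "=" else if (b$order == 3L) "#" else ""
  }

  atom_token <- function(i) {
    a <- mol$atoms[i, ]
    el <- a$element
    sym <- if (a$aromatic) tolower(el) else el
    plain <- el %in% c(.organic_one, .organic_two) && a$charge == 0L &&
      a$chiral == "" &&
      (is.na(a$hcount) || a$hcount == mol$atoms$nH[i]) &&
      !(a$aromatic && el %in% c("N", "P") && mol$atoms$nH[i] > 0L)
    # plain organic-subset atoms only when implicit-H inference reproduces nH
    if (plain && is.na(a$hcount)) return(sym)
    if (plain && !is.na(a$hcount)) {
      # check the implicit valence would regenerate the same H count
      probe <- mol
      probe$atoms$hcount[i] <- NA_integer_
      if (implicit_hydrogens(probe)[i] == a$hcount) return(sym)
    }
    h <- mol$atoms$nH[i]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cstr <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
      if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
    paste0("[", sym, a$chiral, hstr, cstr, "]")
  }

  # assign ring closure digits: DFS, back edges get digits
  dfs_emit <- function(root) {
    # iterative DFS emitting SMILES with explicit stack of work items
    out <- character(0)
    # first pass: find back edges via DFS
    st <- list(list(v = root, p = NA_integer_))
    visited_local <- rep(FALSE, nA)
    back_edges <- integer(0)
    dstack <- integer(0)
    # recursive helper via explicit recursion (molecule sizes are small)
    rec <- function(v, p) {
      visited_local[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == p && !is.na(p)) next
        k <- bond_between(mol, v, w, bmap)
        if (!visited_local[w]) {
          tree_edge[k] <<- TRUE
          rec(w, v)
        } else if (!tree_edge[k] && !(k %in% back_edges)) {
          back_edges <<- c(back_edges, k)
        }
      }
    }
    rec(root, NA_integer_)
    # digits for back edges
    for (k in back_edges) {
      next_digit <<- next_digit + 1L
      d <- next_digit
      b <- mol$bonds[k, ]
      atom_closures[[b$a1]] <<- c(atom_closures[[b$a1]], stats::setNames(d, k))
      atom_closures[[b$a2]] <<- c(atom_closures[[b$a2]], stats::setNames(d, k))
    }
    digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
    # second pass: emit
    emit_rec <- function(v, p, bond_k) {
      tok <- if (!is.na(bond_k)) bond_sym(bond_k) else ""
      tok <- paste0(tok, atom_token(v))
      cls <- atom_closures[[v]]
      if (length(cls)) {
        for (nm in names(cls)) {
          k <- as.integer(nm)
          tok <- paste0(tok, bond_sym(k), digit_str(cls[[nm]]))
        }
      }
      kids <- Filter(function(w) {
        k <- bond_between(mol, v, w, bmap)
        tree_edge[k] && (is.na(p) || w != p)
      }, adj[[v]])
      # exclude the child we came from
      kids <- kids[vapply(kids, function(w) {
        k <- bond_between(mol, v, w, bmap)
        is.na(p) || w != p
      }, TRUE)]
      kid_strs <- character(0)
      for (w in kids) {
        k <- bond_between(mol, v, w, bmap)
        # only descend tree edges from v to unemitted children
        if (emitted[w]) next
        emitted[w] <<- TRUE
        kid_strs <- c(kid_strs, emit_rec(w, v, k))
      }
      if (length(kid_strs) == 0L) return(tok)
      if (length(kid_strs) == 1L) return(paste0(tok, kid_strs))
      paste0(tok, paste0("(", kid_strs[-length(kid_strs)], ")", collapse = ""),
             kid_strs[length(kid_strs)])
    }
    emitted <- rep(FALSE, nA)
    emitted[root] <- TRUE
    emit_rec(root, NA_integer_, NA_integer_)
  }

  comps <- mol_components(mol)
  pieces <- vapply(comps, function(cmp) dfs_emit(min(cmp)), "")
  paste(pieces, collapse = ".")
}
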