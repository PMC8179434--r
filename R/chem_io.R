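# Structure file input / output -----------------------------------------

#' Read molecular structures from a file
#'
#' SMILES files (`format = "smiles"`) hold one `SMILES<whitespace>ID` per
#' line; SDF files (V2000) take the identifier from the title line.
#' Unparsable entries are logged (via `message`) and skipped, never fatal.
#' Multi-component entries are stripped to their largest covalent
#' component. Duplicate identifiers are suffixed with an ordinal.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @return list of `mc_mol` records, in file order.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(errorCondition(paste0("input file not found: ", path),
                        class = "mcspace_input_error"))
  if (format == "auto") {
    format <- if (grepl("\\.sdf?$", path, ignore.case = TRUE)) "sdf"
              else "smiles"
  }
  mols <- if (format == "smiles") .read_smiles_file(path)
          else .read_sdf_file(path)
  if (length(mols) == 0L)
    stop(errorCondition(paste0("no parsable structures in ", path),
                        class = "mcspace_empty_set"))
  # de-duplicate ids with ordinal suffixes
  ids <- vapply(mols, `[[`, "", "id")
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  if (any(duplicated(ids))) {
    seen <- table(ids)
    counters <- stats::setNames(integer(length(seen)), names(seen))
    for (i in seq_along(mols)) {
      id <- ids[i]
      if (seen[[id]] > 1L) {
        counters[[id]] <- counters[[id]] + 1L
        newid <- paste0(id, "_", counters[[id]])
        message("duplicate id '", id, "' renamed to '", newid, "'")
        mols[[i]]$id <- newid
      }
    }
  }
  mols
}

.read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (nchar(ln) == 0L || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2L) parts[2] else paste0("mol", i)
    mol <- tryCatch(parse_smiles(smi, id = id,
                                 source = paste0(path, ":", i)),
                    error = function(e) e)
    if (inherits(mol, "error")) {
      message("skipping unparsable SMILES at ", path, ":", i, " (",
              conditionMessage(mol), ")")
      next
    }
    lc <- largest_component(mol)
    if (lc$stripped > 0L)
      message("kept largest component of ", id, " (stripped ",
              lc$stripped, " atoms)")
    mols[[length(mols) + 1L]] <- lc$mol
  }
  mols
}

# minimal V2000 molfile reader (counts line, atom block, bond block)
.read_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on $$$$ delimiters
  breaks <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(breaks, -1L) + 1L)
  if (length(breaks) == 0L) { starts <- 1L; breaks <- length(lines) + 1L }
  mols <- list()
  for (e in seq_along(starts)) {
    blk <- lines[starts[e]:(breaks[e] - 1L)]
    blk <- blk[seq_len(max(which(nzchar(trimws(blk)) | seq_along(blk) <= 4)))]
    mol <- tryCatch(.parse_molblock(blk, source = paste0(path, "#", e)),
                    error = function(err) err)
    if (inherits(mol, "error")) {
      message("skipping unparsable SDF record ", e, " in ", path, " (",
              conditionMessage(mol), ")")
      next
    }
    lc <- largest_component(mol)
    if (lc$stripped > 0L)
      message("kept largest component of ", mol$id, " (stripped ",
              lc$stripped, " atoms)")
    mols[[length(mols) + 1L]] <- lc$mol
  }
  mols
}

.parse_molblock <- function(blk, source = NA_character_) {
  if (length(blk) < 4L) stop("truncated molblock")
  id <- trimws(blk[1])
  counts <- blk[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || is.na(nbonds)) stop("bad counts line")
  if (grepl("V3000", counts)) stop("V3000 molfiles are not supported")
  at <- data.frame(element = character(natoms), aromatic = FALSE,
                   charge = 0L, hcount = NA_integer_, chiral = "",
                   stringsAsFactors = FALSE)
  for (i in seq_len(natoms)) {
    ln <- blk[4L + i]
    el <- trimws(substr(ln, 32, 34))
    chg_code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    at$element[i] <- el
    if (!is.na(chg_code) && chg_code != 0L)
      at$charge[i] <- 4L - chg_code   # molfile charge code convention
  }
  bd <- data.frame(a1 = integer(nbonds), a2 = integer(nbonds),
                   order = integer(nbonds), aromatic = FALSE)
  for (k in seq_len(nbonds)) {
    ln <- blk[4L + natoms + k]
    bd$a1[k] <- as.integer(substr(ln, 1, 3))
    bd$a2[k] <- as.integer(substr(ln, 4, 6))
    bt <- as.integer(substr(ln, 7, 9))
    if (bt == 4L) { bd$order[k] <- 1L; bd$aromatic[k] <- TRUE }
    else bd$order[k] <- bt
  }
  # aromatic flags on atoms involved in aromatic bonds
  at$aromatic[unique(c(bd$a1[bd$aromatic], bd$a2[bd$aromatic]))] <- TRUE
  # M  CHG lines override
  for (ln in blk[grepl("^M  CHG", blk)]) {
    toks <- strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]]
    nn <- as.integer(toks[1])
    for (t in seq_len(nn)) {
      idx <- as.integer(toks[2 * t])
      at$charge[idx] <- as.integer(toks[2 * t + 1])
    }
  }
  mc_mol(at, bd, id = if (nzchar(id)) id else NA_character_, source = source)
}

#' Write molecules to a SMILES file
#'
#' @param mols list of `mc_mol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(mols, path) {
  lines <- vapply(mols, function(m)
    paste(write_smiles(m), if (is.na(m$id)) "" else m$id), "")
  writeLines(trimws(lines), path)
  invisible(path)
}

#' Filter a compound list to macrocycles
#'
#' A record is kept iff its largest ring (under the package's ring
#' selection policy) has at least `min_ring_size` atoms.
#'
#' @param records list of `mc_mol`.
#' @param min_ring_size threshold (default 11; compounds whose largest
#'   ring is smaller are excluded).
#' @return a `filter_report`: list with `kept` (ids), `excluded`
#'   (data.frame id/reason), `min_ring_size`, and `records` (the kept
#'   `mc_mol` objects).
#' @export
filter_macrocycles <- function(records, min_ring_size = 11L) {
  stopifnot(min_ring_size >= 3L)
  kept <- list(); kept_ids <- character(0)
  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (m in records) {
    lr <- tryCatch(largest_ring(m), mcspace_complexity = function(e) e)
    if (inherits(lr, "error")) {
      excluded <- rbind(excluded, data.frame(
        id = m$id, reason = "complexity budget exceeded"))
      next
    }
    sz <- if (is.null(lr)) 0L else length(lr)
    if (sz >= min_ring_size) {
      kept[[length(kept) + 1L]] <- m
      kept_ids <- c(kept_ids, m$id)
    } else {
      excluded <- rbind(excluded, data.frame(
        id = m$id,
        reason = sprintf("largest ring %d < %d", sz, min_ring_size)))
    }
  }
  structure(list(kept = kept_ids, excluded = excluded,
                 min_ring_size = min_ring_size, records = kept),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %d kept, %d excluded (min ring size %d)>\n",
              length(x$kept), nrow(x$excluded), x$min_ring_size))
  invisible(x)
}

#' Write a filter report to CSV
#' @param report a `filter_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- rbind(
    data.frame(id = report$kept, status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(id = report$excluded$id, status = "excluded",
               reason = report$excluded$reason, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
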