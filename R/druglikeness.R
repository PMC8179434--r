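# Oral-macrocycle druglikeness filter -----------------------------------
#
# 13 key descriptors with value ranges encompassing 80% of the oral
# macrocycle drug set, the per-compound violation count, and the
# within/outside classification at the <= 4 violation threshold.

#' The packaged 13 key property ranges
#'
#' Reference ranges for the 13 descriptors identified as most important
#' for distinguishing macrocycle compound sets, with the value ranges
#' observed for oral macrocycle drugs and clinical candidates and each
#' property's distribution modality (A normal; B unimodal asymmetric,
#' low- or high-biased; C bi-/multimodal).
#'
#' @return a `property_range_set`: data.frame with `mold_id`, `name`,
#'   `lo`, `hi`, `modality`; provenance attribute `"packaged"`.
#' @export
oral_mc_ranges <- function() {
  df <- data.frame(
    mold_id = c(35, 46, 79, 8, 16, 64, 77, 6, 76, 89, 82, 18, 22),
    name = c("SpiroRings", "PeriphO_over_PeriphHA", "StdevGapSize_over_N",
             "tPSA", "PeriphNp1_over_PeriphOp1", "SubstFsp3",
             "MinGapSize_over_N", "CLogP", "MaxGapSize_over_N",
             "PeptideCharacterIndex", "RestrictedFraction",
             "ChiralCenters_over_HA", "RingHet_over_N"),
    lo = c(0, 0.30, 0.06, 50, 0.13, 0.22, 0, 2.40, 0.24, 0, 0, 0.02, 0.06),
    hi = c(0, 0.67, 0.26, 230, 0.50, 1.00, 0.13, 6.00, 0.64, 0.44, 0.42,
           0.33, 0.31),
    modality = c("n/a", "A", "A", "A", "B-low", "B-high", "B-low", "A",
                 "C", "B-low", "C", "A", "B-low"),
    stringsAsFactors = FALSE)
  structure(df, class = c("property_range_set", "data.frame"),
            provenance = "packaged")
}

#' Derive a property range from a sample, by distribution modality
#'
#' Modalities A (normal) and C (bi-/multimodal) use the middle 80% of the
#' data, i.e. the 10th-90th percentile span. Modality B (unimodal but
#' asymmetric) anchors the 80% span at the biased extreme: low-biased
#' ranges run from the minimum to the 80th percentile, high-biased from
#' the 20th percentile to the maximum. Linear-interpolation percentiles.
#'
#' @param values numeric sample (>= 5 observations).
#' @param modality `"A"`, `"C"`, `"B-low"` or `"B-high"`.
#' @param coverage fraction of the data encompassed, default 0.8.
#' @return numeric `c(lo, hi)`.
#' @export
derive_ranges <- function(values, modality = c("A", "C", "B-low", "B-high"),
                          coverage = 0.8) {
  modality <- match.arg(modality)
  if (length(values) == 0L) stop("empty sample")
  if (length(values) < 5L)
    warning("deriving a range from fewer than 5 observations")
  q <- function(p) stats::quantile(values, p, type = 7, names = FALSE)
  out <- switch(modality,
    "A" = , "C" = c(q((1 - coverage) / 2), q(1 - (1 - coverage) / 2)),
    "B-low" = c(min(values), q(coverage)),
    "B-high" = c(q(1 - coverage), max(values)))
  unname(out)
}

#' Count property-range violations for one compound
#'
#' A violation is a descriptor value strictly below `lo` or strictly above
#' `hi`; values on the bounds are compliant.
#'
#' @param vector a `descriptor_vector` (or named numeric with `mold_<id>`
#'   names).
#' @param ranges a `property_range_set`, default [oral_mc_ranges()].
#' @return integer violation count, with attribute `"violated"` naming the
#'   violated descriptors.
#' @export
count_violations <- function(vector, ranges = oral_mc_ranges()) {
  vals <- if (inherits(vector, "descriptor_vector")) vector$values else vector
  violated <- character(0)
  for (i in seq_len(nrow(ranges))) {
    key <- paste0("mold_", ranges$mold_id[i])
    if (!key %in% names(vals))
      stop("descriptor missing from vector: mold_", ranges$mold_id[i])
    v <- vals[[key]]
    if (v < ranges$lo[i] || v > ranges$hi[i])
      violated <- c(violated, ranges$name[i])
  }
  structure(length(violated), violated = violated)
}

#' Classify a violation count
#'
#' @param violations non-negative integer.
#' @param threshold default 4: compounds with at most `threshold`
#'   violations are `"within"` oral-macrocycle-druglike property space,
#'   the rest `"outside"`.
#' @return `"within"` or `"outside"`.
#' @export
classify_violations <- function(violations, threshold = 4L) {
  stopifnot(violations >= 0L)
  if (violations <= threshold) "within" else "outside"
}

#' Per-compound violation report for a descriptor matrix
#'
#' @param matrix descriptor matrix (columns `mold_<id>`).
#' @param ranges a `property_range_set`.
#' @param threshold classification threshold, default 4.
#' @return data.frame: `id`, `violations`, `class`, plus one logical
#'   column per ranged descriptor (`TRUE` = violated).
#' @export
violation_report <- function(matrix, ranges = oral_mc_ranges(),
                             threshold = 4L) {
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("cpd", seq_len(nrow(matrix)))
  out <- data.frame(id = ids, violations = 0L, class = "",
                    stringsAsFactors = FALSE)
  flags <- matrix(FALSE, nrow(matrix), nrow(ranges),
                  dimnames = list(NULL, ranges$name))
  for (r in seq_len(nrow(matrix))) {
    cv <- count_violations(matrix[r, ], ranges)
    out$violations[r] <- as.integer(cv)
    out$class[r] <- classify_violations(as.integer(cv), threshold)
    flags[r, attr(cv, "violated")] <- TRUE
  }
  cbind(out, as.data.frame(flags))
}

#' Export a property range set to JSON
#' @param ranges a `property_range_set`.
#' @param path output path; `NULL` returns the JSON string.
#' @export
ranges_to_json <- function(ranges, path = NULL) {
  js <- jsonlite::toJSON(list(provenance = attr(ranges, "provenance"),
                              entries = as.data.frame(ranges)),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
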