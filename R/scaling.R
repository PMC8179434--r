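# Descriptor scaling -----------------------------------------------------
#
# Two-regime 0-100 scaling. Discrete properties (everything except MW,
# tPSA, CLogP) are scaled from zero to the training maximum:
#     x_hat = 100 * x / p_max            (0 when p_max = 0)
# The three continuous properties are scaled over the +/- 2 sigma window
# around the training mean:
#     x_hat = 100 * (x - p_min) / (4 * sigma),   p_min = mu - 2 * sigma
# so a raw value at mu + 2 sigma maps to exactly 100 and values outside
# the window pass through as > 100 or < 0, unclipped.

#' Fit scaling parameters on a training descriptor matrix
#'
#' @param matrix numeric descriptor matrix, columns named `mold_<id>`.
#' @param manifest descriptor manifest (default [registry_manifest()]);
#'   its `scaling_kind` decides the regime per column. Columns absent from
#'   the manifest are treated as discrete.
#' @return a `scaling_params` object: data.frame with `column`, `kind`,
#'   `p_max`, `mu`, `sigma`, `p_min`, `constant`.
#' @export
fit_scaling <- function(matrix, manifest = registry_manifest()) {
  if (is.null(dim(matrix)) || nrow(matrix) < 2L)
    stop("scaling requires a matrix with at least 2 compounds")
  cols <- colnames(matrix)
  if (is.null(cols)) stop("descriptor matrix must have column names")
  kind_of <- stats::setNames(manifest$scaling_kind,
                             paste0("mold_", manifest$mold_id))
  params <- data.frame(column = cols, kind = "discrete",
                       p_max = NA_real_, mu = NA_real_, sigma = NA_real_,
                       p_min = NA_real_, constant = FALSE,
                       stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    x <- matrix[, i]
    k <- kind_of[cols[i]]
    if (!is.na(k) && k == "continuous") {
      mu <- mean(x); sg <- stats::sd(x)
      params$kind[i] <- "continuous"
      params$mu[i] <- mu; params$sigma[i] <- sg
      params$p_min[i] <- mu - 2 * sg
      params$constant[i] <- !is.finite(sg) || sg == 0
    } else {
      params$p_max[i] <- max(x)
      params$constant[i] <- max(x) == min(x)
    }
  }
  structure(params, class = c("scaling_params", "data.frame"))
}

#' Apply fitted scaling to a descriptor matrix
#'
#' Training parameters are reused verbatim; new compounds are projected
#' with the stored values, never refit.
#'
#' @param matrix numeric matrix with the same columns as the training fit.
#' @param params a `scaling_params` object.
#' @return scaled numeric matrix on the 0-100 frame (continuous columns
#'   may exceed it, by construction).
#' @export
apply_scaling <- function(matrix, params) {
  if (is.null(dim(matrix))) matrix <- matrix(matrix, nrow = 1,
                                             dimnames = list(NULL, names(matrix)))
  missing <- setdiff(colnames(matrix), params$column)
  if (length(missing) > 0L)
    stop("columns missing from scaling params: ",
         paste(missing, collapse = ", "))
  out <- matrix
  for (i in seq_len(ncol(matrix))) {
    p <- params[params$column == colnames(matrix)[i], ]
    x <- matrix[, i]
    out[, i] <- if (p$kind == "continuous") {
      if (p$sigma == 0) rep(0, length(x))
      else 100 * (x - p$p_min) / (4 * p$sigma)
    } else {
      if (p$p_max == 0) rep(0, length(x)) else 100 * x / p$p_max
    }
  }
  out
}

#' Invert scaling (non-constant columns)
#'
#' @param scaled scaled matrix.
#' @param params a `scaling_params` object.
#' @return matrix of raw values.
#' @export
invert_scaling <- function(scaled, params) {
  out <- scaled
  for (i in seq_len(ncol(scaled))) {
    p <- params[params$column == colnames(scaled)[i], ]
    y <- scaled[, i]
    out[, i] <- if (p$kind == "continuous") p$p_min + y * 4 * p$sigma / 100
                else y * p$p_max / 100
  }
  out
}

#' Serialize scaling parameters to JSON
#' @param params a `scaling_params` object.
#' @param path output path; when `NULL` the JSON string is returned.
#' @export
scaling_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(params), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read scaling parameters from JSON
#' @param path JSON file written by [scaling_to_json()].
#' @return a `scaling_params` object.
#' @export
scaling_from_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  structure(df, class = c("scaling_params", "data.frame"))
}
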