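#' Construct a feature-by-sample abundance table
#'
#' The central container of the package: a nonnegative numeric matrix with
#' features as rows and samples as columns, plus a `scale` flag recording
#' whether values are raw abundances/counts or per-sample proportions
#' (every column summing to 1).
#'
#' @param values Numeric matrix, features x samples, all entries finite and
#'   nonnegative. Row and column names, when present, become the feature and
#'   sample identifiers.
#' @param feature_ids,sample_ids Character vectors of unique identifiers;
#'   default to the dimnames of `values` or `f1..fn` / `s1..sn`.
#' @param scale Either `"raw"` or `"relative"`. With `"relative"` every
#'   sample column must sum to 1 (tolerance `1e-6`).
#' @return An object of class `abundance_table`.
#' @seealso [read_abundance_table()], [normalize_relative()]
#' @export
abundance_table <- function(values, feature_ids = NULL, sample_ids = NULL,
                            scale = c("raw", "relative")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("abundance table must have at least one feature and one sample")
  }
  feature_ids <- as.character(feature_ids %||% rownames(values) %||%
    paste0("f", seq_len(nrow(values))))
  sample_ids <- as.character(sample_ids %||% colnames(values) %||%
    paste0("s", seq_len(ncol(values))))
  if (length(feature_ids) != nrow(values)) {
    abort("feature_ids length does not match the number of rows")
  }
  if (length(sample_ids) != ncol(values)) {
    abort("sample_ids length does not match the number of columns")
  }
  if (anyDuplicated(feature_ids)) {
    abort(paste0("duplicate feature id: ",
                 feature_ids[duplicated(feature_ids)][1L]))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample id: ",
                 sample_ids[duplicated(sample_ids)][1L]))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("abundance values must be finite and non-missing")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(paste0("negative abundance at feature '", feature_ids[bad[1L]],
                 "', sample '", sample_ids[bad[2L]], "'"))
  }
  if (scale == "relative") {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-6)
    if (length(off)) {
      abort(paste0("scale = 'relative' but column '", sample_ids[off[1L]],
                   "' sums to ", format(cs[off[1L]])))
    }
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids,
         scale = scale),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", length(x$feature_ids), " features x ",
      length(x$sample_ids), " samples (scale = ", x$scale, ")\n", sep = "")
  cat("  total abundance: ", format(sum(x$values)), "; zero fraction: ",
      format(round(mean(x$values == 0), 3)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Tidy an abundance table into long form
#'
#' @param x An [abundance_table()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `abundance`.
#' @method tidy abundance_table
#' @export
tidy.abundance_table <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(x$feature_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$feature_ids)),
    abundance = as.vector(x$values)
  )
}

#' Convert each sample column to relative abundances
#'
#' Divides every sample column by its total so that an abundance of 0.1 means
#' the feature accounts for 10% of the sample's total observations. Spiking
#' is always applied on the raw scale first and normalization afterwards, so
#' a spike changes the proportions of unspiked features too, as it would in a
#' real resequenced community.
#'
#' @param table An [abundance_table()].
#' @return An `abundance_table` with `scale = "relative"`; already-relative
#'   input is returned unchanged (idempotent).
#' @export
normalize_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale == "relative") {
    return(table)
  }
  totals <- colSums(table$values)
  zero <- which(totals <= 0)
  if (length(zero)) {
    abort(paste0("sample '", table$sample_ids[zero[1L]],
                 "' has zero total abundance; proportions are undefined"))
  }
  abundance_table(sweep(table$values, 2L, totals, "/"),
                  table$feature_ids, table$sample_ids, scale = "relative")
}
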