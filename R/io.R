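#' Read a feature-by-sample abundance table from TSV
#'
#' The dialect is deliberately minimal: UTF-8, tab-separated, no quoting;
#' the header row holds sample identifiers with the literal `feature_id` in
#' the first column, and each following row is one feature. The scale is
#' inferred: relative iff every column sums to 1 within `1e-6`, raw
#' otherwise.
#'
#' @param path Path to a TSV file.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) abort("table needs a feature_id column and at least one sample")
  if (names(raw)[1L] != "feature_id") {
    abort("first column header must be 'feature_id'")
  }
  feature_ids <- raw[[1L]]
  sample_ids <- names(raw)[-1L]
  values <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L)
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) | col < 0)
    if (length(bad)) {
      abort(paste0("cell at feature '", feature_ids[bad[1L]], "', sample '",
                   sample_ids[j], "' is not a nonnegative number: '",
                   raw[[j + 1L]][bad[1L]], "'"))
    }
    values[, j] <- col
  }
  cs <- colSums(values)
  scale <- if (all(abs(cs - 1) <= 1e-6)) "relative" else "raw"
  abundance_table(values, feature_ids, sample_ids, scale = scale)
}

#' Write an abundance table to TSV
#'
#' Emits the dialect accepted by [read_abundance_table()] at full double
#' precision, so that a write/read round trip reproduces the table exactly.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", table$sample_ids), collapse = "\t"), con)
  body <- apply(table$values, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(paste(table$feature_ids, body, sep = "\t"), con)
  invisible(path)
}
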