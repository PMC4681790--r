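#' Pairwise Minkowski distances between samples
#'
#' `d_ij = (sum_f |x_fi - x_fj|^p)^(1/p)` over features, on relative
#' abundances. For `p < 1` the same formula is applied even though the
#' result is then not a metric (the triangle inequality fails); the
#' benchmark grid deliberately includes `p = 0.25` and `p = 0.5` because
#' they up-weight many small per-feature differences.
#'
#' @param table A relative-scale [abundance_table()] (raw input is
#'   normalized first).
#' @param p Minkowski exponent, > 0.
#' @return An object of class `distance_matrix`: `sample_ids` plus the
#'   symmetric, zero-diagonal matrix `d`.
#' @export
minkowski_distance_matrix <- function(table, p = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    abort("Minkowski exponent p must be positive")
  }
  rel <- normalize_relative(table)
  d <- as.matrix(stats::dist(t(rel$values), method = "minkowski", p = p))
  dimnames(d) <- list(rel$sample_ids, rel$sample_ids)
  structure(list(sample_ids = rel$sample_ids, d = d),
            class = "distance_matrix")
}

#' PERMANOVA-style pseudo-F from a distance matrix
#'
#' Gower-centers the squared distances (`A = -d^2/2`, double mean-centered
#' to `G`) and forms the ratio of between-group to residual trace under the
#' two-group indicator design:
#' `F = [tr(HGH)/(m-1)] / [tr((I-H)G(I-H))/(n-m)]` with `m = 2` groups.
#' With Euclidean distances on univariate data this reduces exactly to the
#' classical one-way ANOVA F.
#'
#' @param dist A `distance_matrix` from [minkowski_distance_matrix()] (or a
#'   plain symmetric matrix with dimnames).
#' @param labels Group labels over the distance matrix's samples.
#' @return The pseudo-F statistic (nonnegative real).
#' @export
mdmr_pseudo_f <- function(dist, labels) {
  if (inherits(dist, "distance_matrix")) {
    d <- dist$d
    ids <- dist$sample_ids
  } else {
    d <- as.matrix(dist)
    ids <- rownames(d) %||% paste0("s", seq_len(nrow(d)))
  }
  case <- case_indicator(labels, ids)
  n <- length(ids)
  m <- 2L
  G <- gower_center(d)
  x <- cbind(1, as.numeric(case))
  H <- x %*% solve(crossprod(x), t(x))
  # H idempotent => tr(HGH) = tr(GH), tr((I-H)G(I-H)) = tr(G) - tr(GH)
  tr_gh <- sum(G * t(H))
  tr_g <- sum(diag(G))
  resid <- tr_g - tr_gh
  if (resid <= .Machine$double.eps * max(1, abs(tr_g))) {
    abort("degenerate distance matrix: zero residual trace")
  }
  (tr_gh / (m - 1)) / (resid / (n - m))
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  a - outer(rm, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) + mean(a)
}
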