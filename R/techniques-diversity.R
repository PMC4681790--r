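#' Hill number of order q
#'
#' The effective number of species `^qD = (sum_i p_i^q)^(1/(1-q))` of a
#' relative-abundance profile, with the continuous limits
#' `^1D = exp(-sum p_i log p_i)` (exponential Shannon) and
#' `^InfD = 1/max(p_i)` (inverse Berger-Parker). Zeros are excluded from
#' the sums; `q = 0` counts the nonzero entries (richness). `^qD` is
#' non-increasing in q and at least 1 for any nonempty profile.
#'
#' @param profile Nonnegative numeric vector summing to 1 (tolerance 1e-9).
#' @param q Hill order, a nonnegative real or `Inf`.
#' @return The Hill diversity `^qD`.
#' @export
hill_number <- function(profile, q) {
  if (any(profile < 0)) abort("profile entries must be nonnegative")
  if (abs(sum(profile) - 1) > 1e-9) {
    abort("profile must sum to 1; normalize first")
  }
  p <- profile[profile > 0]
  if (!is.numeric(q) || length(q) != 1L || q < 0) {
    abort("q must be a nonnegative real or Inf")
  }
  if (is.infinite(q)) return(1 / max(p))
  if (q == 0) return(as.numeric(length(p)))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill diversity profile of every sample
#'
#' @param table An [abundance_table()] (normalized internally; every sample
#'   must have positive total).
#' @param orders Ascending Hill orders q.
#' @return A tibble with columns `sample_id`, `q`, `diversity`.
#' @export
hill_profile <- function(table, orders = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- normalize_relative(table)
  purrr::map_dfr(seq_along(rel$sample_ids), function(j) {
    tibble::tibble(
      sample_id = rel$sample_ids[j],
      q = orders,
      diversity = vapply(orders, function(qq) hill_number(rel$values[, j], qq), 0)
    )
  })
}

#' Diversity-family statistic
#'
#' Tests a whole family of Hill diversities at once: each sample's `^qD` is
#' computed for every order in `cfg$hill_orders`, a two-sample t-statistic
#' between groups is formed per order, and the family statistic is the
#' maximum absolute t over orders. Small orders weight richness (rare
#' features), large orders weight dominance, so the family is sensitive to
#' differences at either end without committing to one index in advance.
#' The multiplicity of the family is absorbed by the outer empirical-null
#' calibration, which sees the maximized statistic.
#'
#' @param table An [abundance_table()].
#' @param labels Group labels.
#' @param cfg A [technique_config()]; `hill_orders` supplies the family.
#' @return `max_q |t_q|`, a nonnegative real.
#' @export
diversity_family_statistic <- function(table, labels,
                                       cfg = technique_config("diversity_family")) {
  stopifnot(inherits(table, "abundance_table"))
  case <- case_indicator(labels, table$sample_ids)
  rel <- normalize_relative(table)
  div <- vapply(cfg$hill_orders, function(qq) {
    apply(rel$values, 2L, hill_number, q = qq)
  }, numeric(length(rel$sample_ids)))
  diversity_engine(div, case, cfg)
}

# div: samples x orders matrix of Hill numbers
diversity_engine <- function(div, case, cfg) {
  tvals <- apply(div, 2L, function(d) {
    res <- feature_t_statistic(d[case], d[!case], welch = cfg$welch)
    abs(res$t)
  })
  max(tvals)
}
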