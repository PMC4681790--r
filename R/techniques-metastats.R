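#' Welch two-sample t-statistic for one feature
#'
#' The per-feature building block of the Metastats-style global statistic.
#' When both groups have zero variance the declared convention is
#' `t = 0, p = 1` (no evidence either way); this also covers all-zero
#' features.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each) of
#'   relative abundances.
#' @param welch Use the Welch-Satterthwaite unequal-variance form (default);
#'   `FALSE` pools variances with `n1 + n2 - 2` degrees of freedom.
#' @return A list with elements `t` and `p` (two-sided).
#' @export
feature_t_statistic <- function(case_values, control_values, welch = TRUE) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    abort("each group needs at least two values")
  }
  n1 <- length(case_values); n2 <- length(control_values)
  m1 <- mean(case_values); m2 <- mean(control_values)
  v1 <- var(case_values); v2 <- var(control_values)
  if (v1 + v2 <= 0) {
    return(list(t = 0, p = 1))
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Row-wise Welch/pooled t on a matrix; vectorized because the global
# statistic runs inside resampling loops of up to 10^5 iterations.
row_t_pvalues <- function(m, case, welch = TRUE) {
  x <- m[, case, drop = FALSE]
  y <- m[, !case, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  degenerate <- (v1 + v2) <= 0
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(t))
  }
  p <- 2 * pt(-abs(t), df)
  p[degenerate] <- 1
  p
}

#' Fisher's exact p-value for a sparsely sampled feature
#'
#' Two-sided exact test on the 2x2 table of (feature counts vs all other
#' counts) x (case vs control), via hypergeometric enumeration: the p-value
#' sums the probabilities of all tables with the same margins whose
#' probability does not exceed the observed table's.
#'
#' @param case_total,control_total Feature counts summed over case and
#'   control samples.
#' @param case_other,control_other All-other-feature counts in each group.
#' @return Two-sided p-value.
#' @export
fisher_sparse_pvalue <- function(case_total, control_total,
                                 case_other, control_other) {
  counts <- c(case_total, control_total, case_other, control_other)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Fisher's exact test requires nonnegative integer counts")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg selection
#'
#' Step-up procedure: flags the features rejected at the given FDR level.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param level FDR level (default 0.05).
#' @return Logical vector of rejection flags; empty input gives an empty
#'   vector.
#' @export
fdr_select <- function(pvalues, level = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH") <= level
}

#' Modified-Metastats global statistic
#'
#' The multivariate extension of per-feature Metastats testing: each
#' feature gets a p-value (a two-sample t on relative abundances, or
#' Fisher's exact test on raw counts for features whose summed count is at
#' or below `sparse_total_threshold`), the pooled p-values pass through
#' Benjamini-Hochberg selection at `fdr_level`, and the global statistic is
#' the number of rejected features. Its null distribution is empirical
#' ([derive_null()]); the count itself carries no parametric calibration.
#'
#' Per-feature significance of the t branch is determined by resampling,
#' as in Metastats itself: the observed Welch t is compared against the
#' permutation distribution of the same statistic pooled across all
#' t-branch features (`cfg$inner_permutations` random relabelings), which
#' keeps the far tail of the p-values calibrated on heavy-tailed
#' abundances where the parametric t reference is conservative. Set
#' `cfg$t_null = "welch"` for the parametric reference instead.
#'
#' When the table carries only relative abundances (no counts), every
#' feature is t-tested: proportions cannot feed an exact count test.
#'
#' @param table An [abundance_table()]; raw tables are normalized
#'   internally for the t-branch while their rounded raw values feed the
#'   Fisher branch.
#' @param labels Group labels (see [group_labels()]).
#' @param cfg A [technique_config()].
#' @param seed Seed for the inner permutation draw.
#' @return Integer count of FDR-significant features.
#' @export
metastats_global_statistic <- function(table, labels,
                                       cfg = technique_config("metastats_global"),
                                       seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  case <- case_indicator(labels, table$sample_ids)
  if (sum(case) < 2L || sum(!case) < 2L) {
    abort("each group needs at least two samples")
  }
  raw <- if (table$scale == "raw") round(table$values) else NULL
  rel <- normalize_relative(table)$values
  metastats_engine(rel, raw, case, cfg, seed)
}

metastats_engine <- function(rel, raw, case, cfg, seed = 1L) {
  nf <- nrow(rel)
  sparse <- if (is.null(raw)) rep.int(FALSE, nf) else
    rowSums(raw) <= cfg$sparse_total_threshold
  p <- rep.int(1, nf)
  if (any(!sparse)) {
    dense <- rel[!sparse, , drop = FALSE]
    p[!sparse] <- if (cfg$t_null == "welch") {
      row_t_pvalues(dense, case, cfg$welch)
    } else {
      pooled_permutation_pvalues(dense, case, cfg$inner_permutations,
                                 cfg$welch, seed)
    }
  }
  if (any(sparse)) {
    case_sums <- rowSums(raw[, case, drop = FALSE])
    ctrl_sums <- rowSums(raw[, !case, drop = FALSE])
    tot_case <- sum(case_sums)
    tot_ctrl <- sum(ctrl_sums)
    for (i in which(sparse)) {
      p[i] <- fisher_sparse_pvalue(case_sums[i], ctrl_sums[i],
                                   tot_case - case_sums[i],
                                   tot_ctrl - ctrl_sums[i])
    }
  }
  sum(fdr_select(p, cfg$fdr_level))
}

# Row-wise |t| for B random relabelings at once, via two matrix products
# (group sums and sums of squares against a samples x B indicator matrix).
# Returns the nf x B matrix of absolute t values; degenerate rows give 0.
row_t_permutations <- function(m, n_case, B, welch, seed) {
  n <- ncol(m)
  ind <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      as.numeric(seq_len(n) %in% sample.int(n, n_case))
    }, numeric(n))
  })
  abs(row_t_matrix(m, ind, welch))
}

# t statistics for every column of indicator matrix `ind` (entries 1 for
# group 1, 0 for group 2, fixed group sizes).
row_t_matrix <- function(m, ind, welch) {
  n1 <- sum(ind[, 1L])
  n2 <- nrow(ind) - n1
  tot <- rowSums(m)
  tot2 <- rowSums(m^2)
  s1 <- m %*% ind
  q1 <- (m^2) %*% ind
  m1 <- s1 / n1
  m2 <- (tot - s1) / n2
  v1 <- pmax(0, (q1 - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, ((tot2 - q1) - n2 * m2^2) / (n2 - 1))
  se2 <- if (welch) {
    v1 / n1 + v2 / n2
  } else {
    (((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) * (1 / n1 + 1 / n2)
  }
  t <- (m1 - m2) / sqrt(se2)
  t[se2 <= 0] <- 0
  t
}

# Metastats-style pooled permutation p-values: each feature's observed |t|
# is referred to the permutation distribution of |t| pooled over all
# features, giving p-value resolution 1/(B * nf) — fine enough for the
# step-up FDR selection even at small B.
pooled_permutation_pvalues <- function(m, case, B, welch, seed) {
  obs <- abs(row_t_matrix(m, cbind(as.numeric(case)), welch))[, 1L]
  pool <- sort(row_t_permutations(m, sum(case), B, welch, seed))
  n_pool <- length(pool)
  (n_pool - findInterval(obs - 1e-12, pool)) / n_pool
}
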