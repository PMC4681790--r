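#' Compute a technique's global statistic
#'
#' Single entry point dispatching on `cfg$technique`. Raw tables are
#' normalized internally where a technique needs proportions; the
#' Metastats Fisher branch additionally sees the rounded raw counts when
#' the table scale is raw. All statistics share the orientation
#' "larger = stronger evidence of a group difference".
#'
#' @param table An [abundance_table()].
#' @param labels Group labels (see [group_labels()]).
#' @param cfg A [technique_config()].
#' @param seed Seed for any internal cross-validation fold assignment
#'   (penalized regression, PCR, PLSR); statistics are bit-identical across
#'   runs given the same seed.
#' @return A single finite numeric value.
#' @export
compute_statistic <- function(table, labels, cfg, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(cfg, "technique_config"))
  engine <- statistic_engine(table, cfg)
  case <- case_indicator(labels, table$sample_ids)
  engine(case, seed)
}

# Precompute everything split-independent (normalization, rounded counts,
# transposed predictor matrix, per-sample diversity profiles) and return a
# closure (case_indicator, seed) -> statistic. Null calibration evaluates
# this closure tens of thousands of times on one fixed table, so the
# factoring matters.
statistic_engine <- function(table, cfg) {
  rel <- normalize_relative(table)$values
  switch(cfg$technique,
    metastats_global = {
      raw <- if (table$scale == "raw") round(table$values) else NULL
      function(case, seed) metastats_engine(rel, raw, case, cfg, seed)
    },
    lasso = , ridge = , elastic_net = {
      x <- t(rel)
      function(case, seed) regularized_engine(x, case, cfg, seed)
    },
    mdmr = {
      d <- as.matrix(stats::dist(t(rel), method = "minkowski",
                                 p = cfg$minkowski_p))
      G <- gower_center(d)
      tr_g <- sum(diag(G))
      n <- ncol(rel)
      function(case, seed) {
        x <- cbind(1, as.numeric(case))
        H <- x %*% solve(crossprod(x), t(x))
        tr_gh <- sum(G * t(H))
        resid <- tr_g - tr_gh
        if (resid <= .Machine$double.eps * max(1, abs(tr_g))) {
          abort("degenerate distance matrix: zero residual trace")
        }
        tr_gh / (resid / (n - 2))
      }
    },
    pcr = {
      x <- t(rel)
      function(case, seed) {
        projection_cv_engine(x, case, cfg$n_components, cfg$cv_folds, seed, "pcr")
      }
    },
    plsr = {
      x <- t(rel)
      function(case, seed) {
        projection_cv_engine(x, case, cfg$n_components, cfg$cv_folds, seed, "plsr")
      }
    },
    diversity_family = {
      div <- vapply(cfg$hill_orders, function(qq) {
        apply(rel, 2L, hill_number, q = qq)
      }, numeric(ncol(rel)))
      function(case, seed) diversity_engine(div, case, cfg)
    }
  )
}
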