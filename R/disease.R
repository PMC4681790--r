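#' Specify a spike-in disease model
#'
#' A disease model names a category of features to perturb, the cumulative
#' baseline share of total abundance the perturbed set should account for,
#' and the fold multiplier applied to case samples. The four categories:
#'
#' * `rare` — features added in increasing order of average abundance;
#' * `medium` — features nearest (by absolute difference) to the grand mean
#'   of feature averages;
#' * `common` — features nearest to the average of the `reference_rank`-th
#'   most abundant feature;
#' * `correlated` — features in decreasing order of correlation between
#'   their per-sample abundances and the reference feature's (the reference
#'   itself excluded).
#'
#' In every category, features are added until their cumulative baseline
#' relative abundance first reaches `target_fraction`.
#'
#' @param category One of `"rare"`, `"medium"`, `"common"`, `"correlated"`.
#' @param target_fraction Cumulative baseline abundance share of the
#'   selected set, in (0, 1]; the benchmark study uses 0.01 and 0.10.
#' @param fold Multiplier (>= 1) applied to the selected features in case
#'   samples; `fold = 1` is the embedded null. May be a vector when used as
#'   a grid by [run_benchmark()].
#' @param reference_rank Abundance rank of the reference feature for the
#'   `common` and `correlated` categories (default 100).
#' @param cor_method Correlation coefficient for the `correlated` category,
#'   `"pearson"` (default) or `"spearman"`.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(category = c("rare", "medium", "common", "correlated"),
                          target_fraction = 0.1, fold = 1,
                          reference_rank = 100,
                          cor_method = c("pearson", "spearman")) {
  category <- match.arg(category)
  cor_method <- match.arg(cor_method)
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1) {
    abort("target_fraction must lie in (0, 1]")
  }
  if (!is.numeric(fold) || any(fold < 1)) {
    abort("fold must be >= 1 ('increased by k times' is multiplication by k)")
  }
  if (!is_count(reference_rank)) abort("reference_rank must be a positive integer")
  structure(
    list(category = category, target_fraction = target_fraction,
         fold = fold, reference_rank = as.integer(reference_rank),
         cor_method = cor_method),
    class = "disease_model"
  )
}

#' Select the feature set a disease model perturbs
#'
#' Applies the model's ordering rule to the baseline table and accumulates
#' features until their cumulative share of total average abundance first
#' reaches the target. Ties in the ordering break by feature index, so
#' selection is deterministic.
#'
#' @param table Baseline [abundance_table()] (unspiked).
#' @param model A [disease_model()].
#' @return An object of class `feature_set`: a list with `indices`,
#'   `feature_ids`, and `achieved_fraction` (the smallest attainable
#'   cumulative share at or above the target).
#' @export
select_feature_set <- function(table, model) {
  stopifnot(inherits(table, "abundance_table"), inherits(model, "disease_model"))
  avg <- rowMeans(table$values)
  total <- sum(avg)
  if (total <= 0) abort("table has zero total abundance")
  nf <- length(avg)
  if (model$category %in% c("common", "correlated") &&
      sum(avg > 0) < model$reference_rank) {
    abort("fewer positive-abundance features than reference_rank")
  }

  ord <- switch(model$category,
    rare = order(avg, seq_len(nf)),
    medium = order(abs(avg - mean(avg)), seq_len(nf)),
    common = {
      ref_avg <- sort(avg, decreasing = TRUE)[model$reference_rank]
      order(abs(avg - ref_avg), seq_len(nf))
    },
    correlated = {
      ref <- order(avg, seq_len(nf), decreasing = TRUE)[model$reference_rank]
      rel <- normalize_relative(table)$values
      cc <- suppressWarnings(
        as.vector(cor(t(rel), rel[ref, ], method = model$cor_method))
      )
      cc[is.na(cc)] <- -Inf
      cand <- setdiff(order(-cc, seq_len(nf)), ref)
      cand
    }
  )

  cum <- cumsum(avg[ord]) / total
  hit <- which(cum >= model$target_fraction - 1e-12)
  if (!length(hit)) {
    abort(paste0("target_fraction ", model$target_fraction,
                 " unreachable: selectable features cover only ",
                 format(max(cum)), " of total abundance"))
  }
  n_sel <- hit[1L]
  idx <- ord[seq_len(n_sel)]
  structure(
    list(indices = idx, feature_ids = table$feature_ids[idx],
         achieved_fraction = unname(cum[n_sel])),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", length(x$indices), " features, cumulative baseline fraction ",
      format(round(x$achieved_fraction, 4)), "\n", sep = "")
  invisible(x)
}

#' Multiply selected features in case samples
#'
#' The spike is applied on the raw scale and only afterwards are profiles
#' normalized, so the perturbation propagates into every proportion of a
#' case sample exactly as a genuine abundance increase would.
#'
#' @param table Raw-scale [abundance_table()].
#' @param features A [feature_set()][select_feature_set] (or integer vector
#'   of feature indices).
#' @param fold Multiplier >= 1; `fold = 1` returns the table unchanged.
#' @param case_samples Character vector of sample ids forming the case
#'   group; all other columns are untouched.
#' @return A raw-scale `abundance_table`.
#' @export
apply_spike <- function(table, features, fold, case_samples) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "raw") {
    abort("spikes are applied on the raw scale, before normalization")
  }
  if (!is.numeric(fold) || length(fold) != 1L || fold < 1) {
    abort("fold must be a single number >= 1")
  }
  if (length(case_samples) == 0L) abort("case sample set is empty")
  if (!all(case_samples %in% table$sample_ids)) {
    abort("case_samples contains unknown sample ids")
  }
  idx <- if (inherits(features, "feature_set")) features$indices else as.integer(features)
  values <- table$values
  values[idx, case_samples] <- values[idx, case_samples] * fold
  abundance_table(values, table$feature_ids, table$sample_ids, scale = "raw")
}
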