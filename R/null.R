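#' Derive a technique's empirical null distribution
#'
#' Since the theoretical null distributions of these global statistics are
#' unknown, the null is built by resampling: the unspiked table's samples
#' are split at random into one group of `group_size` versus the rest
#' (by default half/half, mirroring a 44-vs-44 design), the statistic is
#' computed for each split, and the alpha-level rejection threshold is the
#' value such that `round(alpha * N)` of the `N` null statistics are at or
#' above it. With heavily tied (e.g. integer-valued) statistics an exact
#' count may be unattainable; ties then break toward the larger,
#' conservative threshold.
#'
#' @param table The unspiked [abundance_table()] — the only data in which
#'   the null hypothesis is true by construction.
#' @param cfg A [technique_config()].
#' @param n_resamples Number of random splits N (>= `1/alpha`; the full
#'   study scale is 1e5, desk scale 2e3).
#' @param group_size Size of the sampled group; default half the samples.
#' @param alpha Target type-I error rate (default 0.05).
#' @param seed Root seed; each resample draws from its own child stream,
#'   so results are identical for any worker count or evaluation order.
#' @return An object of class `null_distribution`: sorted `statistics`,
#'   `threshold`, `alpha`, `n_resamples`, `technique_id`, `seed`.
#' @export
derive_null <- function(table, cfg, n_resamples = 2000, group_size = NULL,
                        alpha = 0.05, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(cfg, "technique_config"))
  n <- length(table$sample_ids)
  group_size <- as.integer(group_size %||% (n %/% 2L))
  if (2L * group_size > n) abort("2 * group_size exceeds the number of samples")
  if (group_size < 2L) abort("group_size must be at least 2")
  if (n_resamples < ceiling(1 / alpha)) {
    abort("n_resamples below 1/alpha: threshold undefined at this resolution")
  }
  engine <- statistic_engine(table, cfg)
  stats <- vapply(seq_len(n_resamples), function(i) {
    s <- child_seed(seed, "null_split", i)
    case <- withr::with_seed(s, {
      idx <- sample.int(n, group_size)
      seq_len(n) %in% idx
    })
    engine(case, child_seed(seed, "null_cv", i))
  }, numeric(1))
  new_null_distribution(cfg$id, stats, alpha, n_resamples, seed)
}

#' Assemble a null distribution from precomputed statistics
#'
#' Useful for reloading persisted null statistics or for constructing
#' reference distributions directly; [derive_null()] is the usual route.
#'
#' @param statistics Numeric vector of null statistic values.
#' @param alpha Type-I error level the threshold encodes (default 0.05).
#' @param technique_id Identifier recorded on the object.
#' @param seed Seed recorded for provenance (default `NA`).
#' @return A `null_distribution` object with its threshold fixed by the
#'   same rule as [derive_null()].
#' @export
null_distribution <- function(statistics, alpha = 0.05,
                              technique_id = "manual", seed = NA_integer_) {
  if (!is.numeric(statistics) || length(statistics) < ceiling(1 / alpha)) {
    abort("need at least 1/alpha statistic values")
  }
  new_null_distribution(technique_id, as.numeric(statistics), alpha,
                        length(statistics), seed)
}

new_null_distribution <- function(technique_id, stats, alpha, n_resamples, seed) {
  structure(
    list(technique_id = technique_id, statistics = sort(stats),
         alpha = alpha, threshold = choose_threshold(stats, alpha),
         n_resamples = as.integer(n_resamples), seed = seed),
    class = "null_distribution"
  )
}

# Threshold such that #(stats >= threshold) == round(alpha * N) where the
# statistic's granularity allows it; ties escalate to the next larger
# observed value (conservative: achieved level <= alpha).
choose_threshold <- function(stats, alpha) {
  n <- length(stats)
  k <- round(alpha * n)
  if (k < 1) abort("alpha * n_resamples below 1: no upper quantile to fix")
  s <- sort(stats, decreasing = TRUE)
  thr <- s[k]
  if (sum(stats >= thr) > k) {
    higher <- s[s > thr]
    thr <- if (length(higher)) min(higher) else thr + max(1e-8, abs(thr) * 1e-8)
  }
  thr
}

#' Empirical p-value against a null distribution
#'
#' `p = (number of null statistics strictly higher than observed) / N` —
#' the direct resampling definition, deliberately without the `(r+1)/(N+1)`
#' correction, so an observed value above every null statistic yields
#' exactly 0 and one below every null statistic yields exactly 1.
#'
#' @param null A `null_distribution` from [derive_null()].
#' @param observed Observed statistic value.
#' @return Empirical p-value in `[0, 1]`.
#' @export
empirical_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "null_distribution"))
  mean(null$statistics > observed)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$technique_id, ": N = ", x$n_resamples,
      ", alpha = ", x$alpha, ", threshold = ", format(x$threshold), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return A tibble with columns `technique_id` and `statistic` (sorted
#'   ascending).
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(technique_id = x$technique_id, statistic = x$statistics)
}

#' One-row summary of a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return A one-row tibble: technique, N, alpha, threshold, and the
#'   achieved level (fraction of null statistics at or above threshold).
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    technique_id = x$technique_id, n_resamples = x$n_resamples,
    alpha = x$alpha, threshold = x$threshold,
    achieved_level = mean(x$statistics >= x$threshold)
  )
}

#' Histogram of a null distribution with its rejection threshold
#'
#' @param object A `null_distribution`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, bins = 40, ...) {
  df <- tidy.null_distribution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(
      title = paste0("Empirical null: ", object$technique_id),
      subtitle = paste0("N = ", object$n_resamples, ", threshold = ",
                        signif(object$threshold, 4), " (alpha = ",
                        object$alpha, ")"),
      x = "null statistic", y = "count"
    )
}
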