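#' Configure a test statistic
#'
#' Each configuration pairs a technique with its tuning parameters and gets
#' a stable identifier (e.g. `mdmr_p1`, `plsr_k50`) used in every output
#' table. All statistics are oriented so that larger values mean stronger
#' evidence of a difference between the two groups; their significance is
#' always assessed against a resampling-derived empirical null
#' ([derive_null()]), never a parametric reference.
#'
#' @param technique One of `"metastats_global"`, `"lasso"`, `"ridge"`,
#'   `"elastic_net"`, `"mdmr"`, `"pcr"`, `"plsr"`, `"diversity_family"`.
#' @param minkowski_p Minkowski exponent for `mdmr`; the benchmark grid is
#'   `c(0.25, 0.5, 1, 2, 4)`. Values below 1 use the same formula though
#'   the result is then not a metric.
#' @param n_components Component count for `pcr`/`plsr`: a positive integer
#'   or `"all"` (grid `5, 10, 50, "all"`). Capped at the training-fold rank.
#' @param per_feature_alpha Per-feature significance level retained for
#'   configurations that report per-feature decisions.
#' @param fdr_level Benjamini-Hochberg level used inside the Metastats
#'   global statistic (default 0.05).
#' @param sparse_total_threshold A feature whose summed raw count is at or
#'   below this value is tested by Fisher's exact test instead of the
#'   t-test (default 8). Only applies when raw counts are available.
#' @param hill_orders Ascending Hill orders q for the diversity family;
#'   default `c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)`.
#' @param elastic_net_mixing Elastic-net mixing parameter in (0, 1)
#'   (default 0.5).
#' @param cv_folds Folds for every internal cross-validation (default 10),
#'   stratified by group.
#' @param t_null Reference distribution for the per-feature t p-values of
#'   the Metastats global statistic: `"pooled_permutation"` (default;
#'   observed |t| referred to the permutation distribution pooled across
#'   features, as in Metastats' small-sample procedure) or `"welch"`
#'   (parametric Welch-Satterthwaite reference).
#' @param inner_permutations Number of inner relabelings for the pooled
#'   permutation reference (default 1000; p-value resolution is
#'   1/(inner_permutations x features)).
#' @param welch Use Welch (unequal variance) t-tests (default `TRUE`);
#'   `FALSE` pools variances.
#' @param id Optional identifier override.
#' @return An object of class `technique_config`.
#' @export
technique_config <- function(technique = c("metastats_global", "lasso", "ridge",
                                           "elastic_net", "mdmr", "pcr", "plsr",
                                           "diversity_family"),
                             minkowski_p = 1, n_components = 5,
                             per_feature_alpha = 0.05, fdr_level = 0.05,
                             sparse_total_threshold = 8,
                             hill_orders = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf),
                             elastic_net_mixing = 0.5, cv_folds = 10,
                             t_null = c("pooled_permutation", "welch"),
                             inner_permutations = 1000,
                             welch = TRUE, id = NULL) {
  technique <- match.arg(technique)
  t_null <- match.arg(t_null)
  if (!is_count(inner_permutations)) {
    abort("inner_permutations must be a positive integer")
  }
  if (!is.numeric(minkowski_p) || minkowski_p <= 0) {
    abort("minkowski_p must be positive")
  }
  if (!(identical(n_components, "all") || is_count(n_components))) {
    abort("n_components must be a positive integer or 'all'")
  }
  if (is.unsorted(hill_orders) || any(hill_orders < 0)) {
    abort("hill_orders must be nonnegative and ascending")
  }
  if (elastic_net_mixing <= 0 || elastic_net_mixing >= 1) {
    abort("elastic_net_mixing must lie strictly in (0, 1)")
  }
  if (!is_count(cv_folds) || cv_folds < 2) abort("cv_folds must be >= 2")
  if (sparse_total_threshold < 0) abort("sparse_total_threshold must be >= 0")

  id <- id %||% switch(technique,
    metastats_global = "metastats",
    lasso = "lasso",
    ridge = "ridge",
    elastic_net = "enet",
    mdmr = paste0("mdmr_p", format(minkowski_p)),
    pcr = paste0("pcr_k", if (identical(n_components, "all")) "all" else n_components),
    plsr = paste0("plsr_k", if (identical(n_components, "all")) "all" else n_components),
    diversity_family = "diversity"
  )
  family <- switch(technique,
    metastats_global = "metastats",
    lasso = , ridge = , elastic_net = "regularized",
    mdmr = "mdmr", pcr = "pcr", plsr = "plsr",
    diversity_family = "diversity"
  )
  structure(
    list(technique = technique, id = id, family = family,
         minkowski_p = minkowski_p, n_components = n_components,
         per_feature_alpha = per_feature_alpha, fdr_level = fdr_level,
         sparse_total_threshold = sparse_total_threshold,
         hill_orders = hill_orders, elastic_net_mixing = elastic_net_mixing,
         cv_folds = as.integer(cv_folds), t_null = t_null,
         inner_permutations = as.integer(inner_permutations), welch = welch),
    class = "technique_config"
  )
}

#' @export
print.technique_config <- function(x, ...) {
  cat("<technique_config> ", x$id, " (", x$technique, ")\n", sep = "")
  invisible(x)
}

#' Build case/control group labels
#'
#' @param sample_ids Character vector of all sample ids.
#' @param case_samples Sample ids forming the case group; the rest are
#'   controls. Both groups must be non-empty.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
group_labels <- function(sample_ids, case_samples) {
  if (!all(case_samples %in% sample_ids)) {
    abort("case_samples contains unknown sample ids")
  }
  n_case <- length(unique(case_samples))
  if (n_case == 0L || n_case == length(unique(sample_ids))) {
    abort("both groups must be non-empty")
  }
  tibble::tibble(
    sample_id = as.character(sample_ids),
    group = ifelse(sample_ids %in% case_samples, "case", "control")
  )
}

# Coerce labels (tibble sample_id/group, or named vector) to a logical
# case-indicator aligned with the table's columns.
case_indicator <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "group") %in% names(labels))) {
      abort("labels must have columns 'sample_id' and 'group'")
    }
    m <- match(sample_ids, labels$sample_id)
    if (anyNA(m)) abort("labels are missing some of the table's samples")
    g <- labels$group[m]
  } else if (!is.null(names(labels))) {
    m <- match(sample_ids, names(labels))
    if (anyNA(m)) abort("labels are missing some of the table's samples")
    g <- as.character(labels)[m]
  } else {
    abort("labels must be a data frame or a named vector")
  }
  if (!all(g %in% c("case", "control"))) {
    abort("groups must be 'case' or 'control'")
  }
  ind <- g == "case"
  if (!any(ind) || all(ind)) abort("both groups must be non-empty")
  ind
}
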