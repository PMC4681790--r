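#' Estimate power for one disease model, fold and technique (one repeat)
#'
#' Runs the full spike-in cycle `n_replicates` times: randomly assign
#' `group_size` samples as cases, multiply the model's feature set by
#' `fold` in the case columns (on the raw scale), normalize, compute the
#' technique's statistic, and reject when it meets or exceeds the
#' calibrated null threshold. Power is the rejection fraction. `fold = 1`
#' embeds the null, so power then estimates the achieved type-I error.
#'
#' @param table Baseline raw-scale [abundance_table()]; the same table the
#'   null was calibrated on.
#' @param model A [disease_model()] with a scalar `fold`.
#' @param cfg The [technique_config()] the null was derived for.
#' @param null A [derive_null()] result with matching `technique_id`.
#' @param n_replicates Number of random case/control assignments
#'   (default 100).
#' @param group_size Case-group size; default half the samples.
#' @param seed Root seed; each replicate uses its own child stream.
#' @return A one-row tibble: `technique_id`, `category`, `fraction`,
#'   `fold`, `rejections`, `n_replicates`, `power`.
#' @export
estimate_power <- function(table, model, cfg, null, n_replicates = 100,
                           group_size = NULL, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(model, "disease_model"),
            inherits(cfg, "technique_config"),
            inherits(null, "null_distribution"))
  if (!identical(cfg$id, null$technique_id)) {
    abort("null distribution was calibrated for a different technique")
  }
  if (!is_count(n_replicates)) abort("n_replicates must be a positive integer")
  if (length(model$fold) != 1L) abort("model$fold must be a single value here")
  features <- select_feature_set(table, model)
  rej <- power_replicates(table, features, model$fold, cfg, null$threshold,
                          n_replicates, group_size, seed)
  tibble::tibble(
    technique_id = cfg$id, category = model$category,
    fraction = model$target_fraction, fold = model$fold,
    rejections = rej, n_replicates = as.integer(n_replicates),
    power = rej / n_replicates
  )
}

power_replicates <- function(table, features, fold, cfg, threshold,
                             n_replicates, group_size, seed) {
  n <- length(table$sample_ids)
  group_size <- as.integer(group_size %||% (n %/% 2L))
  if (2L * group_size > n) abort("2 * group_size exceeds the number of samples")
  rej <- 0L
  for (r in seq_len(n_replicates)) {
    stat <- replicate_statistics(table, features, fold, list(cfg),
                                 group_size, child_seed(seed, "split", r),
                                 child_seed(seed, "cv", r))[[1L]]
    if (stat >= threshold) rej <- rej + 1L
  }
  rej
}

# One spike-normalize-test cycle shared by all techniques: split, spike the
# case half, and evaluate every configured statistic on the same spiked
# table (as in the benchmark study, where every technique saw identical
# replicates).
replicate_statistics <- function(table, features, fold, cfgs, group_size,
                                 split_seed, cv_seed) {
  n <- length(table$sample_ids)
  case <- withr::with_seed(split_seed, {
    idx <- sample.int(n, group_size)
    seq_len(n) %in% idx
  })
  spiked <- if (fold > 1) {
    apply_spike(table, features, fold, table$sample_ids[case])
  } else {
    table
  }
  lapply(cfgs, function(cfg) {
    engine <- statistic_engine(spiked, cfg)
    engine(case, cv_seed)
  })
}

#' Standard error of power over repeated assessments
#'
#' Repeating the whole power assessment (fresh random case/control
#' assignments, same calibrated threshold) gives a sequence of power
#' values; their sample standard deviation divided by the square root of
#' the number of repeats is the reported standard error.
#'
#' @param repeats Numeric vector of per-repeat power values (length >= 2).
#' @return The standard error.
#' @export
power_standard_error <- function(repeats) {
  if (length(repeats) < 2L) {
    abort("standard error needs at least two repeats")
  }
  sd(repeats) / sqrt(length(repeats))
}
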