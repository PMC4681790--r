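#' Run the full power benchmark grid
#'
#' Orchestrates the whole study on one baseline table: calibrate every
#' technique's empirical null on shared random splits of the unspiked
#' table, then for each disease model, fold, and repeat run the spike-in
#' power loop, with all techniques evaluated on identical replicates. The
#' result holds one detail row per (technique, model, fold, repeat) and
#' one aggregate row per (technique, model, fold) carrying the mean power
#' and its standard error across repeats.
#'
#' @param table Baseline raw-scale [abundance_table()], e.g. from
#'   [generate_table()].
#' @param models List of [disease_model()]s; each model's `fold` may be a
#'   vector and is expanded into a grid (defaults follow the study design:
#'   `1:5` for 10% models would be typical, `c(1, 5, 10, 20, 30, 40)` for
#'   1% models).
#' @param techniques List of [technique_config()]s.
#' @param n_null Null-calibration resamples per technique (shared splits).
#' @param n_replicates Replicates per power estimate (default 100).
#' @param n_repeats Independent repeats of the whole assessment used for
#'   standard errors (study scale 10; desk scale 3).
#' @param alpha Type-I error level for the thresholds.
#' @param group_size Case-group size; default half the samples.
#' @param seed Root seed; the result is bit-identical across runs and
#'   worker counts for a fixed seed.
#' @param best_per_family Keep, per technique family and disease model,
#'   only the parameterization with the highest mean power (averaged over
#'   folds above 1), mirroring best-in-family reporting.
#' @return A `power_benchmark` tibble with columns `level`
#'   (`"repeat"`/`"aggregate"`), `technique_id`, `family`, `category`,
#'   `fraction`, `fold`, `repeat`, `rejections`, `n_replicates`, `power`,
#'   `se`.
#' @export
run_benchmark <- function(table, models, techniques, n_null = 2000,
                          n_replicates = 100, n_repeats = 3, alpha = 0.05,
                          group_size = NULL, seed = 1L,
                          best_per_family = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (inherits(models, "disease_model")) models <- list(models)
  if (inherits(techniques, "technique_config")) techniques <- list(techniques)
  for (m in models) stopifnot(inherits(m, "disease_model"))
  for (cfg in techniques) stopifnot(inherits(cfg, "technique_config"))
  ids <- vapply(techniques, function(cfg) cfg$id, "")
  if (anyDuplicated(ids)) abort("technique ids must be unique")
  n <- length(table$sample_ids)
  group_size <- as.integer(group_size %||% (n %/% 2L))

  nulls <- calibrate_nulls(table, techniques, n_null, group_size, alpha,
                           child_seed(seed, "calibration"))

  detail <- purrr::imap_dfr(models, function(model, mi) {
    features <- select_feature_set(table, model)
    purrr::map_dfr(seq_along(model$fold), function(fi) {
      fold <- model$fold[fi]
      purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
        rep_seed <- child_seed(seed, "power",
                               ((mi * 131L + fi) * 131L + rep_i))
        rej <- integer(length(techniques))
        for (r in seq_len(n_replicates)) {
          stats <- replicate_statistics(
            table, features, fold, techniques, group_size,
            child_seed(rep_seed, "split", r), child_seed(rep_seed, "cv", r))
          for (t in seq_along(techniques)) {
            if (stats[[t]] >= nulls[[t]]$threshold) rej[t] <- rej[t] + 1L
          }
        }
        tibble::tibble(
          level = "repeat",
          technique_id = ids,
          family = vapply(techniques, function(cfg) cfg$family, ""),
          category = model$category, fraction = model$target_fraction,
          fold = fold, `repeat` = rep_i, rejections = rej,
          n_replicates = as.integer(n_replicates),
          power = rej / n_replicates, se = NA_real_
        )
      })
    })
  })

  aggregate <- detail |>
    dplyr::group_by(.data$technique_id, .data$family, .data$category,
                    .data$fraction, .data$fold) |>
    dplyr::summarise(
      level = "aggregate", `repeat` = NA_integer_,
      rejections = NA_integer_,
      n_replicates = .data$n_replicates[1L],
      se = if (dplyr::n() >= 2L) power_standard_error(.data$power) else NA_real_,
      power = mean(.data$power),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(names(detail)))

  out <- dplyr::bind_rows(detail, aggregate)
  if (best_per_family) out <- filter_best_per_family(out)
  class(out) <- c("power_benchmark", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}

# Shared-split calibration: one set of random splits, every technique's
# statistic evaluated on each, thresholds fixed per technique.
calibrate_nulls <- function(table, techniques, n_null, group_size, alpha,
                            seed) {
  n <- length(table$sample_ids)
  if (n_null < ceiling(1 / alpha)) {
    abort("n_null below 1/alpha: threshold undefined at this resolution")
  }
  engines <- lapply(techniques, function(cfg) statistic_engine(table, cfg))
  stats <- matrix(NA_real_, n_null, length(techniques))
  for (i in seq_len(n_null)) {
    case <- withr::with_seed(child_seed(seed, "null_split", i), {
      idx <- sample.int(n, group_size)
      seq_len(n) %in% idx
    })
    cv_seed <- child_seed(seed, "null_cv", i)
    for (t in seq_along(engines)) {
      stats[i, t] <- engines[[t]](case, cv_seed)
    }
  }
  lapply(seq_along(techniques), function(t) {
    new_null_distribution(techniques[[t]]$id, stats[, t], alpha, n_null, seed)
  })
}

filter_best_per_family <- function(out) {
  best <- out |>
    dplyr::filter(.data$level == "aggregate", .data$fold > 1) |>
    dplyr::group_by(.data$family, .data$category, .data$fraction,
                    .data$technique_id) |>
    dplyr::summarise(mean_power = mean(.data$power), .groups = "drop_last") |>
    dplyr::slice_max(.data$mean_power, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("family", "category", "fraction", "technique_id")
  dplyr::semi_join(out, best,
                   by = c("family", "category", "fraction", "technique_id"))
}

#' Power curves from a benchmark run
#'
#' Mean power versus fold with standard-error bars, one colour per
#' technique, faceted by disease model.
#'
#' @param object A `power_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_benchmark
#' @export
autoplot.power_benchmark <- function(object, ...) {
  agg <- dplyr::filter(object, .data$level == "aggregate")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$fold, y = .data$power,
                                    colour = .data$technique_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$power - .data$se),
                   ymax = pmin(1, .data$power + .data$se)),
      width = 0.1, na.rm = TRUE) +
    ggplot2::facet_wrap(~ category + fraction, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold increase in spiked features", y = "power",
                  colour = "technique")
}

#' Tidy a benchmark result to its per-repeat rows
#'
#' @param x A `power_benchmark` tibble.
#' @param ... Unused.
#' @return The detail (per-repeat) rows as a plain tibble.
#' @method tidy power_benchmark
#' @export
tidy.power_benchmark <- function(x, ...) {
  out <- dplyr::filter(tibble::as_tibble(x), .data$level == "repeat")
  dplyr::select(out, -"level", -"se")
}

#' Summarise a benchmark result to its aggregate rows
#'
#' @param x A `power_benchmark` tibble.
#' @param ... Unused.
#' @return The aggregate rows (mean power and standard error) as a plain
#'   tibble.
#' @method glance power_benchmark
#' @export
glance.power_benchmark <- function(x, ...) {
  out <- dplyr::filter(tibble::as_tibble(x), .data$level == "aggregate")
  dplyr::select(out, -"level", -"repeat", -"rejections")
}
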