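test_that("power standard error is the sd of repeats over sqrt(r)", {
  expect_identical(power_standard_error(c(0.6, 0.6, 0.6)), 0)
  expect_equal(power_standard_error(c(0.5, 0.7)), 0.1, tolerance = 1e-12)
  expect_identical(power_standard_error(rep(0.42, 10)), 0)
  expect_error(power_standard_error(0.5), "two repeats")
})

test_that("estimate_power counts rejections against the calibrated threshold", {
  tab <- generate_table(community_model(n_features = 80, n_samples = 30, seed = 51))
  cfg <- technique_config("mdmr", minkowski_p = 1)
  null <- derive_null(tab, cfg, n_resamples = 300, seed = 3)
  model <- disease_model("common", 0.10, fold = 4, reference_rank = 10)
  est <- estimate_power(tab, model, cfg, null, n_replicates = 40, seed = 6)
  expect_identical(est$rejections <= est$n_replicates, TRUE)
  expect_equal(est$power, est$rejections / 40)
  expect_gt(est$power, 0.5)  # strong spike must be detected often

  null_model <- disease_model("common", 0.10, fold = 1, reference_rank = 10)
  est0 <- estimate_power(tab, null_model, cfg, null, n_replicates = 100, seed = 7)
  expect_gte(est0$power, 0)
  expect_lte(est0$power, 0.12)

  expect_error(estimate_power(tab, model, cfg, null, n_replicates = 0),
               "positive integer")
  wrong <- technique_config("mdmr", minkowski_p = 2)
  expect_error(estimate_power(tab, model, wrong, null), "different technique")
})

test_that("run_benchmark honours the counting contract and determinism", {
  tab <- generate_table(community_model(n_features = 60, n_samples = 20, seed = 52))
  techniques <- list(technique_config("mdmr", minkowski_p = 1),
                     technique_config("diversity_family"))
  models <- list(disease_model("common", 0.10, fold = c(1, 3, 5),
                               reference_rank = 5))
  res <- run_benchmark(tab, models, techniques, n_null = 60,
                       n_replicates = 10, n_repeats = 2, seed = 8)
  expect_identical(sum(res$level == "repeat"), 12L)     # 2 x 1 x 3 x 2
  expect_identical(sum(res$level == "aggregate"), 6L)   # 2 x 1 x 3
  res2 <- run_benchmark(tab, models, techniques, n_null = 60,
                        n_replicates = 10, n_repeats = 2, seed = 8)
  expect_identical(tibble::as_tibble(res), tibble::as_tibble(res2))

  agg <- glance(res)
  det <- tidy(res)
  for (i in seq_len(nrow(agg))) {
    rows <- det[det$technique_id == agg$technique_id[i] &
                  det$fold == agg$fold[i], ]
    expect_equal(agg$power[i], mean(rows$power))
    expect_equal(agg$se[i], power_standard_error(rows$power))
  }
})

test_that("tidiers and autoplot return well-formed objects", {
  tab <- generate_table(community_model(n_features = 40, n_samples = 16, seed = 53))
  res <- run_benchmark(tab, disease_model("rare", 0.10, fold = c(1, 4)),
                       technique_config("diversity_family"),
                       n_null = 40, n_replicates = 5, n_repeats = 2, seed = 9)
  expect_s3_class(autoplot(res), "ggplot")
  null <- derive_null(tab, technique_config("diversity_family"),
                      n_resamples = 50, seed = 2)
  expect_s3_class(autoplot(null), "ggplot")
  expect_named(tidy(null), c("technique_id", "statistic"))
  expect_identical(nrow(glance(null)), 1L)
  long <- tidy(tab)
  expect_identical(nrow(long), 40L * 16L)
})
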