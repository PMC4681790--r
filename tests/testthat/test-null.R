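test_that("threshold puts exactly alpha * N continuous statistics at or above", {
  tab <- generate_table(community_model(n_features = 60, n_samples = 24, seed = 31))
  cfg <- technique_config("mdmr", minkowski_p = 1)
  null <- derive_null(tab, cfg, n_resamples = 1000, alpha = 0.05, seed = 2)
  expect_identical(sum(null$statistics >= null$threshold), 50L)
  expect_identical(null$n_resamples, 1000L)
  expect_false(is.unsorted(null$statistics))
  # determinism
  null2 <- derive_null(tab, cfg, n_resamples = 1000, alpha = 0.05, seed = 2)
  expect_identical(null$statistics, null2$statistics)
  expect_identical(null$threshold, null2$threshold)
  expect_error(derive_null(tab, cfg, n_resamples = 10, alpha = 0.05),
               "1/alpha")
})

test_that("tied statistics escalate the threshold conservatively", {
  stats <- c(rep(0, 970), rep(2, 30))
  thr <- mbpower:::choose_threshold(stats, 0.05)
  expect_identical(thr, 2)
  expect_lte(mean(stats >= thr), 0.05)
  # fully degenerate null rejects nothing rather than everything
  thr0 <- mbpower:::choose_threshold(rep(0, 100), 0.05)
  expect_gt(thr0, 0)
})

test_that("empirical p-values follow the strictly-higher counting rule", {
  null <- mbpower:::new_null_distribution(
    "toy", seq_len(10000) / 10000, alpha = 0.05, n_resamples = 10000, seed = 1)
  # exactly 1% of null statistics higher than the observed value => p = 0.01
  expect_identical(empirical_pvalue(null, 0.99), 0.01)
  expect_identical(empirical_pvalue(null, 2), 0)
  expect_identical(empirical_pvalue(null, -1), 1)
  # non-increasing in the observed statistic
  obs <- seq(-0.1, 1.1, length.out = 50)
  ps <- vapply(obs, empirical_pvalue, 0, null = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("threshold and p-value rejection rules agree off ties", {
  tab <- generate_table(community_model(n_features = 50, n_samples = 20, seed = 33))
  cfg <- technique_config("diversity_family")
  null <- derive_null(tab, cfg, n_resamples = 400, alpha = 0.05, seed = 9)
  for (obs in quantile(null$statistics, c(0.5, 0.9, 0.94, 0.96, 0.999))) {
    if (obs == null$threshold) next  # boundary tie: documented exception
    expect_identical(obs >= null$threshold,
                     empirical_pvalue(null, obs) < null$alpha)
  }
  g <- glance(null)
  expect_equal(g$achieved_level, 0.05, tolerance = 1 / 400 + 1e-9)
})

test_that("rejection rate at the calibrated threshold approaches alpha on
           exchangeable data", {
  tab <- generate_table(community_model(n_features = 40, n_samples = 30, seed = 35))
  cfg <- technique_config("mdmr", minkowski_p = 2)
  null <- derive_null(tab, cfg, n_resamples = 600, alpha = 0.05, seed = 4)
  eng <- mbpower:::statistic_engine(tab, cfg)
  rejections <- vapply(1:400, function(i) {
    case <- withr::with_seed(900000 + i, {
      idx <- sample.int(30, 15)
      1:30 %in% idx
    })
    eng(case, 1L) >= null$threshold
  }, logical(1))
  # binomial tolerance: 400 draws at p = 0.05 => sd ~ 0.011
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})
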