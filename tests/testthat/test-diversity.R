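test_that("Hill numbers satisfy the classical identities", {
  u <- rep(0.2, 5)
  for (q in c(0, 0.5, 1, 2, 4, Inf)) {
    expect_equal(hill_number(u, q), 5, tolerance = 1e-12)
  }
  expect_identical(hill_number(c(0.5, 0.3, 0.2, 0, 0), 0), 3)
  expect_equal(hill_number(c(0.9, 0.1), 2), 1 / 0.82, tolerance = 1e-12)
  p <- c(0.6, 0.3, 0.1)
  expect_equal(hill_number(p, 1), exp(-sum(p * log(p))), tolerance = 1e-12)
  expect_equal(hill_number(p, Inf), 1 / 0.6, tolerance = 1e-12)
  # continuity at q = 1
  expect_equal(hill_number(p, 1 - 1e-7), hill_number(p, 1), tolerance = 1e-4)
  expect_error(hill_number(c(0.5, 0.2), 2), "sum to 1")
  expect_error(hill_number(c(0.9, 0.1), -1), "nonnegative")
})

test_that("Hill numbers agree with vegan's Renyi-based values", {
  skip_if_not_installed("vegan")
  prof <- withr::with_seed(8, {
    x <- rexp(30)
    x / sum(x)
  })
  for (q in c(0, 0.5, 1, 2, 4)) {
    ref <- exp(as.numeric(vegan::renyi(prof, scales = q)))
    expect_equal(hill_number(prof, q), ref, tolerance = 1e-8)
  }
})

test_that("Hill profiles are non-increasing in q for every sample", {
  tab <- generate_table(community_model(n_features = 120, n_samples = 12, seed = 19))
  prof <- hill_profile(tab)
  for (s in unique(prof$sample_id)) {
    d <- prof$diversity[prof$sample_id == s]
    expect_true(all(diff(d) <= 1e-8))
    expect_true(all(d >= 1))
  }
})

test_that("diversity family statistic behaves at its edge cases", {
  cfg <- technique_config("diversity_family")
  dup <- duplicated_group_table()
  labels <- group_labels(dup$sample_ids, grep("^case", dup$sample_ids, value = TRUE))
  expect_equal(diversity_family_statistic(dup, labels, cfg), 0)

  # a single order reduces the family to an ordinary two-sample |t|
  tab <- generate_table(community_model(n_features = 80, n_samples = 20, seed = 25))
  labels2 <- half_labels(tab)
  cfg1 <- technique_config("diversity_family", hill_orders = 1)
  div <- hill_profile(tab, orders = 1)
  case_ids <- labels2$sample_id[labels2$group == "case"]
  tref <- feature_t_statistic(div$diversity[div$sample_id %in% case_ids],
                              div$diversity[!div$sample_id %in% case_ids])
  expect_equal(diversity_family_statistic(tab, labels2, cfg1), abs(tref$t),
               tolerance = 1e-12)
})

test_that("richness-only differences are detected at small Hill orders", {
  # one group has 20 extra rare species: low q should drive the signal
  withr::with_seed(41, {
    n <- 20
    base <- matrix(rlnorm(60 * n, meanlog = 3), 60, n)
    extra <- matrix(0, 20, n)
    extra[, 1:10] <- matrix(rlnorm(20 * 10, meanlog = -1), 20, 10)
    tab <- abundance_table(rbind(base, extra))
  })
  labels <- group_labels(tab$sample_ids, tab$sample_ids[1:10])
  cfg <- technique_config("diversity_family")
  rel <- normalize_relative(tab)
  case <- rel$sample_ids %in% labels$sample_id[labels$group == "case"]
  tq <- vapply(cfg$hill_orders, function(q) {
    d <- apply(rel$values, 2, hill_number, q = q)
    abs(feature_t_statistic(d[case], d[!case])$t)
  }, 0)
  expect_lte(cfg$hill_orders[which.max(tq)], 0.5)
  expect_equal(diversity_family_statistic(tab, labels, cfg), max(tq),
               tolerance = 1e-12)
})
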