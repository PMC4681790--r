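test_that("per-feature Welch t agrees with stats::t.test", {
  cases <- list(
    list(a = c(10, 11, 12), b = c(1, 2, 3)),
    list(a = rlnorm(20), b = rlnorm(25, 0.5)),
    list(a = c(0, 0, 0, 5), b = c(1, 1, 2, 2, 3))
  )
  for (cs in cases) {
    got <- feature_t_statistic(cs$a, cs$b)
    ref <- t.test(cs$a, cs$b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # pooled-variance variant against var.equal = TRUE
  got <- feature_t_statistic(c(10, 11, 12), c(1, 2, 3), welch = FALSE)
  ref <- t.test(c(10, 11, 12), c(1, 2, 3), var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)

  expect_identical(feature_t_statistic(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_identical(feature_t_statistic(rep(0, 4), rep(0, 4)),
                   list(t = 0, p = 1))
})

test_that("vectorized row t-statistics match the scalar implementation", {
  m <- withr::with_seed(3, matrix(rlnorm(40 * 12), 40, 12))
  case <- rep(c(TRUE, FALSE), each = 6)
  p_vec <- mbpower:::row_t_pvalues(m, case)
  p_ref <- apply(m, 1, function(r) {
    feature_t_statistic(r[case], r[!case])$p
  })
  expect_equal(p_vec, p_ref, tolerance = 1e-12)
  tmat <- mbpower:::row_t_matrix(m, cbind(as.numeric(case)), welch = TRUE)
  t_ref <- apply(m, 1, function(r) feature_t_statistic(r[case], r[!case])$t)
  expect_equal(tmat[, 1], t_ref, tolerance = 1e-10)
})

test_that("sparse Fisher p-value equals hypergeometric enumeration", {
  # independent oracle: enumerate all 2x2 tables with the observed margins
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_sparse_pvalue(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_sparse_pvalue(5, 0, 0, 5), enum_fisher(5, 0, 0, 5),
               tolerance = 1e-12)
  expect_equal(fisher_sparse_pvalue(3, 1, 7, 9), enum_fisher(3, 1, 7, 9),
               tolerance = 1e-12)
  expect_identical(fisher_sparse_pvalue(0, 0, 100, 100), 1)
  expect_equal(fisher_sparse_pvalue(2, 5, 40, 30),
               fisher_sparse_pvalue(5, 2, 30, 40), tolerance = 1e-12)
  expect_error(fisher_sparse_pvalue(1.5, 0, 3, 3), "integer")
})

test_that("BH selection follows the step-up rule", {
  # step-up by hand: largest k with p_(k) <= k * level / m rejects p_(1..k)
  expect_identical(fdr_select(rep(0.001, 10), 0.05), rep(TRUE, 10))
  expect_identical(fdr_select(c(0.01, 0.04, 0.03, 0.005), 0.05), rep(TRUE, 4))
  expect_identical(fdr_select(c(0.9, 0.95), 0.05), rep(FALSE, 2))
  expect_identical(fdr_select(numeric(0), 0.05), logical(0))
  expect_error(fdr_select(c(0.5, 1.2)), "0, 1")
})

test_that("global statistic is zero for identical groups, positive for a
           strong shift, and bounded by the feature count", {
  dup <- duplicated_group_table()
  labels <- group_labels(dup$sample_ids, grep("^case", dup$sample_ids, value = TRUE))
  cfg <- technique_config("metastats_global")
  expect_identical(metastats_global_statistic(dup, labels, cfg), 0L)

  tab <- generate_table(community_model(n_features = 100, n_samples = 88,
                                        sparsity_curve = NULL, seed = 21))
  vals <- tab$values
  case_ids <- tab$sample_ids[1:44]
  # shift one feature by ~10 pooled standard deviations in the case group
  vals[1, case_ids] <- vals[1, case_ids] + 10 * stats::sd(vals[1, ])
  shifted <- abundance_table(vals, tab$feature_ids, tab$sample_ids)
  labels2 <- group_labels(tab$sample_ids, case_ids)
  stat <- metastats_global_statistic(shifted, labels2, cfg)
  expect_gte(stat, 1L)
  expect_lte(stat, nrow(vals))
})

test_that("pooled permutation p-values are calibrated and order-preserving", {
  m <- withr::with_seed(9, matrix(rlnorm(60 * 20, sdlog = 1), 60, 20))
  case <- rep(c(TRUE, FALSE), each = 10)
  p <- mbpower:::pooled_permutation_pvalues(m, case, B = 200, welch = TRUE,
                                            seed = 5)
  expect_true(all(p >= 0 & p <= 1))
  obs <- abs(mbpower:::row_t_matrix(m, cbind(as.numeric(case)), TRUE)[, 1])
  # smaller p for larger |t|
  expect_true(all(diff(p[order(obs)]) <= 1e-12))
  # roughly uniform under the null: mean close to 1/2
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
})

test_that("relative-only tables use the t branch for every feature", {
  tab <- generate_table(community_model(n_features = 50, seed = 13))
  rel <- normalize_relative(tab)
  labels <- half_labels(tab)
  cfg <- technique_config("metastats_global", t_null = "welch")
  # identical t-branch results whether counts are absent or all non-sparse
  expect_identical(metastats_global_statistic(rel, labels, cfg),
                   mbpower:::metastats_engine(rel$values, NULL,
                                              mbpower:::case_indicator(labels, rel$sample_ids),
                                              cfg))
})
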