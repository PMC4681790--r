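# Brute-force oracle for the selection rule: order candidates by the
# model's key, accumulate average-abundance shares, stop at the target.
brute_select <- function(avg, key_order, target) {
  cum <- cumsum(avg[key_order]) / sum(avg)
  key_order[seq_len(which(cum >= target)[1])]
}

test_that("rare and common selection match the brute-force rule", {
  vals <- matrix(rep(c(50, 30, 10, 5, 3, 2), 2), ncol = 2)
  tab <- abundance_table(vals)
  avg <- rowMeans(tab$values)

  rare <- select_feature_set(tab, disease_model("rare", 0.10))
  expect_setequal(rare$indices, brute_select(avg, order(avg), 0.10))
  expect_setequal(avg[rare$indices], c(2, 3, 5))
  expect_equal(rare$achieved_fraction, 0.10)

  common <- select_feature_set(
    tab, disease_model("common", 0.5, reference_rank = 1))
  expect_identical(common$indices, 1L)
  expect_equal(common$achieved_fraction, 0.5)

  medium <- select_feature_set(tab, disease_model("medium", 0.10))
  key <- order(abs(avg - mean(avg)))
  expect_setequal(medium$indices, brute_select(avg, key, 0.10))
})

test_that("selection stops minimally at the target fraction", {
  tab <- generate_table(community_model(n_features = 400, seed = 8))
  avg <- rowMeans(tab$values)
  for (cat in c("rare", "medium", "common")) {
    fs <- select_feature_set(
      tab, disease_model(cat, 0.05, reference_rank = 50))
    expect_gte(fs$achieved_fraction, 0.05)
    without_last <- fs$achieved_fraction -
      avg[fs$indices[length(fs$indices)]] / sum(avg)
    expect_lt(without_last, 0.05)
  }
  expect_error(
    select_feature_set(toy_table(), disease_model("rare", 1 + 1e-9)),
    "target_fraction")
})

test_that("correlated selection draws from the reference feature's block", {
  model <- community_model(
    n_features = 500, seed = 3,
    correlation_blocks = list(list(size = 150, loading = 0.9)))
  tab <- generate_table(model)
  fs <- select_feature_set(
    tab, disease_model("correlated", 0.10, reference_rank = 100))
  block <- order(rowMeans(tab$values), decreasing = TRUE)[1:150]
  expect_gt(mean(fs$indices %in% block), 0.8)
  ref <- order(rowMeans(tab$values), decreasing = TRUE)[100]
  expect_false(ref %in% fs$indices)
})

test_that("spiking multiplies only the selected cells of case samples", {
  tab <- toy_table()
  spiked <- apply_spike(tab, 3L, 2, "s1")
  expect_equal(unname(spiked$values["fC", "s1"]), 16)
  expect_identical(spiked$values[, "s2"], tab$values[, "s2"])
  expect_identical(spiked$values[c("fA", "fB"), ], tab$values[c("fA", "fB"), ])

  expect_identical(apply_spike(tab, 3L, 1, "s1")$values, tab$values)
  expect_error(apply_spike(tab, 3L, 0.5, "s1"), "fold")
  expect_error(apply_spike(tab, 3L, 2, character(0)), "empty")
  expect_error(apply_spike(normalize_relative(tab), 3L, 2, "s1"), "raw")
})

test_that("spiking raises the selected set's relative share in cases", {
  tab <- generate_table(community_model(n_features = 200, seed = 12))
  fs <- select_feature_set(tab, disease_model("medium", 0.10))
  case <- tab$sample_ids[1:44]
  base_share <- colSums(normalize_relative(tab)$values[fs$indices, , drop = FALSE])
  ctrl <- setdiff(tab$sample_ids, case)
  for (fold in c(2, 5)) {
    rel <- normalize_relative(apply_spike(tab, fs, fold, case))
    share <- colSums(rel$values[fs$indices, , drop = FALSE])
    expect_true(all(share[case] > base_share[case]))
    expect_identical(share[ctrl], base_share[ctrl])
    expect_gt(mean(share[case]), mean(share[ctrl]))
  }
})
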