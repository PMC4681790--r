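# Shared fixtures: all tables are generated in code, seeded, and small.

toy_table <- function() {
  abundance_table(matrix(c(1, 1, 8, 2, 3, 5), nrow = 3),
                  feature_ids = c("fA", "fB", "fC"),
                  sample_ids = c("s1", "s2"))
}

# Balanced labels assigning the first half of samples as cases.
half_labels <- function(table) {
  n <- length(table$sample_ids)
  group_labels(table$sample_ids, table$sample_ids[seq_len(n %/% 2)])
}

# A table in which case and control groups are feature-wise identical:
# every sample appears once in each group.
duplicated_group_table <- function(n_features = 30, n_samples = 10, seed = 7) {
  base <- withr::with_seed(seed, {
    matrix(rexp(n_features * n_samples) + 0.05, n_features, n_samples)
  })
  abundance_table(cbind(base, base),
                  sample_ids = c(paste0("case", seq_len(n_samples)),
                                 paste0("ctrl", seq_len(n_samples))))
}

random_split <- function(table, group_size = NULL, seed = 1) {
  n <- length(table$sample_ids)
  group_size <- group_size %||% (n %/% 2)
  case <- withr::with_seed(seed, sample(table$sample_ids, group_size))
  group_labels(table$sample_ids, case)
}

`%||%` <- rlang::`%||%`
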