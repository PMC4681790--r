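#' @importFrom rlang %||% abort warn
#' @importFrom stats cor pchisq pt rnorm runif sd var
#' @importFrom utils read.delim
NULL

# Deterministic child seeds: every stochastic stage draws from its own named
# stream so that any stage can be reproduced in isolation and results do not
# depend on evaluation order or worker count. Kept below 2^31 - 1.
child_seed <- function(root, stream, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  s <- (abs(as.double(root)) %% 2147483629) * 48271 + h * 9349 +
    as.double(index) * 7919
  as.integer(s %% 2147483629) + 1L
}

# Stratified fold assignment: shuffles within each class so folds are balanced
# in group membership; deterministic given the seed.
make_folds <- function(group, k, seed) {
  k <- as.integer(k)
  if (k < 2L) abort("cv_folds must be at least 2")
  fold <- integer(length(group))
  withr::with_seed(seed, {
    for (g in unique(group)) {
      idx <- which(group == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
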