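#' Specify a synthetic microbial community
#'
#' Describes a generative model for feature-by-sample abundance tables that
#' emulates the salient properties of real surface-microbiome OTU tables:
#' a heavily right-skewed abundance distribution (log-normal body with a
#' Pareto upper tail, so a few features dominate total abundance), high
#' sparsity with rarer features present in fewer samples, and optional
#' blocks of mutually correlated features driven by shared latent factors.
#'
#' Defaults were calibrated so that a default draw reproduces the shape of
#' published hand-microbiome abundance summaries: the lower three points of
#' the five-number summary of per-feature averages fall within one order of
#' magnitude of each other, the maximum exceeds the median by three or more
#' orders of magnitude, and the mean exceeds the median at least five-fold.
#'
#' @param n_features Number of features (OTUs). The default 2000 keeps
#'   benchmark runs desk-sized; the machinery is size-agnostic.
#' @param n_samples Number of samples; default 88, a balanced 44/44 design.
#' @param mean_log_abundance,sd_log_abundance Location and scale of the
#'   log-normal body of per-feature mean abundances. The default body
#'   median of 2 puts raw values on a read-count-like scale, so rounding
#'   them yields sensible counts for exact sparse-feature tests.
#' @param tail_exponent Pareto shape of the upper tail; smaller is heavier.
#'   Must be positive.
#' @param tail_fraction Fraction of features whose means are drawn from the
#'   Pareto tail rather than the log-normal body.
#' @param sparsity_curve Function mapping a feature's mean abundance to its
#'   per-sample presence probability in (0, 1]; must be monotone increasing.
#'   `NULL` disables presence thinning. The default is logistic in log
#'   abundance with midpoint at the body median, so a median feature is
#'   present in about half the samples while abundant features are near 1.
#' @param correlation_blocks List of `list(size =, loading =)` entries; each
#'   block ties `size` features to one latent log-normal factor per sample
#'   with the given loading in `[0, 1)`. Blocks are assigned to the most
#'   abundant features first, since in real communities abundance
#'   correlation is only observable among prevalent features.
#' @param depth_dispersion Standard deviation of independent per-cell
#'   log-normal multiplicative noise.
#' @param detection_floor Smallest observable abundance for a present
#'   feature; present cells below it are censored up to it, mimicking the
#'   count floor of one read that makes the lowest quartiles of real OTU
#'   tables coincide. Default half the body-median abundance; `0` disables
#'   censoring.
#' @param seed Root seed; all draws flow from named child streams so each
#'   stage is independently reproducible.
#' @return An object of class `community_model`.
#' @export
community_model <- function(n_features = 2000, n_samples = 88,
                            mean_log_abundance = log(2),
                            sd_log_abundance = 0.55,
                            tail_exponent = 0.45,
                            tail_fraction = 0.02,
                            sparsity_curve = default_sparsity_curve(exp(mean_log_abundance)),
                            correlation_blocks = list(),
                            depth_dispersion = 0.6,
                            detection_floor = exp(mean_log_abundance) / 2,
                            seed = 1L) {
  if (!is_count(n_features) || !is_count(n_samples)) {
    abort("n_features and n_samples must be positive integers")
  }
  if (n_samples < 4L) abort("n_samples must be at least 4")
  if (!is.numeric(sd_log_abundance) || sd_log_abundance <= 0) {
    abort("sd_log_abundance must be positive")
  }
  if (!is.numeric(tail_exponent) || tail_exponent <= 0) {
    abort("tail_exponent must be positive")
  }
  if (tail_fraction < 0 || tail_fraction > 1) {
    abort("tail_fraction must lie in [0, 1]")
  }
  if (!is.numeric(detection_floor) || detection_floor < 0) {
    abort("detection_floor must be nonnegative")
  }
  if (!is.null(sparsity_curve) && !is.function(sparsity_curve)) {
    abort("sparsity_curve must be a function or NULL")
  }
  for (b in correlation_blocks) {
    if (!is_count(b$size)) abort("block size must be a positive integer")
    if (!is.numeric(b$loading) || b$loading < 0 || b$loading >= 1) {
      abort("block loading must lie in [0, 1)")
    }
  }
  if (sum(vapply(correlation_blocks, function(b) b$size, 0)) > n_features) {
    abort("correlation block sizes exceed n_features")
  }
  structure(
    list(n_features = as.integer(n_features), n_samples = as.integer(n_samples),
         mean_log_abundance = mean_log_abundance,
         sd_log_abundance = sd_log_abundance,
         tail_exponent = tail_exponent, tail_fraction = tail_fraction,
         sparsity_curve = sparsity_curve,
         correlation_blocks = correlation_blocks,
         depth_dispersion = depth_dispersion,
         detection_floor = detection_floor, seed = as.integer(seed)),
    class = "community_model"
  )
}

#' Default presence-probability curve
#'
#' Logistic in log mean abundance: `1 / (1 + (midpoint / m)^steepness)`.
#' Monotone increasing, strictly inside (0, 1].
#'
#' @param midpoint Mean abundance at which presence probability is 0.5.
#' @param steepness Slope in log space.
#' @return A function mapping mean abundance to presence probability.
#' @export
default_sparsity_curve <- function(midpoint = 2, steepness = 0.8) {
  force(midpoint); force(steepness)
  function(m) 1 / (1 + (midpoint / m)^steepness)
}

#' Draw per-feature expected abundances
#'
#' Means come from a log-normal body; a `tail_fraction` share of features
#' (those with the largest body draws) is replaced by Pareto draws anchored
#' at the body's 90th percentile, producing the few dominant features that
#' give real OTU tables their extreme right skew.
#'
#' @param model A [community_model()].
#' @return Numeric vector of length `n_features`, strictly positive;
#'   deterministic given `model$seed`.
#' @export
sample_mean_abundances <- function(model) {
  stopifnot(inherits(model, "community_model"))
  withr::with_seed(child_seed(model$seed, "means"), {
    m <- exp(rnorm(model$n_features, model$mean_log_abundance,
                   model$sd_log_abundance))
    n_tail <- floor(model$tail_fraction * model$n_features)
    if (n_tail > 0) {
      idx <- order(m, decreasing = TRUE)[seq_len(n_tail)]
      anchor <- exp(model$mean_log_abundance + 1.2816 * model$sd_log_abundance)
      m[idx] <- anchor * runif(n_tail)^(-1 / model$tail_exponent)
    }
    m
  })
}

#' Generate a synthetic abundance table
#'
#' Each cell is `mean_f * latent_block_factor^loading * exp(noise)`, thinned
#' to zero with probability `1 - presence(mean_f)`. Latent factors are one
#' log-normal draw per block per sample, shared by all features of the
#' block; noise is independent per cell with standard deviation
#' `depth_dispersion` on the log scale.
#'
#' @param model A [community_model()].
#' @return An [abundance_table()] with `scale = "raw"`, deterministic given
#'   `model$seed`.
#' @export
generate_table <- function(model) {
  stopifnot(inherits(model, "community_model"))
  nf <- model$n_features
  ns <- model$n_samples
  means <- sample_mean_abundances(model)

  loading <- numeric(nf)
  block_of <- integer(nf)
  if (length(model$correlation_blocks)) {
    by_abund <- order(means, decreasing = TRUE)
    offset <- 0L
    for (b in seq_along(model$correlation_blocks)) {
      blk <- model$correlation_blocks[[b]]
      members <- by_abund[(offset + 1L):(offset + blk$size)]
      loading[members] <- blk$loading
      block_of[members] <- b
      offset <- offset + blk$size
    }
  }

  latent <- withr::with_seed(child_seed(model$seed, "latent"), {
    matrix(rnorm(max(1L, length(model$correlation_blocks)) * ns), ncol = ns)
  })
  noise <- withr::with_seed(child_seed(model$seed, "noise"), {
    matrix(rnorm(nf * ns, sd = model$depth_dispersion), nf, ns)
  })

  logv <- log(means) + noise
  blocked <- which(block_of > 0L)
  if (length(blocked)) {
    logv[blocked, ] <- logv[blocked, ] +
      loading[blocked] * latent[block_of[blocked], , drop = FALSE]
  }
  values <- exp(logv)
  if (model$detection_floor > 0) {
    values[values < model$detection_floor] <- model$detection_floor
  }

  if (!is.null(model$sparsity_curve)) {
    pres <- model$sparsity_curve(means)
    if (any(pres <= 0) || any(pres > 1)) {
      abort("sparsity_curve must return probabilities in (0, 1]")
    }
    keep <- withr::with_seed(child_seed(model$seed, "presence"), {
      matrix(runif(nf * ns) < pres, nf, ns)
    })
    values[!keep] <- 0
  }

  abundance_table(values,
                  feature_ids = sprintf("f%04d", seq_len(nf)),
                  sample_ids = sprintf("s%02d", seq_len(ns)),
                  scale = "raw")
}
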