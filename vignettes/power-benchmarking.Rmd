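---
title: "Benchmarking multivariate differential-abundance tests by spike-in simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multivariate differential-abundance tests by spike-in simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recurring first question in comparative microbiome studies is global: do
two sets of samples (say, cases and controls) differ *at all* in their
feature abundance profiles? Feature-by-feature testing answers a different
question and can miss many small coordinated shifts; conversely, a single
multivariate statistic can detect a difference without naming the features
that drive it. mbpower estimates, by simulation, the statistical power of
six families of such global statistics under controlled, known departures
from the null — the standard way to decide which technique to trust on data
with the awkward properties of OTU tables: thousands of features, tens of
samples, extreme right skew, heavy sparsity, and correlated feature blocks.

Every statistic here shares one orientation (larger = stronger evidence of
a group difference) and one inferential engine: an empirical null obtained
by repeatedly splitting an *unspiked* table into two arbitrary groups. No
parametric null distribution is used anywhere, which frees each statistic
to be whatever scalar best summarizes group difference.

```{r, eval = FALSE}
library(mbpower)

tab <- generate_table(community_model(n_features = 2000, seed = 1))
techniques <- list(technique_config("metastats_global"),
                   technique_config("plsr", n_components = 10),
                   technique_config("mdmr", minkowski_p = 1))
res <- run_benchmark(tab,
                     disease_model("medium", 0.10, fold = 1:5),
                     techniques, n_null = 2000,
                     n_replicates = 100, n_repeats = 3, seed = 1)
autoplot(res)
```

## The simulation cycle

One power estimate is the rejection fraction over `n_replicates` cycles of:

1. randomly assign half the samples as cases (default 44 of 88);
2. multiply the disease model's feature set by the fold factor in the case
   columns, on the raw scale;
3. renormalize every sample to proportions (so the spike bleeds into all
   proportions of a case sample, as a real abundance increase would);
4. compute the technique's statistic and reject when it meets or exceeds
   the technique's calibrated threshold.

The threshold comes from `derive_null()`: `n_null` random half/half splits
of the *unspiked* table — the only data in which the null is true by
construction — with the threshold set so that `round(alpha * N)` of the
null statistics lie at or above it. Repeating the whole assessment
(`n_repeats` times, fresh splits, same threshold) yields the standard error
`sd(power) / sqrt(n_repeats)` reported in the aggregate rows.

`fold = 1` is deliberately part of every grid: it embeds the null inside
the power curve, so each curve's left end doubles as a type-I error check.

## The synthetic community

The benchmark was designed around a published hand-surface OTU table whose
summaries are public but whose matrix is not; `community_model()` emulates
the stated properties rather than resampling real data:

* **Skew** — per-feature mean abundances draw from a log-normal body
  (`mean_log_abundance`, default `log(2)` on a read-count-like scale;
  `sd_log_abundance` 0.55) with the top `tail_fraction` (2%) replaced by
  Pareto draws (`tail_exponent` 0.45), so a handful of features carry most
  of the community's mass. A default draw reproduces the published shape:
  lower three points of the five-number summary of feature averages within
  one decade of each other, maximum more than 10^3 times the median, mean
  more than five times the median.
* **Detection floor** — present cells are censored up to `detection_floor`
  (default half the body median, i.e. one read). This is what makes the
  lowest quartiles of real count tables coincide: a feature observed once
  in 88 samples has average 1/88 regardless of its latent mean.
* **Sparsity** — each feature is present in a sample with probability
  given by `sparsity_curve`, logistic in log mean abundance, so rare
  features are absent from most samples (zero fraction is monotonically
  decreasing in abundance, roughly 0.7 down to 0.3 across the default
  range).
* **Correlation** — optional blocks tie features to one latent log-normal
  factor per sample with loading in `[0, 1)`. Blocks attach to the most
  abundant features: in real communities correlation is only observable
  among prevalent features, and the correlated disease model's reference
  feature (abundance rank 100) must be able to sit inside a block.
* **Noise** — independent per-cell log-normal noise (`depth_dispersion`,
  default 0.6 on the log scale).

What the generator does *not* emulate: phylogenetic structure behind the
correlation blocks, read-level sampling (cells are continuous, not
multinomial draws), and the compositional coupling induced by fixed
sequencing depth. Passing benchmarks here therefore show that a technique
behaves correctly under skew, sparsity and blocked correlation — not that
its power on any particular real dataset will match these curves.

## Disease models

`disease_model()` reproduces the eight spike-in designs: a category
(`rare`, `medium`, `common`, `correlated`), a cumulative baseline share
(1% or 10%), and a fold multiplier grid (1–5 for the 10% sets; 1–40 for
the 1% sets). Features are accumulated under the category's ordering rule
until their share of total average abundance first reaches the target;
ties break by feature index, so selection is deterministic and minimal
(dropping the last feature falls below target).

"Increased by k times" is implemented as multiplication by k, making
`fold = 1` the exact null — the reading under which power curves rise from
the alpha level, as observed. Correlation for the `correlated` category is
Pearson on relative abundances over all samples (Spearman available);
"centered around" for `medium`/`common` is nearest-by-absolute-difference
to the anchor average, which yields a contiguous window in sorted-abundance
order.

## The six technique families

* **Modified Metastats** (`metastats_global`) — per-feature tests (t on
  proportions; Fisher's exact test on counts for features whose summed raw
  count is at most `sparse_total_threshold` = 8), Benjamini–Hochberg
  selection at `fdr_level` = 0.05, and the *count of significant features*
  as the global statistic. Per-feature t significance is determined by
  resampling, as in Metastats itself: the observed Welch t is referred to
  the permutation distribution of the statistic pooled across features
  (`inner_permutations` = 1000 relabelings, computed in two matrix
  products). The pooling matters: on heavy-tailed abundances the
  parametric t reference is severalfold conservative at the far tail
  (p ~ alpha/m), and because the count statistic is integer-valued the
  outer calibration cannot absorb that miscalibration — the achieved
  type-I error would sit near 2% instead of 5%. The parametric reference
  remains available (`t_null = "welch"`). Tables without count information
  send every feature down the t branch; proportions cannot feed an exact
  count test.
* **Regularized logistic regression** (`lasso`, `ridge`, `elastic_net`) —
  glmnet fits of group on all proportions; lambda by stratified 10-fold
  cross-validated deviance over a 100-value path down to 1e-4 of the
  all-zero lambda, minimum-deviance rule. Statistic: lasso/elastic net,
  `P(chisq_df <= null dev - model dev)` with df = nonzero coefficients
  (0 when nothing enters); ridge, the raw deviance drop. Any strictly
  monotone mapping gives identical power under empirical-null calibration,
  so the bounded lower-tail-probability reading is safe.
* **MDMR** (`mdmr`) — PERMANOVA-style pseudo-F on Gower-centered Minkowski
  distance matrices, exponent grid 0.25/0.5/1/2/4 (exponents below 1 use
  the same formula knowingly outside metric territory). Equals classical
  one-way ANOVA F for Euclidean distance on univariate data — the identity
  the tests use as an oracle.
* **PCR / PLSR** (`pcr`, `plsr`) — regression of the 0/1 indicator on top
  components (5/10/50/all), statistic = 10-fold cross-validated
  `1 - PRESS/TSS`. PCR orders components by variance (SVD); PLSR extracts
  them by NIPALS deflation to maximize covariance with the response.
  Standardization and component extraction are refit inside every training
  fold; folds are stratified by group and seeded. The linear-on-indicator
  fit (rather than logistic) matches the cross-validated-R-squared
  statistic; the logistic variant would need a different fit metric.
* **Diversity family** (`diversity_family`) — Hill numbers
  `^qD = (sum p^q)^(1/(1-q))` per sample over the order grid
  0, 0.25, 0.5, 1, 2, 4, 8, Inf (with the exponential-Shannon and inverse
  Berger–Parker limits at q = 1 and Inf), a two-sample Welch t per order,
  and the family statistic `max_q |t_q|`. The multiplicity of the family
  is absorbed by the outer calibration, which only ever sees the maximized
  statistic — a deliberate simplification of the cited multivariate-t
  adjustment.

## Numerical and design choices

* **Thresholds with tied statistics.** For continuous statistics the
  threshold leaves exactly `alpha * N` null values at or above it (500 of
  10^5 at the study scale). The Metastats count statistic is integer and
  heavily tied at 0; ties escalate the threshold to the next larger
  observed value, so the achieved level is at most alpha (conservative),
  and when every null statistic is identical the threshold moves above
  them all — rejecting nothing rather than everything.
* **Empirical p-values** are `#(null > observed)/N`, exactly the worked
  definition, without the `(r+1)/(N+1)` correction; p = 0 is possible.
  Threshold rejection (`stat >= threshold`) and p-value rejection
  (`p < alpha`) agree except on boundary ties at the threshold itself.
* **Seeding.** One root seed; every stage (generation, calibration splits,
  power splits, CV folds, inner permutations) draws from a named child
  stream, so results are bit-identical across runs and worker counts, and
  any stage can be reproduced in isolation. The permutation reference and
  CV folds are tied to sample order through these streams, so statistics
  that use them are exactly reproducible but only distributionally
  invariant to sample reordering; the closed-form statistics (MDMR,
  diversity, Welch-reference Metastats) are exactly invariant.
* **Degenerate inputs.** Zero-total samples are an error (silently
  dropping them would change n mid-benchmark); zero-variance features get
  t = 0, p = 1; component counts above the training rank are capped with a
  warning; `n_resamples < 1/alpha` is refused because no threshold exists
  at that resolution.
* **Desk-scale defaults.** The study-scale grid (26k features, 10^5 null
  resamples, 100 replicates x 10 repeats) is configuration-reachable but
  the defaults are sized for a desk: 2,000-feature tables, 2,000 null
  resamples, 100 replicates, 3 repeats. The package's own validation runs
  smaller still (120-200 features), which is enough to exercise every code
  path because the machinery is size-agnostic.
* **Shared splits.** Within one calibration run all techniques see the
  same random splits (valid, since thresholds are per-technique); within
  one power replicate all techniques see the same spiked table, mirroring
  the benchmark design where every technique faced identical data. Each
  repeat reuses the single calibrated threshold rather than recalibrating.

## Known limitations

* The abundance scale is continuous; the Fisher branch rounds raw values
  to counts, which is faithful only when the table really is count-like
  (the generator's default scale is).
* Best-in-family reporting (`best_per_family = TRUE`) selects by observed
  mean power and therefore carries selection optimism; it mirrors how such
  comparisons are usually reported rather than correcting them.
* Covariate adjustment, more than two groups, and depletion (fold < 1)
  spike-ins are out of scope.
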