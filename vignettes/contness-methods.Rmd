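---
title: "Calling conditionally beneficial and detrimental genes from transposon insertion counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling conditionally beneficial and detrimental genes from transposon insertion counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contness)
```

## The measurement and the question

A transposon mutagenesis library is a pool of strains, each carrying one
insertion that disrupts one locus. After the pool grows under some
condition, sequencing counts how often each insertion site is represented.
A gene whose disruption slows growth is depleted; one whose disruption
accelerates growth is enriched. contness works from two per-gene summaries
of the site-level counts:

* **total counts** — the sum of reads over all insertion sites inside the
  gene body; a proxy for the aggregate abundance of mutants in that gene;
* **unique counts** — the number of distinct sites with nonzero reads in
  the sample; a sparser summary that is robust to single-site read
  hotspots (PCR jackpots, positional bias).

The genes of interest are *conditionally beneficial* (disruption decreases
growth in a condition — the mutant is depleted, the gene is needed there)
and *conditionally detrimental* (disruption increases growth — the gene's
product is a liability there). They sit below a hierarchy of qualitative
categories decided by replicate-mean counts alone: a gene with mean
control total count below 1 is *essential*; a nonessential gene with mean
total count below 1 in a target condition is *conditionally essential* in
it. Only the remaining, conditionally nonessential genes are modeled —
a count model has nothing to add when the counts are all zero.

## The per-gene model

For one gene, let `y` be its counts across all samples. Insertion counts
are overdispersed, so the sampling model is negative binomial with log
link, parameterized throughout as

    Var(y) = mu + mu^2 / theta,

so larger `theta` means closer to Poisson. The design has genetic
backgrounds `g` (wild type plus knockout strains, each with its own
library) and environments `e` nested within background:

    log E(y) = b0 + x_g b_g + x_{e|g} b_{e|g}

There is deliberately **no environment main effect**: each stress
experiment is performed on a particular background's library, so an
environment shift is only interpretable relative to that background. A
background coefficient `b_g` answers "does disrupting this gene matter in
the knockout strain, under control conditions?"; a nested coefficient
`b_{e|g}` answers "given the background, does the stress change the
picture?". With every (background, environment) cell populated this
design matrix has full column rank; for `G` backgrounds and `E`
environments it has `1 + (G - 1) + G (E - 1)` columns.

### Ridge penalty

Low counts inflate maximum-likelihood coefficients: a cell whose few
counts happen to be zero drives its log-scale coefficient towards minus
infinity. The remedy is a zero-centered Gaussian prior on all
non-intercept coefficients, which turns estimation into ridge-penalized
maximum likelihood:

    maximize  loglik(beta, theta) - (lambda / 2) * sum_j beta_j^2 .

`nbridge()` solves this by iteratively reweighted least squares with an
exact ridge solve for `beta`, alternated with a safeguarded Newton update
of `theta` on the log scale. Both steps are ascent steps (the IRLS update
is step-halved until the penalized objective does not decrease), so the
objective is monotone across outer iterations; convergence is declared
when its relative change falls below `1e-6` (at most 200 outer
iterations), and non-convergence is a flag consumed downstream, never an
error. `theta` is clamped to `[1e-3, 1e5]`. All-zero genes are refused
with a pointer to the mean-count classifier.

### Choosing lambda

Two regimes need different answers.

**Benchmarking a single gene's fit.** `select_lambda()` runs a
warm-started decreasing grid (default 25 values, `100 n` down to
`0.001 n`) and picks the penalty minimizing
`BIC = -2 loglik + log(n) df`. For a ridge penalty a nonzero-coefficient
count is meaningless — shrinkage never reaches exact zero — so `df` is
the effective degrees of freedom of the ridge smoother,
`tr[(X'WX + lambda D)^{-1} X'WX]`, which runs from the column count at
`lambda = 0` down to 1 (the unpenalized intercept) as the penalty grows.

**Calling across genes.** The discovery step pools one coefficient across
all genes and asks which genes are outliers. That comparison is only
meaningful if all genes are comparably shrunk, so the calling paths
(`run_end_to_end()`, `evaluate_power()`) use one shared penalty. Per-gene
BIC selection produces a mixture of shrinkage levels — most null genes
collapse to the largest grid penalty while a few keep nearly unpenalized
noise, and those form a spurious heavy tail under the pooled empirical
null. Selecting a single shared penalty by summed BIC
(`select_lambda_global()`) goes to the other extreme: dominated by null
genes it picks the maximal penalty, and a strongly affected gene then
reabsorbs its unfitted effect into a collapsed dispersion estimate
(`theta` free-falls, the IRLS weights `mu theta / (theta + mu)` collapse
with it, and the effect is shrunk *harder* than null noise — sensitivity
goes to zero). The default is therefore a fixed weakly-informative prior,
`lambda = 0.25`, i.e. `beta ~ N(0, 2^2)` on natural-log fold changes. The
2-SD range covers ~50-fold effects, which real knockout fitness effects
do reach; a standard-normal prior (`lambda = 1`) is measurably too narrow
— at extreme depletions (condition mean near zero against a control mean
of 1000) the penalized optimum prefers the collapsed-dispersion
explanation and the effect is lost. With `lambda = 0.25` the effect
estimate survives at the strongest simulated depletions while genes with
near-zero information (low counts) are still pulled to zero.

### Baselines

`fit_unregularized_nb()` is exactly the `lambda = 0` fit.
`fit_zinb()` is a zero-inflated baseline — a point mass at zero mixed
with the NB regression, intercept-only mixing probability, fit by EM with
posterior-weighted IRLS M-steps. It exists for benchmarking comparisons,
not for calling.

## Discovery: empirical null and local fdr

Under the two-group view, one coefficient pooled across genes is mostly
null scatter plus a minority of real effects in the tails. The null is
estimated from the center of the distribution (`empirical_null()`):
center `delta0` = median, spread `sigma0` = IQR divided by
`2 qnorm(0.75)`, so the tails never contaminate it; the null proportion
`pi0` is the data mass within `delta0 ± sigma0` over the Gaussian mass of
that window, truncated at 1. (A truncated-maximum-likelihood variant on
the central 80% window is available; the 50% window leaves a
doubly-truncated normal too weakly identified.) At least 50 finite
coefficients are required, and a zero-spread distribution is a hard
error.

`local_fdr()` computes `lfdr(b) = min(1, pi0 f0(b) / f(b))` with `f0` the
null Gaussian density and `f` a smooth marginal density estimated by
Poisson regression of histogram counts (120 bins) on a natural spline
(7 df) of the bin midpoints. A gene is called in one count flavor when
`lfdr <= 0.2` (the conventional local-fdr cutoff; configurable), with the
direction read from the sign of `b - delta0`: negative means depleted
insertions, i.e. conditionally beneficial; positive means conditionally
detrimental. A tail-area false discovery rate (`tail_fdr()`) is reported
for reference but never drives calls.

The model is fit independently to total counts and to unique counts, and
`intersect_calls()` keeps a call only when both flavors agree on the
direction; conflicts and single-flavor calls become `none`. The
intersection trades sensitivity for specificity — the intersected call
set is contained in each marginal call set by construction. Finally
`classify_genes()` assembles the hierarchy: essential, conditionally
essential (mean-count rules on total counts, with per-flavor variants
reported for tallies), then beneficial / detrimental / neutral from the
intersected direction.

## What the simulators emulate

`simulate_fit_benchmark()` reproduces the study conditions used for the
model-fit comparison: 3 backgrounds x 4 environments x 5 replicates
(60 samples), 8 blocks of 500 genes with unique-count means
(0.5, 1, 2, 4, 8, 16, 32, 64) shared across all cells, and block
dispersions `theta_gel ~ Gamma(a_g, b_g)` with `a_g, b_g ~ U(0, 5)`
(read as shape and rate; draws clamped at `1e-6`). A sample's total count
given `u` unique insertions is a sum of `u` iid per-site NB(100, 1) read
counts, drawn in closed form as NB(mu = 100 u, theta = u) by negative
binomial additivity; `u = 0` forces a zero total. Because the per-site
law puts ~1% mass at zero reads, a simulated total can occasionally
undershoot the unique count — real aggregated data cannot, since a
counted site has at least one read.

Note these blocks have **no mean differences between cells** — only the
dispersion varies — so the generating truth is intercept-only and the
nested design (12 columns for 12 cells, i.e. saturated) is pure
overfitting capacity. This matters for interpreting the benchmark below.

`simulate_power_sets()` reproduces the 20-set power design: per set,
4,000 genes in a control and a condition arm (default 5 replicates each;
truth labels attached). Totals are NB(1000, 100) except the 100 affected
genes, whose condition mean takes the set's value from
(1, 50, 100, ..., 950); uniques are NB(20, 100) with affected condition
means 1..20. Arms and flavors are drawn independently; each set uses a
sub-seed derived from the master seed so sets are reproducible in
isolation.

What the simulators do *not* emulate: genomic positions and site-level
structure (gene length, insertion bias, TA-site preference), library-size
differences between samples, correlated replicates, and genes that are
essential in the control arm. Tests passing on these simulations say the
estimator and the calling machinery behave as designed under the stated
laws — not that real libraries satisfy those laws.

## The fit benchmark and what "residual variance" can show

`evaluate_fit_benchmark()` fits each simulated gene's total counts with
the unregularized NB, the BIC-ridge NB and the ZINB baseline, and
compares raw residual variance — the variance (denominator `n`) of
`y - fitted` on the response scale, the one axis on which all three model
families are comparable. Pearson-standardized residuals are available as
an option. The headline summary is the percentage of genes (among those
whose ridge fit converged) where the ridge fit has *strictly* lower raw
residual variance than the unregularized fit.

A caution on reading that number: on the benchmark design the
unregularized NB is saturated, and a log-link NB maximum-likelihood fit
reproduces each cell's sample mean exactly, for any dispersion. Cell
means minimize within-cell sums of squares, so the unregularized fit's
in-sample raw residual variance is a per-gene lower bound — a shrunken
fit can tie but never win. In-sample residual variance is therefore a
measure of flexibility, not of fit quality, on this design; the benefit
of shrinkage is an out-of-sample property (the saturated fit chases
replicate noise in 12 cell means; the shrunken fit does not). The
evaluation reports the in-sample comparison because it is the
conventional one for this benchmark, but the number says more about the
convergence behavior of the baseline optimizer than about the ridge
model's quality; `scripts/acceptance.R` recomputes it from scratch.

`evaluate_power()` scores calls against the truth labels per set:
sensitivity (called affected / 100), specificity (uncalled null / 3900),
accuracy. Sensitivity decays as the condition mean approaches the control
mean, and the intersection dominates both marginals in specificity while
never exceeding either in sensitivity (a set-inclusion fact, checked on
every set).

## Numerical and design choices

* Coordinates are 1-based inclusive (GFF convention); an insertion is a
  single 5' position; strand is ignored when assigning sites to genes; a
  site inside two overlapping genes counts toward both.
* `trim_frac` (default 0) trims `floor(trim_frac * L)` from each end of a
  gene before assigning sites, for analyses that exclude insertions near
  the start/stop codons.
* Unique counts are per-sample counts of sites with nonzero reads.
* One dispersion `theta` is estimated per gene and count flavor; nothing
  is shared across genes.
* The empirical null is estimated separately per coefficient label and
  per flavor: effect-size distributions differ across conditions.
* Direction conflicts between flavors resolve to `none` (conservative).
* Essential and conditionally essential genes are excluded before model
  fitting (union over the control and all modeled conditions of the
  mean-total-count < 1 rule); the pipeline reports genes whose fits did
  not converge as `unresolved` rather than dropping them.
* Degenerate inputs: all-zero genes are never fit; an all-zero ZINB
  response returns the point-mass fit with `zero_prob = 1`; empirical
  nulls refuse fewer than 50 finite coefficients or zero spread.
* Problem sizes in the test suite: module tests use reduced gene counts
  (hundreds); the study-condition checks use the full 4,000-gene,
  20-set design (3 replicates for the trend checks, 5 elsewhere), and the
  benchmark reproduction uses a 1,000-gene version alongside the
  full-size run in `scripts/acceptance.R`.

## Known limitations

* Gene-level modeling only: no site-level (e.g. TA-dinucleotide)
  resolution, and no information from the spatial pattern of insertions
  within a gene.
* The empirical-null machinery assumes most genes are null for every
  coefficient; conditions that perturb a large fraction of the genome
  violate `pi0 ≈ 1` and will be miscalibrated.
* No normalization for library size is applied; the nested design absorbs
  per-cell level differences into its coefficients, but unbalanced
  sequencing depth *within* a cell inflates the dispersion estimate.
* The fixed-prior default (`lambda = 0.25`) is a compromise; data sets
  whose true effects are systematically tiny or enormous may warrant a
  different width, exposed as a single configuration value.
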