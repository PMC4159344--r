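---
title: "Deconvolving two-cell-type co-culture expression profiles"
author: "mixdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving two-cell-type co-culture expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdeconv)
```

## The problem

When two cell types are grown in physical co-culture — here the motivating
setting is glioblastoma cells sharing a dish with brain microvascular
endothelial cells, an in vitro model of the tumor perivascular niche — RNA
harvested from the dish is a mixture of both transcriptomes. A gene can then
appear "differentially expressed" relative to monoculture for two entirely
different reasons: the *proportions* of the two cell types changed over the
culture period, or the cells genuinely *re-programmed each other* through
contact or secreted factors. Only the second is biology of interest.

`mixdeconv` separates the two. Its working assumption, shared with the wider
co-culture profiling literature, is that only a small minority of genes
(well under 10%) respond to the interaction, so the bulk of the mixed
profile is explained by a convex combination of the two monoculture
profiles.

## The mixture model and the correlation scan

Write $A_g$ and $B_g$ for the linear-scale intensities of gene $g$ in the
two monocultures and $\alpha$ for the fraction of cell type A in the mixed
RNA pool. The computational mixture at a candidate fraction is

$$m_g(\alpha) = \alpha A_g + (1 - \alpha) B_g,$$

and the estimate $\hat\alpha$ is the grid value whose mixture correlates
best (Pearson) with the observed co-culture profile. The default grid runs
from 0.001 to 0.999 in steps of 0.001 — 999 candidate mixtures spanning
0.1%/99.9% to 99.9%/0.1%.

Two numerical choices deserve comment:

* **Correlation scale.** By default the correlation is computed on
  $\log_2(x + 1)$. On the raw linear scale, Pearson correlation is dominated
  by the handful of brightest probes and the scan loses sensitivity to the
  mixing fraction; the log transform weights the bulk of the distribution.
  `scale = "linear"` is available for fidelity experiments.
* **Ties.** If several grid points tie at the maximum (possible in
  degenerate inputs), the smallest fraction wins, deterministically, and the
  tie count is reported on the `MixtureScan` object and via `message()`.

Each co-culture replicate receives *its own* scan — cell proportions drift
between dishes — and its own expected profile
$m_g(\hat\alpha)$, floored at a configurable pseudocount (default 1
intensity unit) so that per-gene ratios
$r_g = \mathrm{observed}_g / \mathrm{expected}_g$ stay finite. Genes whose
expected intensity sits at the floor are flagged `lowConfidence` and kept:
filtering them is a choice the analyst, not the package, should make.

For raw array summaries, `normalize = TRUE` (the command-line default for
file input) quantile-normalizes all arrays together before scanning. This is
a declared stand-in for platform-specific preprocessing, which is outside
this package's scope; data that are already on a common scale — including
everything produced by the built-in simulator — should skip it, and the R
API therefore defaults to `normalize = FALSE`.

## Calling interaction genes

The per-gene evidence is the vector of $\log_2 r_g$ across replicate
deconvolutions. The table reports:

* the geometric-mean ratio $2^{\overline{\log_2 r_g}}$, expressed as a
  **signed fold change**: $r$ if $r \ge 1$, else $-1/r$, so magnitudes are
  symmetric about $\pm 1$ and no value falls inside $(-1, 1)$;
* a two-sided one-sample t-test of the mean $\log_2$ ratio against 0
  (df $= n - 1$); genes with identical ratios across replicates have their
  variance floored at $10^{-8}$ (log2 scale) so they yield a tiny but
  nonzero p-value rather than an exact zero, which keeps the step-up
  adjustment well behaved;
* Benjamini–Hochberg adjusted p-values;
* the conjunctive call: adjusted $p < 0.05$ (strict) **and**
  $|\mathrm{fold\ change}| \ge 2$ (inclusive — published tables list genes
  at exactly 2.00, so the boundary is in).

### Why a variance-moderation mode exists

With three replicates the per-gene t-test has two degrees of freedom. At
genome scale, a BH threshold near $10^{-3}$ then demands $|t| \gtrsim 25$,
while even a clean four-fold effect over typical replicate noise yields a
noncentrality around 14: the plain test has essentially no power at that
scale, however real the effect. This is a property of df = 2 t-tests, not of
the data. `method = "moderated"` applies empirical-Bayes variance moderation
across genes (limma's `lmFit`/`eBayes`), which borrows strength exactly as
recommended for few-replicate microarray designs and restores sensitivity
(measured sensitivity 1.0 for four-fold spikes at replicate noise 0.25 in
the test suite, versus ~0.01 for the plain test). The plain t-test remains
the default for transparency — its null distribution is exact and
assumption-light — and the moderated mode is the recommendation whenever
$n \le 4$.

## Limiting-dilution (ELDA) analysis

The sphere-formation module estimates the clonogenic cell frequency $f$
under the single-hit Poisson model: a well seeded with $d$ cells stays
sphere-free with probability $(1 - f)^d$. Equivalently, with
$\lambda = -\log(1 - f)$, the per-well positive probability is
$1 - e^{-\lambda d}$ — a binomial complementary log-log model with log-dose
offset. The log-likelihood is concave in $\lambda$, so `fitFrequency()`
solves the score equation directly by root finding (to $10^{-14}$ in
$\lambda$) rather than relying on iteratively reweighted least squares,
which can stall on small plates where some doses are saturated. The 95%
interval is Wald on the cloglog scale, using the analytic expected Fisher
information, mapped back to $[0,1]$ — stable near the boundaries, with
measured coverage 0.956 at $f = 1/9$ over 500 simulated plates of the
default design.

Degenerate plates are flagged rather than fitted: all-negative plates
return $f = 0$ with the exact one-sided upper bound
$1 - 0.05^{1/\sum d_i n_i}$; all-positive plates return the boundary
estimate $f = 1$ with the exact one-sided lower bound. The default plate
design (doses 81/27/9/3/1, 12 wells each) is packaged as data, never
hard-coded: doses are always read from the input.

Group comparisons default to a Welch t-test on per-biological-replicate
frequency estimates (the convention in the experimental literature, where
each biological replicate contributes one frequency); a pooled
likelihood-ratio test (`compareFrequenciesLRT()`), the statistically
standard ELDA comparison, is provided alongside and reported when
replicates permit. `eldaSummary()` emits the log fraction negative per dose
— the quantity whose expectation is the line $d \log(1 - f)$ through the
origin — flagging (not dropping) doses where no well was negative.

## ΔΔCt and subtype statistics

`ddctExpression()` implements standard $\Delta\Delta$Ct quantification with
amplification efficiency fixed at 2, scaled so the reference gene (GAPDH by
default) sits at 10,000 arbitrary units:
$\mathrm{expr} = 10{,}000 \cdot 2^{-(Ct_{gene} - Ct_{ref})}$. Technical
replicates are averaged per (sample, gene) at table construction;
efficiency-corrected variants are out of scope. Doubling `scaleUnits`
doubles every output exactly.

`centroidScores()` averages each tumor subtype's signature genes per sample
(the centroid profile); `centroidCorrelations()` correlates one gene's
expression with each centroid across samples, returning `NA` (flagged, not
an error) where either side has zero variance. `pairwiseSubtypeTests()`
runs all unordered pairwise two-sample t-tests (Welch by default — the
pooled-variance form is an option, since published methods rarely say
which) with Bonferroni correction by the number of pairs; four subtypes
give six pairs.

## What the simulator emulates — and what it does not

`simConfig()` / `genMonocultures()` / `genCoculture()` generate:

* heavy-tailed per-gene intensities, $2^{N(\mu, \sigma)}$ with defaults
  $\mu = 8$, $\sigma = 2$ (log2 units), emulating bead-array summary
  intensities;
* two cell types diverging by a per-gene log2 offset $N(0, \tau)$,
  $\tau = 2$ by default — clearly distinct monoculture profiles, as between
  an endothelial and a glioma line;
* linear mixing at a known $\alpha$, multiplicative replicate noise
  $2^{N(0, \sigma_\epsilon)}$ ($\sigma_\epsilon = 0.1$ by default; the
  source study reports no replicate variance, so this knob is a free choice,
  not a literature value), and a chosen set of interaction genes multiplied
  by $2^{e_g}$;
* by default the interaction effect multiplies the *summed* mixture signal,
  because a bulk assay sees only the pooled RNA — which cell type changed is
  not identifiable from the array alone. `effectCompartment = "A"` or
  `"B"` applies the effect to one compartment's contribution before summing,
  for sensitivity studies.

Seeding is split per generator call and per replicate, so identical
configurations are bit-identical and adding a fourth replicate never
perturbs the first three.

The simulator does **not** model probe-level bead replicates, background,
detection p-values, cross-hybridization, probe GC effects, or any
within-gene correlation structure; passing tests on simulated data
demonstrate the estimators' correctness under the stated generative model,
not robustness to every artifact of real arrays. The companion ELDA and Ct
generators draw negative wells as
$\mathrm{Binomial}(n, (1-f)^d)$ and Ct values with additive Gaussian cycle
noise respectively.

## Problem sizes used in the test suite

The suite exercises exact-recovery over 50 seeded mixtures (300 genes),
contaminated recovery over 200 runs (2,000 genes, 10% two-fold
contamination, noise 0.2), the global-null calling behavior over 200 runs
(10,000 genes, 3 replicates), ELDA fits against a $10^{-6}$-resolution
brute-force likelihood grid on 100 random plates plus 500-plate coverage,
and closed-form oracles for every scalar statistic. These sizes were chosen
to estimate each property's pass/fail status with comfortable Monte-Carlo
margins while keeping the default test run in the minutes range.

## Known limitations

* The mixture model is strictly two-component; a third cell type biases
  $\hat\alpha$ toward whichever monoculture it resembles.
* $\hat\alpha$ is a grid value; off-grid truth is recovered to grid
  resolution (0.001 by default), which is far below the biological
  replicate-to-replicate variation in practice.
* The interaction call cannot localize the responding cell type or the
  mechanism (contact vs secreted factor); that requires follow-up designs
  such as conditioned-media swaps or fixed-cell co-cultures.
* Reciprocal changes that cancel in the pooled signal (up in one
  compartment, down in the other) are invisible by construction.
* ΔΔCt assumes perfect doubling per cycle; primer efficiencies below 2
  bias relative expression multiplicatively.
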