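---
title: "Comparing partial-correlation networks in like-sex twin samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing partial-correlation networks in like-sex twin samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinnet)
```

## The scientific problem

Depressive symptoms, cognitive functions and leisure activities are strongly
interrelated, which makes it hard to isolate the contribution of any single
risk factor. A Gaussian graphical model (GGM) addresses this by treating each
symptom, test score and activity frequency as a node and estimating the
*partial* correlation between every pair of nodes — the association that
remains after conditioning on all other variables. A like-sex twin sample
adds a natural control for genetic and shared-environmental confounding:
if two networks built from the two members of the same twin pairs do not
differ, and monozygotic (MZ) networks do not differ from dizygotic (DZ)
ones, then a difference between women's and men's networks is unlikely to be
a genetic artifact.

`twinnet` implements this whole design as a reusable pipeline: a synthetic
twin-pair generator with known ground-truth networks, skewness screening
with rank-based Gaussianization, regularized GGM estimation with extended-BIC
model selection, centrality and stability diagnostics, a permutation network
comparison test (NCT), and the three-level comparison (co-twins, zygosity,
gender).

## Network estimation

Estimation works on the Pearson correlation matrix of the (preprocessed)
data, so it is invariant to column rescaling. The graphical lasso maximizes

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \neq j} |\theta_{ij}|$$

over positive-definite precision matrices $\Theta$; the diagonal is not
penalized. Edge weights are the partial correlations
$w_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$. The solver is
blockwise coordinate descent with warm starts along a log-spaced path of
100 penalties from $\lambda_{\max}$ (the smallest penalty that empties the
graph) down to $0.01\,\lambda_{\max}$. Every fit satisfies the stationarity
(KKT) conditions of the objective to well below $10^{-4}$; the test suite
certifies this against an independent ADMM solver of the same objective.

Model selection uses the extended Bayesian information criterion,
$\mathrm{EBIC} = -2\ell + E\log n + 4E\gamma\log p$, with $\gamma = 0.5$ by
default, minimized over the 100-model path with ties resolved toward the
sparser model. One choice deserves emphasis: the log-likelihood $\ell$ of a
candidate graph is evaluated at the *support-constrained unpenalized MLE*
of that graph (`refit = TRUE`), not at the shrunken glasso estimate. With
the shrunken estimates, moving down the penalty path reduces the shrinkage
bias on true edges, and that likelihood gain pays for a couple of tiny
spurious edges that ride along — in chain-graph simulations
(p = 10, partial correlations 0.3, n = 2000) the selected model then carries
2–3 false edges of magnitude ~0.01. Evaluating candidates at their refit
MLE removes the bias term from the comparison: a spurious edge then gains
roughly $n\hat\rho^2/2 \approx 0.2$ log-likelihood units against a penalty
of $\log n + 2\log p \approx 12$, and the true support wins essentially
always. The penalized-likelihood variant remains available as
`refit = FALSE`.

## Preprocessing

GGMs assume approximate multivariate normality. Columns whose absolute
skewness (unadjusted Fisher–Pearson $g_1 = m_3/m_2^{3/2}$) exceeds 1 are
passed through the nonparanormal transform: average ranks are mapped through
the Winsorized empirical CDF with truncation constant
$\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$, then through $\Phi^{-1}$, and
rescaled to unit variance. The map is monotone, so rank correlations are
preserved; columns already near-normal are only standardized, preserving
the original data where possible. Transformation happens inside each
estimation call — that is, separately per group and per permutation or
bootstrap resample — because networks are estimated per group; users who
prefer pooled transformation can preprocess once and call
`estimate_network(..., preprocess = FALSE)`.

Missing data are handled by complete-case deletion with a warning; no
imputation is attempted. Constant columns are dropped with a warning.

## Centrality and stability

Strength is the sum of absolute incident edge weights; expected influence
is the signed sum (one-step). Both are reported raw and z-standardized
within each network with the sample (n − 1) SD. Covariate nodes (age,
alcohol) participate in estimation but are flagged so substantive rankings
can exclude them.

The correlation stability (CS) coefficient drops an increasing proportion
of cases (grid 0.05–0.75 by 0.05), re-estimates the network `B` times per
proportion, and reports the largest proportion at which at least 95% of the
subsample centralities still correlate ≥ 0.7 with the full-sample
centralities — requiring all smaller proportions to qualify as well, so a
single noisy grid point cannot inflate the value. The grid caps the
coefficient at 0.75, which is why strongly identified networks at large n
saturate at that value. Values above 0.25 are conventionally read as
acceptable, above 0.5 as good. Edge accuracy uses a nonparametric
case-resampling bootstrap with percentile intervals (BCa adds complexity
without changing any decision here); bootstrapped difference tests declare
two edges (or two nodes' strengths) different when the percentile interval
of their difference excludes zero.

## The network comparison test

Two groups are compared through $S = |{\sum_{i<j}|w^{(1)}_{ij}}| -
\sum_{i<j}|w^{(2)}_{ij}||$ (global strength difference) and
$M = \max_{i<j}|w^{(1)}_{ij} - w^{(2)}_{ij}|$ (maximum edge difference).
Group labels are permuted and the *entire* estimation pipeline — skew
screen, Gaussianization, 100-model EBIC-glasso — is re-run on both permuted
groups; shortcuts on fixed networks would understate the null variability.
p-values use the add-one convention $(b+1)/(K+1)$, so they are never
exactly zero. Per-edge tests reuse the same permutation draws; raw and
Holm-corrected p-values are both reported.

Twin data violate the row-independence assumption of naive permutation, so
three schemes are provided:

* `plain` — permute individuals freely (valid for independent rows);
* `pair` with split pairs — when each pair has one member per group (the
  co-twin design), permutation swaps members within pairs, preserving the
  cross-group dependence exactly;
* `pair` with nested pairs — when pairs are wholly inside one group
  (zygosity and gender comparisons), whole pairs are reallocated.

Pair-respecting permutation keeps the tests exact under co-twin
exchangeability at any cross-twin correlation; plain permutation is
conservative when pairs are split across groups and anticonservative when
they are nested, and is retained mainly for comparability with analyses
that ignored the dependence. `run_study()` defaults to `pair`.

## The three-level design

Level 1 asks whether arbitrary twin labelling matters: within each
gender-by-zygosity stratum, each pair's members are reallocated by fair
coins `R` times (default 1000); each reallocation is tested with an NCT and
the per-group estimated networks are averaged elementwise across
iterations. The p-value distributions are summarized by their minimum, 5th
percentile and the proportion below α; a stratum is flagged as showing real
co-twin differences when that proportion exceeds
$\alpha + 2\sqrt{\alpha(1-\alpha)/R}$ — a conservative binomial band around
the rate expected under exchangeability, made explicit because a decision
rule is needed and none is standard.

Level 2 pools co-twins and compares MZ to DZ within gender; level 3 pools
zygosity and compares women to men, optionally focusing edge-level results
on depressive-symptom nodes. The pooling logic is gated (level 2 is
justified by the absence of co-twin differences, level 3 by the absence of
zygosity differences) but the gates are advisory: all levels are always
computed and gate violations are flagged in the report rather than halting
the pipeline.

## The synthetic twin generator

Real registry data of this kind cannot be redistributed, so the generator
emulates its structure with known ground truth. Each stratum draws pairs
from a $2p$-dimensional Gaussian whose within-twin covariance is
$\Sigma_g = \Theta_g^{-1}$ (gender-specific) and whose cross-twin covariance
is $\rho_z \Sigma_g$ — the equicorrelated ACE simplification with
$\rho_{MZ} = h^2 + c^2$ and $\rho_{DZ} = h^2/2 + c^2$. Defaults are
$h^2 = 0.6$, $c^2 = 0.2$ (cross-twin correlations 0.8 and 0.5, typical for
moderately heritable behavioural phenotypes), stratum sizes mirroring a
middle-aged like-sex twin cohort (918/1122 MZ/DZ female and 730/982 MZ/DZ
male individuals) at quarter scale, and chain-graph ground truth with
partial correlations 0.25, boosted ×1.8 in women so that female networks
are denser and stronger — the qualitative configuration the three-level
design is built to detect. A subset of frequency/count columns plus alcohol
is passed through the monotone map $x \mapsto \exp(x/s)$, standardized with
the exact lognormal moments rather than sample moments — sample-moment
standardization would give each generated batch its own random scale factor
on these heavy-tailed columns, which breaks row exchangeability across
batches and visibly distorts downstream permutation tests. The resulting
sample skewness is well above 1, so the nonparanormal step is always
exercised. Ordinal frequency items are emulated as continuous variables
because the analysis treats them numerically; quantile binning can be
applied downstream as a stress test.

What the generator deliberately does not emulate: item-level floor/ceiling
effects, missingness, response biases, per-variable heritabilities (the
single $\rho_z$ is a simplification; a per-variable extension would slot
into the same interface), or any resemblance to real item distributions.
Passing tests therefore demonstrate that the machinery is correct and well
calibrated under a faithful dependence structure — not that any particular
empirical finding generalizes.

## Numerical choices

* Solver stopping: maximum absolute change in the working covariance below
  $10^{-4} \times$ mean $|S_{ij}|$ (the conventional glasso criterion);
  inner lasso tolerance $10^{-6}$. Fits are KKT-certified at $10^{-4}$ in
  the tests; measured residuals are below $10^{-5}$.
* Edge counts threshold at $10^{-10}$, removing numerical dust only — the
  coordinate-descent soft threshold produces exact zeros.
* EBIC ties (within $10^{-9}$) resolve to the larger penalty.
* Degenerate inputs: constant columns are dropped with a warning before
  skew screening; an all-tied column cannot be Gaussianized and errors.
* Every stochastic routine takes a seed; `run_study` derives per-stage
  substreams from one master seed, so reports reproduce byte-identically.
* The permutation stream of `nct` is made invariant to the order of its two
  group arguments by deterministically sorting the pooled rows (or pairs)
  before permuting.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path at desk scale: oracle comparisons
at $p \le 6$; recovery studies at $p = 10$, $n = 2000$; NCT calibration at
$p = 8$ with 400–500 individuals per group and 100–200 permutations over a
few hundred replicates; the end-to-end three-level study at $p = 6$–39 with
quarter-scale strata, 10–36 reassignments and 20–150 permutations. Defaults
in the package itself remain at the full values (1000 permutations, 1000
reassignments, B = 1000).

## Known limitations

* Gaussian copula margins only; no polychoric option for genuinely ordinal
  data.
* The NCT compares two groups; covariate-adjusted or paired variants are
  out of scope.
* Averaged co-twin networks are means of EBIC-selected weight matrices
  (zeros included), so their sparsity pattern is a union, not a selected
  model.
* No structural-equation variance decomposition (ACE model fitting) — the
  design detects where differences lie, not their biometric composition.
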