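# twinnet

Estimation and comparison of Gaussian graphical models (GGMs) in like-sex
twin samples.

Depression research increasingly models symptoms and risk factors as a
*network*: each depressive symptom, cognitive test score and leisure-activity
frequency is a node, and edges are partial correlations — the association
between two variables conditional on all the others. Comparing such networks
between co-twins, between monozygotic (MZ) and dizygotic (DZ) pairs, and
between genders separates genetically driven from environmentally driven
differences in network architecture. `twinnet` packages that entire design
for researchers in psychiatric epidemiology and behaviour genetics, together
with a synthetic twin-pair generator so every stage can be validated against
known ground truth.

## What it implements

* **Regularized GGM estimation** — graphical lasso (blockwise coordinate
  descent in C++, diagonal unpenalized) over a log-spaced path of 100
  penalties, with extended-BIC model selection:
  `EBIC = -2ℓ + E log n + 4 E γ log p`, γ = 0.5 by default, each candidate
  graph evaluated at its support-constrained unpenalized MLE. Edge weights
  are partial correlations `w_ij = -θ_ij / sqrt(θ_ii θ_jj)`.
* **Preprocessing** — skewness screening (|g₁| > 1) with the Winsorized-ECDF
  nonparanormal transform for offending columns.
* **Centrality** — strength `Σ_j |w_ij|`, one-step expected influence
  `Σ_j w_ij`, z-standardized per network; global strength `Σ_{i<j} |w_ij|`.
* **Stability** — case-dropping bootstrap CS-coefficient (largest drop
  proportion retaining centrality correlation ≥ 0.7 in ≥ 95% of subsamples,
  grid-capped at 0.75), bootstrap percentile CIs for edges, bootstrapped
  difference tests.
* **Network comparison test (NCT)** — permutation test of global strength
  invariance (S) and maximum edge difference (M), re-running the full
  estimation pipeline in every permutation; per-edge tests with Holm
  correction; plain or pair-respecting permutation for twin data.
* **Three-level twin design** — (1) co-twin reassignment analysis with 1000
  random reallocations and averaged networks per stratum, (2) MZ vs DZ
  within gender, (3) women vs men, with advisory pooling gates.
* **Synthetic twin-pair generator** — equicorrelated ACE cross-twin
  structure (ρ_MZ = h² + c², ρ_DZ = h²/2 + c²), gender-specific ground-truth
  precision matrices, skewed marginals, and a 39-node variable registry
  (9 depressive symptoms, 6 cognitive scores, 8 intellectual / 6 physical /
  8 social activity frequencies, age, alcohol).

## Worked example

```r
library(twinnet)

reg <- variable_registry(p = 8)
cfg <- twin_config(
  n_pairs = c(MZ_F = 115, DZ_F = 140, MZ_M = 91, DZ_M = 123),
  registry = reg,
  theta_f  = make_chain_precision(8, 0.25, boost = 1.8),  # women denser
  theta_m  = make_chain_precision(8, 0.25),
  h2 = 0.6, c2 = 0.2, seed = 11)
tw <- generate_twin_pairs(cfg)

fit <- estimate_network(twin_matrix(split_strata(tw)$MZ_F, reg))
fit
#> Regularized partial-correlation network
#>   nodes: 8   edges: 7   n: 230
#>   lambda: 0.5084 (EBIC 1176.09 at gamma 0.50)
#>   global strength: 3.181

study <- run_study(tw, study_config(n_permutations = 100,
                                    n_reassignments = 25,
                                    inner_permutations = 50, seed = 3),
                   registry = reg)
study
#> Three-level twin network comparison
#>   Level 1 (co-twins exchangeable):  MZ_F=TRUE DZ_F=TRUE MZ_M=TRUE DZ_M=TRUE
#>   Level 2 (F, MZ vs DZ): S = 0.133 (p = 0.139), M = 0.133 (p = 0.248)
#>   Level 2 (M, MZ vs DZ): S = 0.289 (p = 0.673), M = 0.271 (p = 0.644)
#>   Level 3 (women vs men): S = 1.477 (p = 0.010), M = 0.256 (p = 0.020)
```

Reading the output: the selected female network recovers the 7 chain edges at
n = 230 with global strength 3.18 (truth: 7 × 0.45 = 3.15). In the study
report, co-twin reallocations and the MZ/DZ comparisons show no differences
(the twin structure is exchangeable by construction), while the women-vs-men
comparison rejects both global strength invariance (S) and structure
invariance (M) — the generator's women's network was boosted ×1.8, and the
three-level design isolates exactly that difference.

Networks export to edge-list TSV, matrix CSV, or GraphML with node-category
attributes for Cytoscape-style rendering via `write_network()`.

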