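---
title: "Pareto task inference on expression data: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto task inference on expression data: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

When cell populations must allocate finite resources across a small number of
essential tasks, theory predicts that their positions in trait space — here,
gene-expression space — concentrate inside a polytope whose vertices
("archetypes") are the phenotypes maximally specialized for one task. A
population trading off `k` tasks fills a `(k-1)`-dimensional simplex: a
triangle for three tasks, a tetrahedron for four. `paretoscope` tests this
geometric prediction on a non-negative expression matrix (samples x genes,
TPM units) and extracts the genes that define each vertex.

The pipeline is, in order:

1. **Informative-gene filter.** Genes with across-sample standard deviation
   and variance both at least 1 TPM are kept (`filter_informative_genes()`).
   Both criteria are evaluated even though at the default thresholds the
   standard-deviation rule alone decides; the redundancy is retained so that
   non-default thresholds behave as documented. No log transform or any
   other preprocessing is applied anywhere: the analysis deliberately runs
   on raw TPM to avoid transformation-induced artefacts.
2. **PCA validation.** Before reducing dimensionality we check that the data
   contain non-random correlation structure at all, by a permutation test on
   correlation-matrix eigenvalues (`pca_permutation_test()`). The statistics
   are `Psi = sum((lambda_i - 1)^2)` and
   `phi = sqrt(Psi / (p (p - 1)))`; both are zero for spherical
   (uncorrelated) data. Each permutation replicate shuffles every gene
   column independently, which destroys inter-gene correlation while
   preserving marginals. p-values use the `(b + 1)/(B + 1)` correction, so
   the smallest reportable value with `B` permutations is `1/(B + 1)` — a
   permutation test can bound, but never certify, smaller p-values.
3. **Covariance PCA.** Dimensionality reduction for the geometry uses
   column-centered, unscaled PCA (`fit_pca()`); eight components by default.
   This is deliberately a different PCA variant from the correlation-based
   one in step 2: validation asks "is there structure among standardized
   variables", geometry wants distances in raw TPM space.
4. **Simplex fitting.** `fit_simplex()` selects `k` actual data points
   (strict data constraint) whose simplex in the leading `k - 1` PCs has
   maximal volume: greedy successive volume maximization from random
   starting points, then single-vertex swap hill-climbing. Restricting
   vertices to data points makes the fit robust to the noise sensitivity
   that afflicts unconstrained maximum-volume formulations, at the price of
   a small inward bias (a vertex can never sit outside the observed cloud).
   Per-sample task weights come from exact simplex-constrained least
   squares, and the explained sample variance (ESV) is
   `1 - sum(residual^2) / sum(centered^2)`.
5. **Choosing k.** `select_k_elbow()` fits each candidate `k`, builds the
   ESV-vs-k curve and returns the knee (below).
6. **t-ratio test.** The ratio of the fitted simplex volume to the convex
   hull volume of the data (both in the leading `k - 1` PCs) is near 1 when
   the cloud itself is simplex-shaped. `t_ratio_test()` builds the null by
   randomizing the data and refitting with identical settings. Because the
   vertices are data points, the observed ratio can never exceed 1.
7. **Archetype-defining genes.** Each archetype's PC coordinates are
   back-projected through the loadings to a centered gene-space profile
   ("coefficients"); positive coefficients mean expression above the cohort
   average at that vertex. The elbow rule (below) cuts the descending
   positive tail and the magnitude-descending negative tail into defining
   gene lists.
8. **Characterization.** Defining-gene lists are tested for gene-set
   over-representation (one-sided hypergeometric against a user-supplied
   GMT, BH-adjusted); sample attributes are tested against archetype
   proximity — hypergeometric for discrete labels, Mann-Whitney for
   continuous covariates — on the top decile of archetype weight.

## Two PCA variants, on purpose

The validation stage standardizes genes (correlation matrix) because its
null — sphericity, all eigenvalues 1 — is only meaningful on standardized
variables. The geometry stage must not standardize: rescaling genes would
distort volumes and hence both the fitted vertices and the t-ratio. The two
stages are separate operations with separate contracts, and swapping either
variant into the other stage would be a modelling error.

## The elbow rule

Both the ESV-vs-k curve and the coefficient curves are cut by the same
construction (`find_elbow_cutoff()`): normalize both axes to `[0, 1]` and
find the point of maximum perpendicular distance from the chord joining the
endpoints. Geometrically this is where a tangent at 45 degrees touches the
normalized curve — the operational version of drawing the horizontal
asymptote of the flat part, the steep line of the extreme part, and taking
the point where the bisecting 45-degree line touches the data.

One subtlety: for a concave curve (high plateau, then drop) the knee lies
*above* the chord; for a convex, L-shaped curve (few extreme values, long
flat tail — the typical coefficient profile) the whole curve lies *below*
the chord, and the relevant landmark is the corner where the curve leaves
the steep segment. The implementation therefore uses the maximum distance
above the chord when the curve rises above it, and otherwise takes the
point just before the maximum-distance corner below the chord. Ties return
the earliest index; a curve with no curvature beyond tolerance returns the
first index with a warning rather than inventing a cutoff. Duplicate values
are collapsed before locating the knee, because the cutoff is a coefficient
*value*: tied genes enter or leave together.

## The t-ratio null: two randomization schemes

The randomization scheme is a genuine design choice, so both defensible
readings are implemented and recorded in the output:

- `shuffle_genes_then_pca` permutes every gene column of the raw matrix,
  re-runs the covariance PCA and refits. This is the more faithful null
  (the whole pipeline is re-applied to structure-free data) and the default
  for reported results.
- `shuffle_pc_columns` permutes the PC coordinate columns directly and is
  roughly two orders of magnitude faster; it preserves the observed
  marginal spread along each component. It is the scheme used for the
  100,000-randomization significance bound, where the slower scheme would
  be prohibitive.

Both schemes are exchangeable for structure-free data, which is what makes
the test calibrated (verified by simulation in the test suite at alpha =
0.05 over 200 datasets). p-values always carry the plus-one correction.

## Numerical choices

- **Convex hull volume** is computed exactly by an incremental hull in
  general dimension (C++), summing signed simplex volumes against an
  interior point. Points within `1e-9 * scale` of a supporting hyperplane
  are treated as non-visible; for volume purposes boundary-coincident
  points are irrelevant.
- **Simplex-constrained least squares** enumerates weight supports and
  solves the equality-constrained normal equations per support — exact for
  the small `k` of this problem class (enumeration is capped at `k <= 12`).
- **Vertex matching** between two archetype sets (bootstrap alignment,
  ground-truth comparison) is the exact assignment optimum, found by
  permutation enumeration with ties broken toward the lexicographically
  earliest permutation.
- **Degenerate inputs** fail loudly: all-identical points, rank-deficient
  clouds for the hull, constant curves for the elbow, and zero-variance
  genes in the validation stage are errors, not silent repairs. Degenerate
  bootstrap or randomization replicates are redrawn/dropped with a count in
  the result.
- **Determinism**: every stochastic stage takes an explicit seed; the
  pipeline derives per-stage seeds from the master seed. Simplex fitting
  canonicalizes row order (lexicographic sort) before seeding restarts, so
  the fitted vertex set does not depend on input row order.

## What the synthetic generator emulates — and what it does not

`generate_pareto_data()` builds a cohort with a known Pareto structure:

- **Geometry.** `k = 4` archetype profiles over a 300-gene panel; samples
  are Dirichlet convex mixtures (`alpha = 0.3`, symmetric) of the profiles.
  The small concentration places samples near the vertices, so each
  archetype has near-pure representatives (minimum vertex purity around
  0.95 at the default cohort size of 200). That is the regime in which
  fitting vertices *as data points* is meaningful; with diffuse mixtures
  (alpha near 1) no sample sits near a vertex and a data-constrained fit is
  the wrong tool.
- **Planted defining genes.** 40 per archetype; half of the distinct
  defining genes are shared between two archetypes, planted as
  opposite-signed trade-off pairs (elevated at one vertex, depressed at the
  other — the sharing pattern the trade-off interpretation predicts).
  Unique genes deviate at a single archetype, with the deviation scaled by
  `k/(k-1)` so that every planted gene has the same centered effect size
  (default 30 TPM) in the space the coefficient extraction reads.
- **Noise and units.** Additive Gaussian noise (default sd 3 TPM — one
  tenth of the planted effect size) truncated at zero to keep TPM-like
  non-negativity; truncation is a documented mild departure from purely
  additive noise. Baselines are uniform on 50-70 TPM so that depressed
  profiles stay non-negative.
- **Attributes.** A binary label drawn with probability
  `0.2 + 0.7 * w` of the enriched category, where `w` is the weight on the
  attribute archetype (strong but non-deterministic enrichment), and a
  continuous covariate `5 * w + N(0, 1)` that increases toward that
  archetype — equivalently, decreases with distance from it.

The generator deliberately does **not** emulate RNA-seq count noise
(negative-binomial overdispersion), library-size or batch artefacts,
correlated background genes, or contamination by non-tumor cell types. A
pipeline that passes on these simulations is therefore validated for its
geometry and statistics, not certified against the full messiness of real
cohorts; on real data the informative-gene filter, the PCA validation step
and the t-ratio test are the guards against absent structure.

## Problem sizes used in the validation suite

The test suite and the acceptance script run the whole pipeline at reduced
scale, chosen to exercise every code path in minutes on one CPU: cohorts of
200 samples by 300 genes for structural checks (the elbow reproducibly
selects four archetypes across 20 seeds), 100,000 fast-scheme
randomizations for the t-ratio significance bound, 200 simulated datasets
for type-I calibration of the t-ratio and of the discrete attribute test,
and exhaustive-enumeration oracles (all vertex subsets at `n <= 12`, all
group assignments for the exact Mann-Whitney, direct pmf summation for the
hypergeometric) wherever a brute-force answer exists.

## Known limitations

- The data-constrained fit cannot place a vertex outside the observed
  cloud; with diffuse mixtures all vertices shrink inward, and the
  recovered archetypes underestimate the true extremes.
- The elbow is a heuristic: ESV curves without a pronounced knee (noise
  blobs) produce a warning and an arbitrary-but-deterministic choice, not
  an abstention.
- The permutation floor `1/(B + 1)` means "p < 1e-5" claims require 1e5
  randomizations; the package reports the attainable bound rather than
  extrapolating.
- Gene-set enrichment is over-representation only (no depletion, no ranked
  statistics), against the informative-gene universe — the sampling frame
  from which defining genes are actually drawn; using the whole genome as
  the universe would inflate significance.
- Attribute tests condition on a single bin fraction (default top decile of
  archetype weight); the choice is exposed and recorded in the output, and
  results should be read as conditional on it.
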