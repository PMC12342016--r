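# paretoscope

Pareto task inference for transcriptomic data, as an R package.

When tumor cell populations trade off a small number of essential tasks
(energy production, protein synthesis, immune evasion, ...), Pareto
optimality theory predicts that their gene-expression profiles fill a
low-dimensional polytope whose vertices — *archetypes* — are the phenotypes
maximally specialized for one task. `paretoscope` tests this prediction on a
non-negative expression matrix (samples × genes, TPM) and characterizes the
archetypes it finds. It is aimed at computational biologists analysing bulk
or single-cell expression cohorts who want the full inference chain —
validation, geometry, significance, gene lists, enrichment — as plain,
seeded, testable R functions.

## The method in brief

Given an expression matrix `X` (n samples × p genes, TPM):

1. keep informative genes (`sd ≥ 1` and `var ≥ 1` TPM across samples);
2. validate PCA by permutation on correlation-matrix eigenvalues
   `λ₁, …, λ_p`: `Ψ = Σ(λᵢ − 1)²`, `ϕ = √(Ψ / (p(p−1)))`, with p-values
   `(b+1)/(B+1)` from B column-wise shuffles;
3. reduce with covariance PCA (8 components by default);
4. fit, for each candidate k, the **maximum-volume simplex with vertices at
   data points** in the leading k−1 PCs (greedy volume maximization + swap
   refinement), and pick k at the elbow of the explained-sample-variance
   curve;
5. test significance with the **t-ratio**: fitted simplex volume over the
   convex-hull volume of the data, compared with the same ratio on
   column-randomized data (one-sided, plus-one-corrected);
6. back-project each archetype to gene space; the elbow of the ordered
   coefficient curve cuts the positive and negative **archetype-defining
   gene lists**, whose cross-archetype sharing is summarized and exported;
7. characterize archetypes by hypergeometric gene-set enrichment (GMT
   input, BH-FDR) and by association with sample attributes
   (hypergeometric for discrete labels, Mann–Whitney for continuous
   covariates, on the top decile of archetype weight).

A seeded synthetic generator (`generate_pareto_data()`) produces cohorts
with known archetypes, planted defining genes with a controlled
shared-vs-unique structure, a label enriched near one archetype and a
covariate gradient — the ground truth every stage is tested against.

## Worked example

```r
library(paretoscope)

truth <- generate_pareto_data(synthetic_config(seed = 1))
run <- run_pipeline(truth$expression,
                    labels = truth$discrete_labels,
                    covariates = list(covariate = truth$continuous_covariate),
                    dims = 8, k = "auto", n_perm = 50, n_rand = 1000,
                    n_boot = 200, scheme = "shuffle_pc_columns", seed = 1)
print(run)
```

```
Pareto task inference run (seed 1)
  informative genes: 300 of 300
  PCA validation: Psi = 4156.829 (p = 0.0196), phi = 0.215 (p = 0.0196)
  8 PCs explain 88.0% of variance
  archetypes: k = 4 (ESV = 0.982)
  t-ratio = 0.798, p = 0.000999 (shuffle_pc_columns)
  defining genes: 109 unique, 67 (61%) shared
```

Reading the output: the permutation test rejects sphericity at its floor
(`1/(B+1)` with B = 50 permutations), so PCA is justified; the elbow on the
explained-sample-variance curve selects four archetypes (the planted
tetrahedron); the fitted simplex covers 80% of the data's convex hull
volume, a ratio no column-randomized replicate reaches, so the t-ratio p
sits at its attainable minimum `1/(n_rand + 1)`; and the defining-gene
extraction yields 109 unique genes of which 61% appear in at least two
archetype lists — the planted trade-off structure (the generator plants 107
distinct defining genes per cohort, about half shared). `run$gene_lists`, `run$overlap$ribbon_table`,
`run$attributes` and `run$enrichment` (when a GMT is supplied) hold the
per-archetype tables.

## Package layout

- `R/expression-io.R` — TSV/GMT/attribute readers, informative-gene filter
- `R/synthetic.R` — ground-truth generator, archetype matching, recovery error
- `R/pca.R` — covariance PCA, Ψ/ϕ statistics, permutation validation
- `R/simplex.R` — simplex fit, weights, ESV, elbow k-selection, bootstrap
- `R/tratio.R` — t-ratio randomization test
- `R/genes.R` — coefficients, elbow cutoff, defining genes, overlap/ribbons
- `R/enrichment.R` — hypergeometric enrichment, BH, attribute tests
- `R/pipeline.R` — end-to-end orchestration (`run_pipeline()`, YAML config)
- `src/geometry.cpp` — convex-hull volume, max-volume simplex, t-ratio null

The methods vignette (`vignettes/pareto-task-inference.Rmd`) documents the
model, the elbow construction, the randomization schemes, numerical choices
and the generator's scope.
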