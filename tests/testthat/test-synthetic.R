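test_that("generator is deterministic, non-negative, and honors the planted design", {
  cfg <- synthetic_config(n_samples = 60, n_genes = 120,
                          n_defining_per_archetype = 12, seed = 7)
  t1 <- generate_pareto_data(cfg)
  t2 <- generate_pareto_data(cfg)
  expect_identical(t1$expression, t2$expression)
  expect_identical(t1$weights, t2$weights)

  expect_true(all(t1$expression >= 0))
  expect_equal(unname(rowSums(t1$weights)), rep(1, 60), tolerance = 1e-12)
  expect_true(all(t1$weights >= 0))

  # per-archetype list sizes are exactly n_defining_per_archetype
  sizes <- vapply(t1$defining_genes,
                  function(d) length(d$positive) + length(d$negative), integer(1))
  expect_identical(unname(sizes), rep(12L, 4))

  # shared fraction by construction: genes in >= 2 lists over unique genes
  all_lists <- lapply(t1$defining_genes, function(d) c(d$positive, d$negative))
  tab <- table(unlist(all_lists))
  expect_equal(sum(tab >= 2) / length(tab), 0.5, tolerance = 0.04)
  expect_identical(sort(names(tab[tab >= 2])), sort(t1$shared_genes))
})

test_that("noiseless expression is exactly the convex mixture of the profiles", {
  cfg <- synthetic_config(n_samples = 50, n_genes = 60, k_archetypes = 4,
                          n_defining_per_archetype = 6, noise_sd = 0,
                          dirichlet_alpha = 0.1, seed = 3)
  truth <- generate_pareto_data(cfg)
  expect_equal(truth$expression, truth$weights %*% truth$archetype_profiles,
               ignore_attr = TRUE, tolerance = 1e-12)
  # samples sitting (numerically) on a vertex match that archetype's profile
  pur <- apply(truth$weights, 1L, max)
  hot <- apply(truth$weights, 1L, which.max)
  at_vertex <- which(pur > 1 - 1e-6)
  expect_gt(length(at_vertex), 0)
  for (i in at_vertex)
    expect_equal(truth$expression[i, ], truth$archetype_profiles[hot[i], ],
                 ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("Dirichlet weight means match alpha/sum(alpha) within Monte Carlo error", {
  alpha <- c(0.5, 1, 2, 0.8)
  cfg <- synthetic_config(n_samples = 2000, n_genes = 40, k_archetypes = 4,
                          n_defining_per_archetype = 5, dirichlet_alpha = alpha,
                          baseline_range = c(45, 60), amplitude = 30, seed = 11)
  truth <- generate_pareto_data(cfg)
  a0 <- sum(alpha)
  expected <- alpha / a0
  se <- sqrt(alpha * (a0 - alpha) / (a0^2 * (a0 + 1)) / 2000)
  dev <- abs(colMeans(truth$weights) - expected)
  expect_true(all(dev < 3 * se))
})

test_that("generator rejects impossible configurations", {
  expect_error(synthetic_config(n_samples = 3, k_archetypes = 4), "at least as many samples")
  expect_error(synthetic_config(n_genes = 100, n_defining_per_archetype = 40),
               "exceeds n_genes")
  expect_error(synthetic_config(latent_dim = 2, k_archetypes = 4), "latent_dim")
})

test_that("archetype matching is an exact assignment and recovery error behaves", {
  set.seed(42)
  ref <- matrix(rnorm(12), 4, 3)
  # permuted copy recovers zero error for any vertex ordering
  perm0 <- c(3, 1, 4, 2)
  truth_like <- list(archetype_profiles = ref)
  class(truth_like) <- "synthetic_truth"
  expect_equal(recovery_error(truth_like, ref[perm0, ]), 0)

  # constant offset c on every coordinate gives c * sqrt(d)
  off <- ref + 0.7
  expect_equal(recovery_error(truth_like, off), 0.7 * sqrt(3), tolerance = 1e-12)

  # assignment solution equals brute force over all k! matchings
  for (trial in 1:5) {
    fitted <- ref[sample(4), ] + matrix(rnorm(12, sd = 0.3), 4, 3)
    D <- as.matrix(dist(rbind(ref, fitted)))[1:4, 5:8]
    allp <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 4), ]
    brute <- min(apply(allp, 1, function(p) sum(D[cbind(1:4, unlist(p))])))
    got <- match_archetypes(ref, fitted)
    expect_equal(attr(got, "total_distance"), brute, tolerance = 1e-12)
  }
})

test_that("synthetic datasets write to plain-text files that read back", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_samples = 20, n_genes = 60, k_archetypes = 3,
                          n_defining_per_archetype = 6, seed = 5)
  truth <- generate_pareto_data(cfg)
  write_synthetic_data(truth, dir)
  back <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(back, truth$expression, tolerance = 0)
  sets <- read_gmt(file.path(dir, "defining_genes.gmt"))
  expect_identical(sets$archetype1_positive$genes,
                   truth$defining_genes[[1]]$positive)
  at <- read_attributes(file.path(dir, "attributes.tsv"),
                        sample_ids = rownames(truth$expression))
  expect_true("label" %in% colnames(at$discrete))
  expect_true("covariate" %in% colnames(at$continuous))
})
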