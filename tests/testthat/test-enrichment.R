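test_that("hypergeometric enrichment matches direct pmf summation", {
  # N = 20, K = 5, n = 5, overlap = 4 -> 76/15504
  universe <- paste0("g", 1:20)
  sets <- list(S = list(description = "", genes = universe[1:5]))
  gl <- c(universe[1:4], "g20")
  res <- hypergeometric_enrichment(gl, sets, universe)
  expect_equal(res$p_raw, 76 / 15504, tolerance = 1e-12)
  expect_identical(res$overlap, 4L)

  # pmf-summation oracle across a grid of configurations
  for (N in c(15, 30)) for (K in c(0, 4, 10)) for (n in c(3, 8)) {
    uni <- paste0("u", seq_len(N))
    set_genes <- head(uni, K)
    glist <- sample(uni, n)
    ov <- length(intersect(glist, set_genes))
    oracle <- sum(dhyper(seq(ov, min(K, n)), K, N - K, n))
    got <- hypergeometric_enrichment(
      glist, list(S = list(description = "", genes = set_genes)), uni)$p_raw
    if (K == 0) expect_equal(got, 1) else
      expect_equal(got, oracle, tolerance = 1e-12)
  }

  # list = universe: overlap = K and p = 1 for every set
  res2 <- hypergeometric_enrichment(universe, sets, universe)
  expect_identical(res2$overlap, 5L)
  expect_equal(res2$p_raw, 1)
  expect_error(hypergeometric_enrichment(gl, sets, character(0)), "empty")
  expect_error(hypergeometric_enrichment("zz", sets, universe), "outside")
})

test_that("BH adjustment reproduces the textbook step-up and stays monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  q <- bh_adjust(p)
  # smallest p: q = min over j of p_(j) * m / j, monotonicity enforced
  expect_equal(q[1], min(p * 25 / seq_along(p)))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Mann-Whitney exact enumeration matches wilcox.test and hand cases", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2/20
  expect_equal(paretoscope:::mann_whitney_exact(1:3, 4:6), 0.1)
  # identical multisets: p = 1 under tie handling
  expect_equal(paretoscope:::mann_whitney_exact(c(1, 2), c(1, 2)), 1)

  # tie-free group sizes <= 8: agreement with the exact wilcox.test null
  set.seed(20)
  for (trial in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(paretoscope:::mann_whitney_exact(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("archetype bins are deterministic and favor the archetype's neighborhood", {
  bundle <- default_fit_bundle()
  fit <- bundle$fit
  b <- bin_samples_by_archetype(fit, 1, 0.1)
  expect_length(b$bin, ceiling(0.1 * nrow(fit$weights)))
  expect_identical(sort(c(b$bin, b$rest)), sort(rownames(fit$weights)))
  # bin members carry the highest weights on the archetype
  expect_gte(min(fit$weights[b$bin, 1]), max(fit$weights[b$rest, 1]) - 1e-12)
  # bin_fraction = 1 returns everyone
  expect_length(bin_samples_by_archetype(fit, 1, 1)$bin, nrow(fit$weights))
})

test_that("discrete attribute test matches the closed-form all-success tail", {
  # bin of 10 all of category c with cohort prevalence 50% over n = 40:
  # p = C(20,10)/C(40,10) (hypergeometric all-success tail)
  w <- matrix(0, 40, 2)
  w[, 1] <- c(seq(0.9, 0.51, length.out = 10), seq(0.5, 0.01, length.out = 30))
  w[, 2] <- 1 - w[, 1]
  rownames(w) <- sprintf("s%02d", 1:40)
  fit <- structure(list(k = 2L, weights = w), class = "simplex_fit")
  labels <- setNames(rep(c("c", "other"), c(20, 20)), rownames(w))
  # the 10 highest-weight samples on archetype 1 are all category "c"
  res <- attribute_discrete(fit, labels, bin_fraction = 0.25)
  row <- res[res$archetype_index == 1 & res$category == "c", ]
  expect_equal(row$p_raw, choose(20, 10) / choose(40, 10), tolerance = 1e-12)
  expect_identical(row$overlap, 10L)
  expect_equal(row$effect, 2)  # bin prevalence 1 vs cohort prevalence 0.5
})

test_that("continuous attribute test uses exact enumeration for small samples", {
  w <- matrix(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), 6, 1)
  w <- cbind(w, 1 - w)
  rownames(w) <- paste0("s", 1:6)
  fit <- structure(list(k = 2L, weights = w), class = "simplex_fit")
  vals <- setNames(c(1, 2, 3, 4, 5, 6), rownames(w))
  res <- attribute_continuous(fit, vals, bin_fraction = 0.5)
  expect_equal(res$p_raw[1], 0.1)  # {1,2,3} vs {4,5,6}
  expect_equal(res$effect[1], -3)
  # missing values are dropped test-wise
  vals2 <- vals; vals2["s3"] <- NA
  res2 <- attribute_continuous(fit, vals2, bin_fraction = 0.5)
  expect_identical(res2$n_bin[1], 2L)
})

test_that("planted attribute structure is detected at the planted archetype", {
  bundle <- default_fit_bundle()
  truth <- bundle$truth
  back <- pca_back_project(bundle$pca, bundle$fit$archetypes_pc)
  perm <- match_archetypes(truth$archetype_profiles[, colnames(back)], back)
  target <- perm[truth$config$attribute_archetype]

  disc <- attribute_discrete(bundle$fit, truth$discrete_labels, 0.1)
  enriched <- disc[disc$category == "enriched", ]
  expect_identical(enriched$archetype_index[which.min(enriched$q_bh)], target)

  cont <- attribute_continuous(bundle$fit, truth$continuous_covariate, 0.1)
  expect_identical(cont$archetype_index[which.min(cont$q_bh)], target)
  # covariate increases with weight on the planted archetype
  expect_gt(cont$effect[cont$archetype_index == target], 0)
})
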