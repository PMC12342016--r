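# Seeded generator of TPM-like expression matrices with planted simplex
# structure: K archetype profiles, Dirichlet mixture weights, planted
# positive/negative defining genes with a configurable shared-vs-unique
# structure, a discrete label enriched near one archetype and a continuous
# covariate increasing with the weight on that archetype.

#' Configuration for the synthetic archetype generator
#'
#' Defaults describe the simulation conditions used throughout the package's
#' tests: a scaled-down cohort of 200 samples over a 300-gene panel filling a
#' tetrahedron (4 archetypes), with 40 planted defining genes per archetype of
#' which half are shared between archetypes as opposite-signed trade-off
#' pairs, and defining-gene deviations ten times the noise level.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param k_archetypes number of archetypes (>= 2).
#' @param latent_dim latent dimensionality; must be at least
#'   `k_archetypes - 1` (the dimension of the spanned simplex). Values above
#'   the minimum are accepted for interface compatibility but add no further
#'   latent structure.
#' @param noise_sd standard deviation of the additive Gaussian noise (TPM).
#' @param dirichlet_alpha Dirichlet concentration; scalar (recycled) or
#'   length-k vector. Values below 1 concentrate samples near the vertices.
#' @param n_defining_per_archetype planted defining genes per archetype.
#' @param shared_fraction target fraction of unique defining genes appearing
#'   in at least two archetype lists (the shared count is rounded to an
#'   integer; see Details).
#' @param amplitude absolute deviation (TPM) of a defining gene's archetype
#'   profile from the gene's baseline.
#' @param baseline_range range of the per-gene baseline expression (TPM).
#' @param attribute_archetype index of the archetype carrying the label
#'   enrichment and covariate gradient, or `NA` to skip attributes.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `synthetic_config` list.
#' @details With `s` shared genes (each planted in exactly two archetype
#'   lists) and `u` unique genes, list slots satisfy `u + s = k * m` and the
#'   shared fraction is `s / u`; `s` is `round(f * k * m / (1 + f))`.
#' @export
synthetic_config <- function(n_samples = 200, n_genes = 300, k_archetypes = 4,
                             latent_dim = k_archetypes - 1, noise_sd = 3,
                             dirichlet_alpha = 0.3,
                             n_defining_per_archetype = 40,
                             shared_fraction = 0.5,
                             amplitude = 30, baseline_range = c(50, 70),
                             attribute_archetype = 1, seed = 1) {
  k <- as.integer(k_archetypes)
  if (k < 2) stop("k_archetypes must be at least 2")
  if (latent_dim < k - 1) stop("latent_dim must be at least k_archetypes - 1")
  if (n_samples < k) stop("need at least as many samples as archetypes")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  alpha <- rep_len(dirichlet_alpha, k)
  if (any(alpha <= 0)) stop("dirichlet_alpha must be positive")
  m <- as.integer(n_defining_per_archetype)
  if (m * k > n_genes)
    stop("n_defining_per_archetype * k_archetypes exceeds n_genes")
  if (baseline_range[1] < amplitude * k / (k - 1))
    stop("baseline_range must stay above amplitude * k/(k-1) to keep profiles non-negative")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    k_archetypes = k, latent_dim = as.integer(latent_dim),
    noise_sd = noise_sd, dirichlet_alpha = alpha,
    n_defining_per_archetype = m, shared_fraction = shared_fraction,
    amplitude = amplitude, baseline_range = baseline_range,
    attribute_archetype = attribute_archetype, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Allocate defining-gene slots: s shared genes live in exactly two archetype
# lists, u - s unique genes in one, with per-archetype list sizes exactly m.
plant_defining_structure <- function(k, m, shared_fraction) {
  total_slots <- k * m
  s <- round(shared_fraction * total_slots / (1 + shared_fraction))
  u <- total_slots - s
  capacity <- rep(m, k)
  assign_pair <- function() {
    ord <- order(-capacity)
    pair <- sort(ord[1:2])
    capacity[pair] <<- capacity[pair] - 1L
    pair
  }
  assign_single <- function() {
    a <- which.max(capacity)
    capacity[a] <<- capacity[a] - 1L
    a
  }
  membership <- vector("list", u)
  if (s > 0) for (g in seq_len(s)) membership[[g]] <- assign_pair()
  if (u > s) for (g in (s + 1):u) membership[[g]] <- assign_single()
  stopifnot(all(capacity == 0L))
  list(n_unique = u, n_shared = s, membership = membership)
}

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- g / rowSums(g)
  # guard against all-zero gamma draws at tiny alpha
  bad <- !is.finite(rowSums(sw))
  if (any(bad)) sw[bad, ] <- 1 / k
  sw
}

#' Generate a synthetic expression matrix with known archetype structure
#'
#' Builds k archetype profiles as a per-gene baseline plus `amplitude`
#' deviations (positive or negative) on that archetype's planted defining
#' genes, draws per-sample mixture weights from a Dirichlet distribution,
#' adds Gaussian noise, and truncates at zero to keep TPM-like
#' non-negativity. A binary label is drawn with probability
#' `0.2 + 0.7 * w` (clipped to \[0, 1\]) of being the enriched category,
#' where `w` is the sample's weight on the attribute archetype, and a
#' continuous covariate is `5 * w` plus unit Gaussian noise.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_truth` list: `expression` (samples x genes matrix),
#'   `archetype_profiles` (k x genes), `weights` (samples x k),
#'   `defining_genes` (per archetype, `positive` and `negative` gene ids),
#'   `shared_genes`, `discrete_labels`, `continuous_covariate`, `config`.
#' @export
generate_pareto_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$k_archetypes
  p <- config$n_genes
  n <- config$n_samples
  m <- config$n_defining_per_archetype
  gene_ids <- sprintf("gene%03d", seq_len(p))
  sample_ids <- sprintf("sample%03d", seq_len(n))

  baseline <- runif(p, config$baseline_range[1], config$baseline_range[2])
  plan <- plant_defining_structure(k, m, config$shared_fraction)
  defining_idx <- sample.int(p, plan$n_unique)

  profiles <- matrix(rep(baseline, each = k), nrow = k,
                     dimnames = list(NULL, gene_ids))
  defining <- replicate(k, list(positive = character(0), negative = character(0)),
                        simplify = FALSE)
  for (g in seq_len(plan$n_unique)) {
    gi <- defining_idx[g]
    members <- plan$membership[[g]]
    # shared genes are trade-off pairs: elevated at one archetype, depressed
    # at the other, so their profile mean stays at baseline. Unique genes
    # deviate at one archetype only; their deviation is scaled by k/(k-1) so
    # the centered effect size (deviation from the cohort mean, which is the
    # quantity the coefficient extraction reads) equals `amplitude` for every
    # planted gene regardless of its sharing status.
    signs <- if (runif(1) < 0.5) c(1, -1) else c(-1, 1)
    dev <- if (length(members) == 2) config$amplitude else
      config$amplitude * k / (k - 1)
    for (j in seq_along(members)) {
      a <- members[j]
      sign_a <- signs[j]
      profiles[a, gi] <- baseline[gi] + sign_a * dev
      slot <- if (sign_a > 0) "positive" else "negative"
      defining[[a]][[slot]] <- c(defining[[a]][[slot]], gene_ids[gi])
    }
  }

  weights <- rdirichlet_rows(n, config$dirichlet_alpha)
  expr <- weights %*% profiles
  if (config$noise_sd > 0)
    expr <- expr + matrix(rnorm(n * p, sd = config$noise_sd), nrow = n)
  expr[expr < 0] <- 0
  dimnames(expr) <- list(sample_ids, gene_ids)

  discrete_labels <- NULL
  continuous_covariate <- NULL
  if (!is.na(config$attribute_archetype)) {
    w <- weights[, config$attribute_archetype]
    pr <- pmin(pmax(0.2 + 0.7 * w, 0), 1)
    discrete_labels <- factor(ifelse(rbinom(n, 1, pr) == 1, "enriched", "background"),
                              levels = c("background", "enriched"))
    names(discrete_labels) <- sample_ids
    continuous_covariate <- 5 * w + rnorm(n)
    names(continuous_covariate) <- sample_ids
  }

  shared_genes <- gene_ids[defining_idx[seq_len(plan$n_shared)]]
  structure(list(
    expression = expr,
    archetype_profiles = profiles,
    weights = weights,
    defining_genes = defining,
    shared_genes = shared_genes,
    discrete_labels = discrete_labels,
    continuous_covariate = continuous_covariate,
    config = config
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic archetype dataset:", cfg$n_samples, "samples x",
      cfg$n_genes, "genes,", cfg$k_archetypes, "archetypes\n")
  cat("  noise sd:", cfg$noise_sd, " amplitude:", cfg$amplitude,
      " shared defining genes:", length(x$shared_genes), "\n")
  invisible(x)
}

# Exact assignment matching by permutation enumeration (k <= 10).
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Match fitted archetypes to reference archetypes
#'
#' Exact one-to-one assignment minimizing the total Euclidean distance,
#' found by enumerating all permutations (k is small in this problem class);
#' ties go to the lexicographically earliest permutation.
#'
#' @param reference,fitted k x d matrices with matching dimensions.
#' @return integer vector `perm` such that `fitted[perm[i], ]` matches
#'   `reference[i, ]`, with attribute `total_distance`.
#' @export
match_archetypes <- function(reference, fitted) {
  if (!all(dim(reference) == dim(fitted)))
    stop("reference and fitted archetype matrices must have identical dimensions")
  k <- nrow(reference)
  if (k > 10) stop("assignment enumeration supports at most 10 archetypes")
  D <- as.matrix(stats::dist(rbind(reference, fitted)))[seq_len(k), k + seq_len(k), drop = FALSE]
  perms <- all_permutations(k)
  costs <- apply(perms, 1L, function(p) sum(D[cbind(seq_len(k), p)]))
  best <- which.min(costs)  # first minimum = lexicographically earliest
  structure(unname(perms[best, ]), total_distance = unname(costs[best]))
}

#' Mean distance between true and fitted archetypes after optimal matching
#'
#' Fitted archetypes given in PC space are first back-projected to gene space
#' through the PCA model; the result is the mean Euclidean distance between
#' matched archetype profiles.
#'
#' @param truth a `synthetic_truth` object.
#' @param fitted_archetypes k x d matrix of fitted archetype positions
#'   (PC coordinates if `pca` is supplied, gene space otherwise).
#' @param pca optional [fit_pca()] model used to back-project.
#' @return non-negative scalar.
#' @export
recovery_error <- function(truth, fitted_archetypes, pca = NULL) {
  ref <- truth$archetype_profiles
  fitted <- fitted_archetypes
  if (!is.null(pca)) fitted <- pca_back_project(pca, fitted_archetypes)
  if (nrow(fitted) != nrow(ref))
    stop("number of fitted archetypes differs from the ground truth")
  if (ncol(fitted) != ncol(ref) && !is.null(colnames(fitted))) {
    # PCA fitted on a gene subset (e.g. after the informative filter):
    # compare on the genes the model carries
    if (!all(colnames(fitted) %in% colnames(ref)))
      stop("fitted archetype genes are not a subset of the ground-truth genes")
    ref <- ref[, colnames(fitted), drop = FALSE]
  }
  if (ncol(fitted) != ncol(ref))
    stop("fitted archetypes have ", ncol(fitted), " coordinates but the truth has ",
         ncol(ref), "; back-project through the PCA model first")
  perm <- match_archetypes(ref, fitted)
  mean(sqrt(rowSums((ref - fitted[perm, , drop = FALSE])^2)))
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the expression TSV, an attribute TSV, a GMT whose sets are the
#' planted defining-gene lists, and a JSON summary of the ground truth.
#'
#' @param truth a `synthetic_truth` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_data <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(truth$expression, file.path(dir, "expression.tsv"))
  if (!is.null(truth$discrete_labels)) {
    tab <- data.frame(sample_id = rownames(truth$expression),
                      label = as.character(truth$discrete_labels),
                      covariate = truth$continuous_covariate)
    write.table(tab, file.path(dir, "attributes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  sets <- list()
  for (a in seq_along(truth$defining_genes)) {
    for (sgn in c("positive", "negative")) {
      genes <- truth$defining_genes[[a]][[sgn]]
      if (length(genes))
        sets[[sprintf("archetype%d_%s", a, sgn)]] <-
          list(description = sprintf("planted %s defining genes, archetype %d", sgn, a),
               genes = genes)
    }
  }
  write_gmt(sets, file.path(dir, "defining_genes.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(
      config = unclass(truth$config),
      shared_genes = truth$shared_genes,
      weights = truth$weights,
      archetype_profiles = truth$archetype_profiles
    ), file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}
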