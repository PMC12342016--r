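# Two distinct PCA variants are used deliberately: covariance PCA on raw TPM
# feeds the simplex fitting, while the permutation validation (Psi/phi) works
# on correlation-matrix eigenvalues of standardized variables, following the
# eigenvalue permutation-test methodology.

#' Covariance PCA of an expression matrix
#'
#' Column-centered (no scaling) SVD-based PCA with a deterministic sign
#' convention: the largest-magnitude loading entry of every component is
#' positive.
#'
#' @param x samples x genes numeric matrix.
#' @param d number of components to retain
#'   (at most `min(n_samples - 1, n_genes)`).
#' @return a `pca_model` list: `means`, `loadings` (genes x d, orthonormal),
#'   `scores` (samples x d), `eigenvalues` (all `min(n-1, p)` covariance
#'   eigenvalues), `explained_fraction` (length d), `d`.
#' @export
fit_pca <- function(x, d) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  n <- nrow(x); p <- ncol(x)
  rank_max <- min(n - 1L, p)
  if (d < 1 || d > rank_max)
    stop("d must be between 1 and min(n_samples - 1, n_genes) = ", rank_max)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = d, nv = d)
  ev <- sv$d^2 / (n - 1)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
  for (j in seq_len(d)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(d))
  structure(list(
    means = mu, loadings = loadings, scores = scores,
    eigenvalues = ev[seq_len(rank_max)],
    explained_fraction = (ev / sum(ev))[seq_len(d)],
    d = d
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Covariance PCA:", nrow(x$scores), "samples,", nrow(x$loadings),
      "genes,", x$d, "components\n")
  cat("  cumulative explained variance:",
      sprintf("%.1f%%", 100 * sum(x$explained_fraction)), "\n")
  invisible(x)
}

#' Back-project PC coordinates to gene space
#'
#' @param pca a `pca_model`.
#' @param coords matrix of PC coordinates (rows = points), or a vector.
#' @return matrix of gene-space positions (means added back).
#' @export
pca_back_project <- function(pca, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  d <- ncol(coords)
  if (d > pca$d) stop("coordinates use more components than the PCA model holds")
  out <- coords %*% t(pca$loadings[, seq_len(d), drop = FALSE])
  sweep(out, 2L, pca$means, `+`)
}

#' Psi sphericity statistic
#'
#' `Psi = sum((lambda_i - 1)^2)` over the eigenvalues of the correlation
#' matrix; zero exactly when all eigenvalues are 1 (no correlation structure).
#'
#' @param eigenvalues_corr correlation-matrix eigenvalues. Supply all `p` of
#'   them (pad with zeros past the matrix rank when `p > n - 1`).
#' @return non-negative scalar.
#' @export
psi_statistic <- function(eigenvalues_corr) {
  if (length(eigenvalues_corr) < 2) stop("need at least two eigenvalues")
  sum((eigenvalues_corr - 1)^2)
}

#' phi sphericity statistic
#'
#' `phi = sqrt(Psi / (p * (p - 1)))`, a \[0, 1\]-scaled companion of
#' [psi_statistic()].
#'
#' @param eigenvalues_corr correlation-matrix eigenvalues (length `p`, padded
#'   with zeros past the rank).
#' @param p number of variables; defaults to `length(eigenvalues_corr)`.
#' @return scalar in `[0, sqrt(p/(p-1))]`.
#' @export
phi_statistic <- function(eigenvalues_corr, p = length(eigenvalues_corr)) {
  if (p < 2) stop("need at least two variables")
  sqrt(psi_statistic(eigenvalues_corr) / (p * (p - 1)))
}

# Full-length correlation eigenvalue vector of a samples x genes matrix
# (zeros appended past the rank so that sum(lambda) = p).
correlation_eigenvalues <- function(x) {
  n <- nrow(x); p <- ncol(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0))
    stop("zero-variance gene encountered; run filter_informative_genes() first")
  z <- scale(x)
  ev <- svd(z, nu = 0, nv = 0)$d^2 / (n - 1)
  c(ev, rep(0, p - length(ev)))
}

#' Permutation validation of PCA
#'
#' Tests for non-random correlation structure before dimensionality
#' reduction. Each permutation replicate independently shuffles every gene
#' column across samples, which destroys inter-gene correlation while
#' preserving each gene's marginal distribution. Psi and phi are computed on
#' correlation-matrix eigenvalues; p-values use the `(b + 1) / (B + 1)`
#' correction and therefore can never reach zero. A principal component is
#' called significant while its observed eigenvalue exceeds the
#' `1 - alpha` quantile of the permutation null of the same-ranked
#' eigenvalue (leading run). Per-PC counts of genes with significant
#' correlation to the scores come from bootstrap percentile intervals that
#' exclude zero; genes with zero variance inside a replicate are assigned
#' correlation zero.
#'
#' @param x samples x genes matrix (informative genes only).
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed integer seed.
#' @param alpha significance level for eigenvalue and correlation calls.
#' @param n_boot bootstrap replicates for gene-correlation intervals;
#'   defaults to `n_perm`. Set to 0 to skip the bootstrap stage.
#' @return a `pca_validation` list with observed and null Psi/phi, p-values,
#'   `n_significant_pcs`, `genes_significant_per_pc`, `n_permutations`,
#'   `seed`.
#' @export
pca_permutation_test <- function(x, n_perm = 100, seed = 1, alpha = 0.05,
                                 n_boot = n_perm) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  n <- nrow(x); p <- ncol(x)
  rank_max <- min(n - 1L, p)
  set.seed(seed)
  ev_obs <- correlation_eigenvalues(x)
  psi_obs <- psi_statistic(ev_obs)
  phi_obs <- phi_statistic(ev_obs, p)

  psi_null <- numeric(n_perm)
  phi_null <- numeric(n_perm)
  ev_null <- matrix(0, n_perm, rank_max)
  for (b in seq_len(n_perm)) {
    xp <- apply(x, 2L, sample)
    evb <- correlation_eigenvalues(xp)
    psi_null[b] <- psi_statistic(evb)
    phi_null[b] <- phi_statistic(evb, p)
    ev_null[b, ] <- evb[seq_len(rank_max)]
  }
  p_psi <- (1 + sum(psi_null >= psi_obs)) / (1 + n_perm)
  p_phi <- (1 + sum(phi_null >= phi_obs)) / (1 + n_perm)

  thresh <- apply(ev_null, 2L, quantile, probs = 1 - alpha, names = FALSE)
  sig <- ev_obs[seq_len(rank_max)] > thresh
  n_sig <- if (sig[1]) which.min(c(sig, FALSE)) - 1L else 0L

  genes_sig <- integer(0)
  if (n_sig > 0 && n_boot > 0) {
    z <- scale(x)
    ref <- svd(z, nu = n_sig, nv = n_sig)
    counts <- matrix(0, n_boot, n_sig)
    lo <- array(NA_real_, c(n_boot, p, n_sig))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      sb <- apply(xb, 2L, sd)
      keep <- sb > 0
      zb <- matrix(0, n, p)
      zb[, keep] <- scale(xb[, keep, drop = FALSE])
      svb <- svd(zb, nu = n_sig, nv = n_sig)
      # align component signs with the reference loadings
      flip <- sign(colSums(svb$v * ref$v[, seq_len(n_sig), drop = FALSE]))
      flip[flip == 0] <- 1
      scores_b <- svb$u %*% diag(svb$d[seq_len(n_sig)] * flip, n_sig, n_sig)
      cors <- suppressWarnings(cor(xb, scores_b))
      cors[!is.finite(cors)] <- 0
      lo[b, , ] <- cors
    }
    genes_sig <- integer(n_sig)
    for (j in seq_len(n_sig)) {
      ci <- apply(lo[, , j, drop = FALSE], 2L, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
      genes_sig[j] <- sum(ci[1, ] > 0 | ci[2, ] < 0)
    }
  }

  structure(list(
    psi_observed = psi_obs, phi_observed = phi_obs,
    psi_null = psi_null, phi_null = phi_null,
    p_psi = p_psi, p_phi = p_phi,
    eigenvalues_observed = ev_obs[seq_len(rank_max)],
    n_significant_pcs = n_sig,
    genes_significant_per_pc = genes_sig,
    n_permutations = n_perm, alpha = alpha, seed = seed
  ), class = "pca_validation")
}

#' @export
print.pca_validation <- function(x, ...) {
  cat("PCA permutation validation (", x$n_permutations, " permutations)\n", sep = "")
  cat(sprintf("  Psi = %.3f (p = %.4g), phi = %.3f (p = %.4g)\n",
              x$psi_observed, x$p_psi, x$phi_observed, x$p_phi))
  cat("  significant PCs:", x$n_significant_pcs, "\n")
  if (length(x$genes_significant_per_pc))
    cat("  genes significantly correlated per PC:",
        paste(x$genes_significant_per_pc, collapse = ", "), "\n")
  invisible(x)
}
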