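# t-ratio randomization test: the volume of the fitted data-constrained
# simplex divided by the volume of the data's convex hull, compared against
# the same ratio on column-shuffled data. Ratios near 1 mean the cloud is
# simplex-shaped; shuffling destroys the joint geometry while preserving
# marginals.

#' t-ratio randomization test
#'
#' Computes the observed t-ratio `simplex_volume / hull_volume` in the
#' leading `k - 1` dimensions and an empirical null distribution by
#' randomizing the data and refitting with identical settings. Two schemes
#' are available: `"shuffle_genes_then_pca"` permutes every gene column of
#' the raw expression matrix, re-runs covariance PCA and refits (faithful,
#' slow); `"shuffle_pc_columns"` permutes the PC coordinate columns directly
#' (fast). The one-sided p-value is `(1 + #{t_null >= t_obs}) / (1 + n_rand)`
#' — larger observed ratios mean a more simplex-like cloud.
#'
#' @param x either a samples x genes expression matrix (required for the
#'   gene-shuffling scheme) or an n x (k-1) matrix of PC scores.
#' @param k number of archetypes.
#' @param n_rand number of randomization replicates (>= 1).
#' @param scheme randomization scheme; see Details.
#' @param seed integer seed.
#' @param n_restarts restarts per simplex fit (observed and null).
#' @param fit optional precomputed [fit_simplex()] on the observed points;
#'   must use the same `k`.
#' @return a `t_ratio_test` list: `t_observed`, `t_null`, `p_value`,
#'   `p_uncorrected` (raw exceedance fraction), `n_randomizations`,
#'   `randomization_scheme`, `n_degenerate`, `seed`.
#' @export
t_ratio_test <- function(x, k, n_rand = 1000,
                         scheme = c("shuffle_genes_then_pca", "shuffle_pc_columns"),
                         seed = 1, n_restarts = 10, fit = NULL) {
  scheme <- match.arg(scheme)
  if (n_rand < 1) stop("n_rand must be at least 1")
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  d <- k - 1L

  if (scheme == "shuffle_genes_then_pca") {
    pca <- fit_pca(x, d)
    points <- pca$scores
  } else {
    if (ncol(x) < d) stop("points need at least k-1 columns")
    points <- x[, seq_len(d), drop = FALSE]
  }

  if (is.null(fit)) {
    fit <- fit_simplex(points, k, n_restarts = n_restarts, seed = seed)
  } else if (fit$k != k) {
    stop("precomputed fit has k = ", fit$k, ", expected ", k)
  }
  t_obs <- simplex_volume(fit$archetypes_fit_dims) / hull_volume(points[, seq_len(d), drop = FALSE])

  set.seed(seed)
  n_degenerate <- 0L
  if (scheme == "shuffle_pc_columns") {
    nul <- .t_ratio_null_cpp(points[, seq_len(d), drop = FALSE], as.integer(k),
                             as.integer(n_rand), as.integer(n_restarts))
    t_null <- nul$t_null
    n_degenerate <- nul$n_degenerate
  } else {
    t_null <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      ok <- FALSE
      for (attempt in 1:100) {
        xp <- apply(x, 2L, sample)
        val <- tryCatch({
          pp <- fit_pca(xp, d)$scores
          fr <- fit_simplex(pp, k, n_restarts = n_restarts, seed = seed + r)
          simplex_volume(fr$archetypes_fit_dims) / hull_volume(pp)
        }, error = function(e) NULL)
        if (!is.null(val) && is.finite(val)) { t_null[r] <- val; ok <- TRUE; break }
        n_degenerate <- n_degenerate + 1L
      }
      if (!ok) stop("could not obtain a non-degenerate randomization replicate")
    }
  }
  if (n_degenerate > 0)
    message(n_degenerate, " degenerate randomization draw(s) redrawn")

  exceed <- sum(t_null >= t_obs)
  structure(list(
    t_observed = t_obs,
    t_null = t_null,
    p_value = (1 + exceed) / (1 + n_rand),
    p_uncorrected = exceed / n_rand,
    n_randomizations = n_rand,
    randomization_scheme = scheme,
    n_degenerate = n_degenerate,
    seed = seed
  ), class = "t_ratio_test")
}

#' @export
print.t_ratio_test <- function(x, ...) {
  cat("t-ratio randomization test (", x$randomization_scheme, ", ",
      x$n_randomizations, " randomizations)\n", sep = "")
  cat(sprintf("  t observed = %.4f, null max = %.4f, p = %.3g\n",
              x$t_observed, max(x$t_null), x$p_value))
  invisible(x)
}
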