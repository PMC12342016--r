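# Maximum-volume data-constrained simplex fitting in PC space. Vertices are
# always actual data points (strict data constraint); the optimizer is greedy
# successive volume maximization from random starts followed by
# single-vertex swap hill-climbing, implemented in C++.

# Canonical row order: rows sorted lexicographically, so the fitted vertex
# set is invariant to the input row order at a fixed seed.
canonical_order <- function(points) {
  do.call(order, c(lapply(seq_len(ncol(points)), function(j) points[, j]),
                   list(method = "radix")))
}

#' Volume of a simplex from its vertex coordinates
#'
#' For k vertices in k-1 dimensions this is
#' `|det(v_2 - v_1, ..., v_k - v_1)| / (k-1)!`; in higher ambient dimension
#' the Gram determinant generalization is used.
#'
#' @param vertices k x d matrix, `d >= k - 1`.
#' @return non-negative scalar (zero for degenerate vertex sets).
#' @export
simplex_volume <- function(vertices) {
  if (!is.matrix(vertices)) vertices <- as.matrix(vertices)
  k <- nrow(vertices)
  if (k < 2) stop("a simplex needs at least two vertices")
  if (ncol(vertices) < k - 1)
    stop("k vertices need at least k-1 coordinates")
  A <- sweep(vertices[-1L, , drop = FALSE], 2L, vertices[1L, ])
  if (ncol(A) == k - 1) {
    abs(det(A)) / factorial(k - 1)
  } else {
    g <- det(A %*% t(A))
    sqrt(max(g, 0)) / factorial(k - 1)
  }
}

#' Volume of the convex hull of a point cloud
#'
#' Exact d-dimensional convex hull volume (incremental hull construction).
#' The points must span all d dimensions.
#'
#' @param points n x d numeric matrix.
#' @return positive scalar.
#' @export
hull_volume <- function(points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  storage.mode(points) <- "double"
  .hull_volume_cpp(points)
}

#' Simplex-constrained least-squares mixture weights
#'
#' Each row of `points` is decomposed as the convex combination of the
#' archetypes minimizing the Euclidean residual subject to non-negative
#' weights summing to one. Solved exactly by enumerating weight supports and
#' solving the equality-constrained normal equations on each (k is small).
#'
#' @param points n x d matrix.
#' @param archetypes k x d matrix of vertex positions.
#' @return n x k weight matrix; rows are non-negative and sum to 1.
#' @export
decompose_weights <- function(points, archetypes) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  k <- nrow(archetypes)
  if (ncol(points) != ncol(archetypes))
    stop("points and archetypes must share their coordinate space")
  if (k > 12) stop("support enumeration supports at most 12 archetypes")
  supports <- lapply(seq_len(k), function(m) combn(k, m, simplify = FALSE))
  supports <- unlist(supports, recursive = FALSE)
  G <- archetypes %*% t(archetypes)
  n <- nrow(points)
  W <- matrix(0, n, k)
  Ax <- archetypes %*% t(points)  # k x n
  for (i in seq_len(n)) {
    best_obj <- Inf
    best_w <- NULL
    for (S in supports) {
      m <- length(S)
      if (m == 1) {
        w <- 1
      } else {
        KKT <- rbind(cbind(2 * G[S, S, drop = FALSE], 1), c(rep(1, m), 0))
        rhs <- c(2 * Ax[S, i], 1)
        sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        w <- sol[seq_len(m)]
      }
      if (any(w < -1e-10)) next
      w <- pmax(w, 0); w <- w / sum(w)
      resid <- points[i, ] - drop(crossprod(archetypes[S, , drop = FALSE], w))
      obj <- sum(resid^2)
      if (obj < best_obj - 1e-15) { best_obj <- obj; best_w <- list(S, w) }
    }
    if (is.null(best_w)) stop("degenerate archetypes: weight decomposition failed")
    W[i, best_w[[1]]] <- best_w[[2]]
  }
  rownames(W) <- rownames(points)
  colnames(W) <- paste0("archetype", seq_len(k))
  W
}

#' Explained sample variance of a simplex fit
#'
#' `ESV = 1 - sum(|x_i - w_i A|^2) / sum(|x_i - mean|^2)`: the fraction of
#' total point variance captured by projecting every sample onto the fitted
#' simplex.
#'
#' @param points n x d matrix.
#' @param archetypes k x d vertex matrix.
#' @param weights optional precomputed n x k weights
#'   (from [decompose_weights()]).
#' @return scalar in `[0, 1]` up to numerical error.
#' @export
explained_sample_variance <- function(points, archetypes, weights = NULL) {
  if (!is.matrix(points)) points <- as.matrix(points)
  tot <- sum(sweep(points, 2L, colMeans(points))^2)
  if (tot <= 0) stop("zero total variance: all points identical")
  if (is.null(weights)) weights <- decompose_weights(points, archetypes)
  resid <- points - weights %*% archetypes
  1 - sum(resid^2) / tot
}

#' Fit the maximum-volume data-constrained simplex
#'
#' Selects k data points whose simplex has (locally) maximal volume in the
#' leading `k - 1` coordinates: greedy successive volume maximization from
#' `n_restarts` random starting points, refined by single-vertex swap
#' hill-climbing; ties are broken toward the lowest sample index. Rows are
#' canonicalized (sorted lexicographically) before seeding so the result is
#' invariant to input row order at a fixed seed. Mixture weights and
#' explained sample variance are computed in the full supplied
#' dimensionality.
#'
#' @param points n x d matrix of PC scores (`d >= k - 1`).
#' @param k number of archetypes (>= 2).
#' @param n_restarts random restarts of the greedy stage.
#' @param seed integer seed.
#' @return a `simplex_fit` list: `k`, `archetypes_pc` (k x d),
#'   `archetypes_fit_dims` (k x (k-1)), `vertex_sample_indices`, `weights`,
#'   `esv`, `volume` ((k-1)-dimensional, in the fitting dims), `algorithm`,
#'   `n_restarts`, `seed`.
#' @export
fit_simplex <- function(points, k, n_restarts = 10, seed = 1) {
  if (!is.matrix(points)) points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of samples")
  if (ncol(points) < k - 1)
    stop("need at least k-1 dimensions to embed a k-vertex simplex")
  fit_dims <- seq_len(k - 1)
  pts_fit <- points[, fit_dims, drop = FALSE]
  if (max(apply(pts_fit, 2L, function(col) diff(range(col)))) == 0)
    stop("degenerate input: all points identical in the fitting dimensions")

  ord <- canonical_order(pts_fit)
  set.seed(seed)
  res <- .max_volume_simplex_cpp(pts_fit[ord, , drop = FALSE], as.integer(k),
                                 as.integer(n_restarts))
  if (length(res$indices) < k || res$volume <= 0)
    stop("degenerate geometry: no non-degenerate k-vertex simplex found")
  idx <- sort(ord[res$indices])
  archetypes_pc <- points[idx, , drop = FALSE]
  weights <- decompose_weights(points, archetypes_pc)
  esv <- explained_sample_variance(points, archetypes_pc, weights)
  structure(list(
    k = as.integer(k),
    archetypes_pc = archetypes_pc,
    archetypes_fit_dims = pts_fit[idx, , drop = FALSE],
    vertex_sample_indices = idx,
    weights = weights,
    esv = esv,
    volume = res$volume,
    algorithm = "greedy_volume_max_swap",
    n_restarts = n_restarts,
    seed = seed
  ), class = "simplex_fit")
}

#' @export
print.simplex_fit <- function(x, ...) {
  cat("Data-constrained simplex fit:", x$k, "archetypes (",
      x$algorithm, ")\n")
  cat(sprintf("  explained sample variance: %.4f, simplex volume: %.4g\n",
              x$esv, x$volume))
  cat("  vertex sample indices:", paste(x$vertex_sample_indices, collapse = ", "), "\n")
  invisible(x)
}

# Knee of a monotone curve: the point of maximum perpendicular distance from
# the chord, on whichever side of the chord the knee lies. Shared by
# find_elbow_cutoff (values vs rank) and select_k_elbow (ESV vs k).
chord_elbow <- function(y, tol = 1e-9) {
  m <- length(y)
  x <- (seq_len(m) - 1) / (m - 1)
  ry <- diff(range(y))
  if (ry == 0) return(list(index = 1L, flat = TRUE))
  yn <- (y - min(y)) / ry
  # signed vertical offset from the chord; the perpendicular distance is
  # proportional to it, so the argmax is unchanged by the 45-degree rotation
  above <- yn - (yn[1] + x * (yn[m] - yn[1]))
  if (max(above) > tol) return(list(index = which.max(above), flat = FALSE))
  if (min(above) < -tol) {
    # knee on the far side of the chord: the corner point itself is the
    # first value past the break, so the elbow is the point just before it
    corner <- which.min(above)
    return(list(index = max(corner - 1L, 1L), flat = FALSE))
  }
  list(index = 1L, flat = TRUE)
}

#' Select the number of archetypes by the elbow method
#'
#' Fits a simplex for every k in `k_min:k_max`, builds the explained sample
#' variance (ESV) curve and returns the k at its elbow: the point of maximum
#' distance from the chord joining the curve's endpoints after normalizing
#' both axes to `[0, 1]`. A curve with no pronounced curvature triggers a
#' warning and returns the maximum-distance point anyway.
#'
#' @param points n x d matrix of PC scores.
#' @param k_min,k_max candidate range (fits use the leading `k - 1` of the
#'   supplied dimensions; `k_max - 1` must not exceed `ncol(points)`).
#' @param n_restarts,seed passed to [fit_simplex()] (the same restart seeds
#'   are shared across k so the ESV curve is monotone up to local-optimum
#'   noise).
#' @return the selected k (integer) with attribute `esv_curve`.
#' @export
select_k_elbow <- function(points, k_min = 2, k_max, n_restarts = 10, seed = 1) {
  if (k_max <= k_min) stop("k_max must exceed k_min")
  if (k_max > nrow(points)) stop("k_max exceeds the number of samples")
  ks <- k_min:k_max
  esv <- vapply(ks, function(k)
    fit_simplex(points, k, n_restarts = n_restarts, seed = seed)$esv,
    numeric(1))
  if (any(diff(esv) < -0.05))
    stop("ESV decreased sharply with k: simplex fitting failed")
  el <- chord_elbow(esv)
  if (el$flat)
    warning("ESV curve has no pronounced elbow; returning its maximum-distance point")
  structure(ks[el$index], esv_curve = stats::setNames(esv, paste0("k", ks)))
}

#' Bootstrap uncertainty of archetype positions
#'
#' Resamples samples with replacement, refits the simplex, aligns every
#' replicate's vertices to the reference fit by exact assignment matching,
#' and summarizes positional spread as 95% coverage ellipse areas
#' (`pi * chi2_0.95(2) * sqrt(det(Sigma))`) in each plotted PC plane.
#'
#' @param points n x d matrix of PC scores.
#' @param k number of archetypes.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param n_restarts restarts per replicate fit.
#' @param planes list of length-2 integer vectors: PC planes for the ellipse
#'   areas (defaults to all pairs of the first `min(3, k-1)` dimensions).
#' @return a `bootstrap_archetypes` list: `replicate_archetypes`
#'   (k x d x n_kept array), `ellipse_areas` (k x planes matrix),
#'   `n_boot`, `n_dropped`, `seed`.
#' @export
bootstrap_archetypes <- function(points, k, n_boot = 1000, seed = 1,
                                 n_restarts = 5, planes = NULL) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (!is.matrix(points)) points <- as.matrix(points)
  reference <- fit_simplex(points, k, n_restarts = 10, seed = seed)
  d_fit <- k - 1
  if (is.null(planes)) {
    dd <- min(3, d_fit)
    planes <- if (dd >= 2) combn(dd, 2, simplify = FALSE) else list(c(1L, 1L))
  }
  set.seed(seed)
  n <- nrow(points)
  reps <- array(NA_real_, c(k, ncol(points), n_boot))
  kept <- 0L
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      fit_simplex(points[idx, , drop = FALSE], k, n_restarts = n_restarts,
                  seed = seed + b),
      error = function(e) NULL)
    if (is.null(fb)) { dropped <- dropped + 1L; next }
    perm <- match_archetypes(reference$archetypes_fit_dims, fb$archetypes_fit_dims)
    kept <- kept + 1L
    reps[, , kept] <- fb$archetypes_pc[perm, , drop = FALSE]
  }
  if (dropped > 0)
    message(dropped, " degenerate bootstrap replicate(s) dropped")
  reps <- reps[, , seq_len(kept), drop = FALSE]
  areas <- matrix(NA_real_, k, length(planes))
  colnames(areas) <- vapply(planes, function(pl) paste0("PC", pl[1], "-PC", pl[2]),
                            character(1))
  scale95 <- qchisq(0.95, df = 2)
  for (a in seq_len(k)) {
    for (j in seq_along(planes)) {
      pl <- planes[[j]]
      xy <- t(reps[a, pl, , drop = TRUE])
      if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
      S <- stats::cov(xy)
      areas[a, j] <- pi * scale95 * sqrt(max(det(S), 0))
    }
  }
  structure(list(
    reference = reference,
    replicate_archetypes = reps,
    ellipse_areas = areas,
    n_boot = n_boot, n_kept = kept, n_dropped = dropped, seed = seed
  ), class = "bootstrap_archetypes")
}

#' @export
print.bootstrap_archetypes <- function(x, ...) {
  cat("Archetype position bootstrap:", x$n_kept, "of", x$n_boot,
      "replicates kept\n")
  cat("  mean 95% ellipse area per archetype:\n")
  print(rowMeans(x$ellipse_areas))
  invisible(x)
}
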