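# Back-projection of archetypes to gene space and extraction of
# archetype-defining gene lists. "Coefficients" are the centered gene-space
# reconstruction of each archetype (no mean added), so positive/negative
# means expression above/below the cohort average at that archetype.

#' Gene-space coefficients of fitted archetypes
#'
#' For each archetype, `coefficients = loadings %*% archetype_pc`: the
#' centered reconstruction of the archetype's position in gene space. Adding
#' the PCA means recovers the archetype's expression-space position.
#'
#' @param fit a [fit_simplex()] result.
#' @param pca the [fit_pca()] model the fit's coordinates live in
#'   (`fit` must use at most `pca$d` dimensions).
#' @return a list of `archetype_profile` objects, each with
#'   `archetype_index`, `coefficients` (named per-gene vector) and `order`
#'   (gene indices sorted by coefficient, descending).
#' @export
archetype_gene_coefficients <- function(fit, pca) {
  d <- ncol(fit$archetypes_pc)
  if (d > pca$d)
    stop("fit uses ", d, " dimensions but the PCA model holds ", pca$d)
  L <- pca$loadings[, seq_len(d), drop = FALSE]
  lapply(seq_len(fit$k), function(a) {
    coef <- drop(L %*% fit$archetypes_pc[a, ])
    names(coef) <- rownames(pca$loadings)
    structure(list(
      archetype_index = a,
      coefficients = coef,
      order = order(coef, decreasing = TRUE)
    ), class = "archetype_profile")
  })
}

#' Elbow cutoff of a non-increasing value curve
#'
#' Normalizes rank and value to `[0, 1]` and returns the index of the last
#' value before the curve's knee: the point of maximum perpendicular
#' distance from the chord joining the endpoints, on whichever side of the
#' chord the knee lies (this is where a tangent at -45 degrees touches the
#' normalized curve). Ties return the earliest index; a curve with no
#' curvature beyond `tol` returns index 1 with a warning.
#'
#' @param sorted_values non-increasing numeric vector, length >= 3.
#' @param tol curvature tolerance on the normalized scale.
#' @return integer index into `sorted_values` (1-based; values `1:index` lie
#'   before the knee).
#' @export
find_elbow_cutoff <- function(sorted_values, tol = 1e-9) {
  m <- length(sorted_values)
  if (m < 3) stop("need at least 3 values to locate an elbow")
  if (any(diff(sorted_values) > 0)) stop("values must be non-increasing")
  if (diff(range(sorted_values)) == 0) stop("constant input has no elbow")
  el <- chord_elbow(sorted_values, tol = tol)
  if (el$flat)
    warning("curve is essentially linear; returning the earliest index")
  el$index
}

#' Select positive and negative archetype-defining genes
#'
#' Applies the elbow rule separately to the descending positive coefficient
#' tail and to the magnitude-descending negative tail; genes before each
#' elbow form the lists. Duplicate coefficient values are collapsed before
#' locating the elbow (the cutoff is a coefficient value, so ties enter or
#' leave together).
#'
#' @param profile an `archetype_profile` from
#'   [archetype_gene_coefficients()], or a named coefficient vector.
#' @return a list with `positive_genes`, `negative_genes` (ordered by
#'   |coefficient|, descending), `positive_cutoff`, `negative_cutoff`.
#' @export
select_defining_genes <- function(profile) {
  coef <- if (inherits(profile, "archetype_profile")) profile$coefficients else profile
  if (is.null(names(coef))) stop("coefficients must be named by gene")

  one_tail <- function(mags) {
    # mags: named, positive magnitudes sorted descending
    if (!length(mags)) return(list(genes = character(0), cutoff = NA_real_))
    vals <- unique(unname(mags))
    if (length(vals) < 3) {
      cutoff <- vals[1]
    } else {
      idx <- tryCatch(find_elbow_cutoff(vals),
                      warning = function(w) 1L)
      cutoff <- vals[idx]
    }
    list(genes = names(mags)[mags >= cutoff], cutoff = cutoff)
  }

  pos <- sort(coef[coef > 0], decreasing = TRUE)
  neg <- sort(-coef[coef < 0], decreasing = TRUE)
  pos_sel <- one_tail(pos)
  neg_sel <- one_tail(neg)
  list(
    positive_genes = pos_sel$genes,
    negative_genes = neg_sel$genes,
    positive_cutoff = pos_sel$cutoff,
    negative_cutoff = if (is.na(neg_sel$cutoff)) NA_real_ else -neg_sel$cutoff
  )
}

#' Defining-gene lists for every archetype
#'
#' @param profiles list of `archetype_profile` objects.
#' @return an `archetype_gene_lists` object: one [select_defining_genes()]
#'   entry per archetype.
#' @export
archetype_gene_lists <- function(profiles) {
  out <- lapply(profiles, select_defining_genes)
  names(out) <- paste0("archetype", seq_along(out))
  structure(out, class = "archetype_gene_lists")
}

#' Cross-archetype sharing of defining genes
#'
#' A gene counts as shared when it appears (with either sign) in the lists
#' of at least two archetypes. The ribbon table lists every gene shared by
#' an archetype pair with its sign in each, suitable for circular-plot
#' tools.
#'
#' @param lists an `archetype_gene_lists` object (or plain list with
#'   `positive_genes` / `negative_genes` per archetype).
#' @return an `overlap_summary` list: `n_unique_genes`, `n_shared_genes`,
#'   `shared_fraction`, `pairwise_counts` (symmetric k x k matrix),
#'   `ribbon_table` (data.frame: archetype_a, archetype_b, gene, sign_a,
#'   sign_b).
#' @export
overlap_summary <- function(lists) {
  k <- length(lists)
  per_arch <- lapply(lists, function(l) {
    g <- c(l$positive_genes, l$negative_genes)
    s <- c(rep("positive", length(l$positive_genes)),
           rep("negative", length(l$negative_genes)))
    stats::setNames(s, g)
  })
  all_genes <- unique(unlist(lapply(per_arch, names)))
  n_unique <- length(all_genes)
  count_in <- vapply(all_genes, function(g)
    sum(vapply(per_arch, function(pa) g %in% names(pa), logical(1))), integer(1))
  n_shared <- sum(count_in >= 2)

  pairwise <- matrix(0L, k, k,
                     dimnames = list(names(lists), names(lists)))
  ribbon <- list()
  if (k >= 2) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        common <- intersect(names(per_arch[[a]]), names(per_arch[[b]]))
        pairwise[a, b] <- pairwise[b, a] <- length(common)
        if (length(common))
          ribbon[[length(ribbon) + 1L]] <- data.frame(
            archetype_a = a, archetype_b = b, gene = common,
            sign_a = unname(per_arch[[a]][common]),
            sign_b = unname(per_arch[[b]][common]),
            stringsAsFactors = FALSE)
      }
    }
  }
  ribbon_table <- if (length(ribbon)) do.call(rbind, ribbon) else
    data.frame(archetype_a = integer(0), archetype_b = integer(0),
               gene = character(0), sign_a = character(0),
               sign_b = character(0), stringsAsFactors = FALSE)
  structure(list(
    n_unique_genes = n_unique,
    n_shared_genes = n_shared,
    shared_fraction = if (n_unique > 0) n_shared / n_unique else NA_real_,
    pairwise_counts = pairwise,
    ribbon_table = ribbon_table
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Defining-gene overlap:", x$n_unique_genes, "unique genes,",
      x$n_shared_genes,
      sprintf("(%.0f%%) shared between >=2 archetypes\n",
              100 * x$shared_fraction))
  invisible(x)
}
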