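# Gene-set over-representation (hypergeometric / one-sided Fisher) with
# Benjamini-Hochberg adjustment, and archetype-proximity association tests:
# hypergeometric for discrete attributes, Mann-Whitney for continuous ones.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`), after validating that all p-values lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation of gene sets in a gene list
#'
#' One-sided over-representation test: `p = P(X >= overlap)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set in universe|, n = |list|)`,
#' BH-adjusted across all sets tested for the list. Sets are intersected
#' with the universe before testing; the gene list must be contained in the
#' universe.
#'
#' @param gene_list character vector of genes (e.g. one archetype's
#'   defining genes).
#' @param gene_sets named list as returned by [read_gmt()].
#' @param universe character vector of all candidate genes (typically the
#'   informative genes).
#' @return data.frame: `set_name`, `overlap`, `list_size`, `set_size`,
#'   `universe_size`, `p_raw`, `q_bh`.
#' @export
hypergeometric_enrichment <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("gene list contains genes outside the universe")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set_genes <- intersect(gene_sets[[nm]]$genes, universe)
    K <- length(set_genes)
    ov <- length(intersect(gene_list, set_genes))
    p <- if (n == 0L || K == 0L) 1
    else phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, list_size = n, set_size = K,
               universe_size = N, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out[order(out$p_raw), ]
}

#' Samples closest to an archetype
#'
#' The bin is the `ceiling(bin_fraction * n)` samples with the highest
#' mixture weight on the archetype; ties are broken by sample id so the bin
#' is invariant to row order.
#'
#' @param fit a [fit_simplex()] result.
#' @param archetype_index which archetype.
#' @param bin_fraction fraction of the cohort forming the bin.
#' @param sample_ids optional ids (defaults to the fit's weight rownames).
#' @return list with `bin` and `rest` (character ids, or integer indices if
#'   no ids are available).
#' @export
bin_samples_by_archetype <- function(fit, archetype_index, bin_fraction = 0.1,
                                     sample_ids = NULL) {
  w <- fit$weights[, archetype_index]
  if (is.null(sample_ids)) sample_ids <- rownames(fit$weights)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(w))
  if (bin_fraction <= 0 || bin_fraction > 1)
    stop("bin_fraction must be in (0, 1]")
  n_bin <- ceiling(bin_fraction * length(w))
  ord <- order(-w, sample_ids)
  list(bin = sample_ids[ord[seq_len(n_bin)]],
       rest = sample_ids[ord[-seq_len(n_bin)]])
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments
# (symmetric deviation of U from its null mean; handles ties through
# midranks). Used when the combined sample is small.
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sel <- combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Discrete attribute association with archetype proximity
#'
#' For each archetype and each category of the label, tests hypergeometric
#' over-representation of the category inside the archetype's bin relative
#' to the non-missing cohort; `effect` is the fold enrichment
#' (bin prevalence / cohort prevalence). BH adjustment runs across all
#' archetype x category tests.
#'
#' @param fit a [fit_simplex()] result.
#' @param labels factor or character vector of per-sample categories, named
#'   by sample id or aligned with the fit's samples; missing values are
#'   dropped test-wise.
#' @param bin_fraction fraction of samples forming each archetype's bin.
#' @return data.frame: `archetype_index`, `attribute`, `kind`, `category`,
#'   `n_bin`, `n_rest`, `overlap`, `effect`, `p_raw`, `q_bh`.
#' @export
attribute_discrete <- function(fit, labels, bin_fraction = 0.1) {
  ids <- rownames(fit$weights)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fit$weights)))
  labels <- align_attribute(labels, ids)
  keep <- !is.na(labels)
  cats <- sort(unique(as.character(labels[keep])))
  rows <- list()
  for (a in seq_len(fit$k)) {
    bins <- bin_samples_by_archetype(fit, a, bin_fraction, sample_ids = ids)
    bin <- intersect(bins$bin, ids[keep])
    rest <- intersect(bins$rest, ids[keep])
    N <- length(bin) + length(rest)
    for (cc in cats) {
      K <- sum(as.character(labels[keep]) == cc)
      ov <- sum(as.character(labels[bin]) == cc)
      p <- if (K == 0L || length(bin) == 0L) 1
      else phyper(ov - 1, K, N - K, length(bin), lower.tail = FALSE)
      prev_bin <- if (length(bin)) ov / length(bin) else 0
      prev_all <- K / N
      rows[[length(rows) + 1L]] <- data.frame(
        archetype_index = a, attribute = "label", kind = "discrete",
        category = cc, n_bin = length(bin), n_rest = length(rest),
        overlap = ov,
        effect = if (prev_all > 0) prev_bin / prev_all else NA_real_,
        p_raw = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out
}

#' Continuous attribute association with archetype proximity
#'
#' Two-sided Mann-Whitney comparison of the attribute between each
#' archetype's bin and the remaining samples (missing values dropped);
#' `effect` is `median(bin) - median(rest)` in the attribute's units. The
#' exact enumeration null is used when the combined non-missing sample has
#' at most `exact_max` observations, otherwise the normal approximation
#' with tie correction. BH adjustment runs across archetypes.
#'
#' @param fit a [fit_simplex()] result.
#' @param values numeric vector, named by sample id or aligned with the
#'   fit's samples.
#' @param bin_fraction fraction of samples forming each archetype's bin.
#' @param attribute attribute name echoed in the output.
#' @param exact_max largest combined sample size for the enumeration null.
#' @return data.frame: `archetype_index`, `attribute`, `kind`, `n_bin`,
#'   `n_rest`, `effect`, `p_raw`, `q_bh`.
#' @export
attribute_continuous <- function(fit, values, bin_fraction = 0.1,
                                 attribute = "covariate", exact_max = 20) {
  ids <- rownames(fit$weights)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fit$weights)))
  values <- align_attribute(values, ids, numeric = TRUE)
  rows <- list()
  for (a in seq_len(fit$k)) {
    bins <- bin_samples_by_archetype(fit, a, bin_fraction, sample_ids = ids)
    vb <- values[bins$bin]; vb <- vb[!is.na(vb)]
    vr <- values[bins$rest]; vr <- vr[!is.na(vr)]
    if (!length(vb) || !length(vr)) {
      p <- 1; eff <- NA_real_
    } else if (length(vb) + length(vr) <= exact_max) {
      p <- mann_whitney_exact(vb, vr)
      eff <- median(vb) - median(vr)
    } else {
      p <- suppressWarnings(
        wilcox.test(vb, vr, alternative = "two.sided", exact = FALSE,
                    correct = TRUE)$p.value)
      if (!is.finite(p)) p <- 1
      eff <- median(vb) - median(vr)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      archetype_index = a, attribute = attribute, kind = "continuous",
      n_bin = length(vb), n_rest = length(vr), effect = eff,
      p_raw = min(p, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out
}

# Align a per-sample attribute vector with the fit's sample ids: use names
# if present, positions otherwise.
align_attribute <- function(v, ids, numeric = FALSE) {
  if (!is.null(names(v))) {
    out <- v[ids]
  } else {
    if (length(v) != length(ids))
      stop("attribute vector has no names and its length differs from the cohort")
    out <- v
  }
  names(out) <- ids
  if (numeric) out <- as.numeric(stats::setNames(out, ids))
  names(out) <- ids
  out
}
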