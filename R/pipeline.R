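# End-to-end orchestration: filter -> PCA validation -> PCA -> k selection ->
# simplex fit -> t-ratio -> bootstrap -> gene selection -> overlap ->
# enrichment -> attribute tests. Every stochastic stage derives its seed
# deterministically from the master seed, so identical inputs and config
# yield identical reports.

stage_seed <- function(seed, stage) {
  offsets <- c(pca_validation = 1L, k_select = 2L, fit = 3L, t_ratio = 4L,
               bootstrap = 5L)
  seed * 100L + offsets[[stage]]
}

#' Run the full Pareto task inference pipeline
#'
#' @param expr samples x genes expression matrix (or a path readable by
#'   [read_expression_matrix()]).
#' @param gene_sets optional gene sets ([read_gmt()] list or a GMT path) for
#'   enrichment of the defining-gene lists.
#' @param labels optional discrete per-sample attribute (vector named by
#'   sample id).
#' @param covariates optional named list of continuous per-sample attributes.
#' @param sd_min,var_min informative-gene filter thresholds (TPM).
#' @param dims number of PCs retained for ESV and gene coefficients
#'   (capped at the matrix rank).
#' @param k number of archetypes, or `"auto"` for elbow selection.
#' @param k_max upper bound of the elbow search when `k = "auto"`.
#' @param n_restarts simplex-fit restarts.
#' @param n_perm PCA-validation permutations (0 skips the stage).
#' @param n_rand t-ratio randomizations (0 skips the stage).
#' @param n_boot bootstrap replicates for archetype uncertainty
#'   (0 skips the stage).
#' @param bin_fraction attribute-test bin fraction.
#' @param alpha significance level used by the PCA validation.
#' @param scheme t-ratio randomization scheme.
#' @param seed master seed.
#' @return a `pareto_run` list with one element per stage (`filter`,
#'   `pca_validation`, `pca`, `k`, `fit`, `t_ratio`, `bootstrap`,
#'   `profiles`, `gene_lists`, `overlap`, `enrichment`, `attributes`),
#'   plus `config` and per-stage wall times.
#' @export
run_pipeline <- function(expr, gene_sets = NULL, labels = NULL,
                         covariates = NULL,
                         sd_min = 1, var_min = 1, dims = 8,
                         k = "auto", k_max = 8, n_restarts = 10,
                         n_perm = 100, n_rand = 1000, n_boot = 1000,
                         bin_fraction = 0.1, alpha = 0.05,
                         scheme = c("shuffle_genes_then_pca", "shuffle_pc_columns"),
                         seed = 1) {
  scheme <- match.arg(scheme)
  config <- list(sd_min = sd_min, var_min = var_min, dims = dims, k = k,
                 k_max = k_max, n_restarts = n_restarts, n_perm = n_perm,
                 n_rand = n_rand, n_boot = n_boot,
                 bin_fraction = bin_fraction, alpha = alpha, scheme = scheme,
                 seed = seed)
  report <- list(config = config, timings = c(),
                 version = as.character(utils::packageVersion("paretoscope")))
  tic <- function() proc.time()[["elapsed"]]
  record <- function(stage, t0) {
    report$timings[stage] <<- proc.time()[["elapsed"]] - t0
  }
  run_stage <- function(stage, code) {
    t0 <- tic()
    out <- tryCatch(code, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    record(stage, t0)
    out
  }

  if (is.character(expr)) expr <- read_expression_matrix(expr)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)

  filtered <- run_stage("filter",
    filter_informative_genes(expr, sd_min = sd_min, var_min = var_min))
  report$filter <- list(n_genes_in = ncol(expr), n_genes_kept = ncol(filtered))

  if (n_perm > 0)
    report$pca_validation <- run_stage("pca_validation",
      pca_permutation_test(filtered, n_perm = n_perm,
                           seed = stage_seed(seed, "pca_validation"),
                           alpha = alpha))

  d_use <- min(dims, nrow(filtered) - 1L, ncol(filtered))
  pca <- run_stage("pca", fit_pca(filtered, d_use))
  report$pca <- pca

  if (identical(k, "auto")) {
    k_hi <- min(k_max, d_use + 1L, nrow(filtered))
    k_sel <- run_stage("k_select",
      select_k_elbow(pca$scores, k_min = 2, k_max = k_hi,
                     n_restarts = n_restarts,
                     seed = stage_seed(seed, "k_select")))
    report$esv_curve <- attr(k_sel, "esv_curve")
    k <- as.integer(k_sel)
  }
  report$k <- as.integer(k)

  fit <- run_stage("fit",
    fit_simplex(pca$scores, report$k, n_restarts = n_restarts,
                seed = stage_seed(seed, "fit")))
  report$fit <- fit

  if (n_rand > 0) {
    x_or_points <- if (scheme == "shuffle_genes_then_pca") filtered else pca$scores
    report$t_ratio <- run_stage("t_ratio",
      t_ratio_test(x_or_points, report$k, n_rand = n_rand, scheme = scheme,
                   seed = stage_seed(seed, "t_ratio"),
                   n_restarts = n_restarts,
                   fit = if (scheme == "shuffle_pc_columns") fit else NULL))
  }

  if (n_boot > 0)
    report$bootstrap <- run_stage("bootstrap",
      bootstrap_archetypes(pca$scores, report$k, n_boot = n_boot,
                           seed = stage_seed(seed, "bootstrap")))

  profiles <- run_stage("genes", archetype_gene_coefficients(fit, pca))
  report$profiles <- profiles
  report$gene_lists <- archetype_gene_lists(profiles)
  report$overlap <- overlap_summary(report$gene_lists)

  if (!is.null(gene_sets)) {
    universe <- colnames(filtered)
    report$enrichment <- run_stage("enrichment", {
      res <- list()
      for (a in seq_len(report$k)) {
        for (sgn in c("positive", "negative")) {
          gl <- report$gene_lists[[a]][[paste0(sgn, "_genes")]]
          if (!length(gl)) next
          tab <- hypergeometric_enrichment(gl, gene_sets, universe)
          tab$archetype_index <- a
          tab$list_sign <- sgn
          res[[length(res) + 1L]] <- tab
        }
      }
      if (length(res)) do.call(rbind, res) else NULL
    })
  }

  attr_tabs <- list()
  if (!is.null(labels))
    attr_tabs$discrete <- run_stage("attributes_discrete",
      attribute_discrete(fit, labels, bin_fraction = bin_fraction))
  if (!is.null(covariates)) {
    cont <- lapply(names(covariates), function(nm)
      attribute_continuous(fit, covariates[[nm]],
                           bin_fraction = bin_fraction, attribute = nm))
    if (length(cont)) {
      tab <- do.call(rbind, cont)
      tab$q_bh <- bh_adjust(tab$p_raw)  # BH across archetypes x attributes
      attr_tabs$continuous <- tab
    }
  }
  if (length(attr_tabs)) report$attributes <- attr_tabs

  class(report) <- "pareto_run"
  report
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file may contain `matrix`, `gmt`, `attributes` (file paths),
#' any [run_pipeline()] parameter, and `declared_types` for the attribute
#' table.
#'
#' @param path path to the YAML config.
#' @return a `pareto_run` report.
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$matrix)) stop("config must name an expression 'matrix' file")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
  expr <- read_expression_matrix(resolve(cfg$matrix),
                                 orientation = cfg$orientation %||% "samples_by_genes")
  gene_sets <- if (!is.null(cfg$gmt)) read_gmt(resolve(cfg$gmt)) else NULL
  labels <- NULL; covariates <- NULL
  if (!is.null(cfg$attributes)) {
    at <- read_attributes(resolve(cfg$attributes), sample_ids = rownames(expr),
                          declared_types = cfg$declared_types)
    if (ncol(at$discrete) >= 1)
      labels <- stats::setNames(at$discrete[[1L]], at$sample_ids)
    if (ncol(at$continuous) >= 1)
      covariates <- lapply(at$continuous, function(v)
        stats::setNames(v, at$sample_ids))
  }
  pass <- intersect(names(cfg),
                    c("sd_min", "var_min", "dims", "k", "k_max", "n_restarts",
                      "n_perm", "n_rand", "n_boot", "bin_fraction", "alpha",
                      "scheme", "seed"))
  do.call(run_pipeline, c(list(expr = expr, gene_sets = gene_sets,
                               labels = labels, covariates = covariates),
                          cfg[pass]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pareto_run <- function(x, ...) {
  cat("Pareto task inference run (seed ", x$config$seed, ")\n", sep = "")
  cat("  informative genes:", x$filter$n_genes_kept, "of", x$filter$n_genes_in, "\n")
  if (!is.null(x$pca_validation))
    cat(sprintf("  PCA validation: Psi = %.3f (p = %.3g), phi = %.3f (p = %.3g)\n",
                x$pca_validation$psi_observed, x$pca_validation$p_psi,
                x$pca_validation$phi_observed, x$pca_validation$p_phi))
  cat(sprintf("  %d PCs explain %.1f%% of variance\n", x$pca$d,
              100 * sum(x$pca$explained_fraction)))
  cat("  archetypes: k =", x$k,
      sprintf("(ESV = %.3f)\n", x$fit$esv))
  if (!is.null(x$t_ratio))
    cat(sprintf("  t-ratio = %.3f, p = %.3g (%s)\n", x$t_ratio$t_observed,
                x$t_ratio$p_value, x$t_ratio$randomization_scheme))
  cat(sprintf("  defining genes: %d unique, %d (%.0f%%) shared\n",
              x$overlap$n_unique_genes, x$overlap$n_shared_genes,
              100 * x$overlap$shared_fraction))
  invisible(x)
}
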