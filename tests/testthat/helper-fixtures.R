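# Shared fixtures, built in code and cached per test run.

default_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_pareto_data(synthetic_config(seed = 1))
    cache
  }
})

# Filtered matrix + 3-PC model + k=4 fit of the default synthetic dataset
default_fit_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- default_truth()
      expr <- filter_informative_genes(truth$expression)
      pca <- fit_pca(expr, 3)
      fit <- fit_simplex(pca$scores, 4, seed = 1)
      cache <<- list(truth = truth, expr = expr, pca = pca, fit = fit)
    }
    cache
  }
})

# Tiny expression matrix with known structure for the IO tests
tiny_matrix <- function() {
  m <- matrix(c(1.5, 0, 2.25,
                3, 1, 0.5,
                2, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("gA", "gB", "gC")))
  m
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
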