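# Readers and validators for expression matrices, GMT gene sets and sample
# attribute tables. Matrices are plain numeric matrices oriented samples x
# genes with rownames = sample ids and colnames = gene ids.

#' Validate an expression matrix
#'
#' Checks the container contract: a numeric samples x genes matrix with
#' unique row (sample) and column (gene) identifiers, all entries finite and
#' non-negative.
#'
#' @param x numeric matrix, samples in rows, genes in columns, with dimnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry sample ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (any(x < 0))
    stop("expression values must be non-negative (TPM-like)")
  invisible(x)
}

#' Read an expression matrix from a TSV file
#'
#' Expects one header row and one leading label column; the body must be
#' numeric. Gzip-compressed files are read transparently. The result is
#' always oriented samples x genes, regardless of how the file is stored.
#'
#' @param path path to a tab-separated file (optionally `.gz`).
#' @param orientation `"samples_by_genes"` if rows of the file are samples
#'   (the default), `"genes_by_samples"` if rows are genes.
#' @return a validated numeric matrix, samples x genes.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_by_genes", "genes_by_samples")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) stop("expected a label column plus at least one data column in ", path)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]  # before subsetting, which repairs duplicates
  body <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(body) <- col_ids
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  # values literally written as NA are also parse failures for a numeric body
  bad_na <- which(is.na(body), arr.ind = TRUE)
  if (nrow(bad_na)) bad <- rbind(bad, bad_na)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value %s at row '%s', column '%s' in %s",
                 dQuote(body[bad[1, 1], bad[1, 2]]),
                 row_ids[bad[1, 1]], colnames(body)[bad[1, 2]], path))
  }
  dimnames(num) <- list(row_ids, colnames(body))
  if (orientation == "genes_by_samples") num <- t(num)
  validate_expression(num)
  num
}

#' Write an expression matrix to a TSV file
#'
#' Inverse of [read_expression_matrix()] at full precision
#' (values are printed with 17 significant digits).
#'
#' @param x samples x genes numeric matrix with dimnames.
#' @param path output path; a `.gz` suffix writes gzip-compressed output.
#' @param label header name of the leading sample-id column.
#' @export
write_expression_matrix <- function(x, path, label = "sample_id") {
  validate_expression(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(label, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Keep informative genes
#'
#' Retains genes whose across-sample standard deviation and variance both meet
#' their thresholds (both criteria are evaluated, even though for the default
#' thresholds of 1 TPM the standard-deviation rule alone decides). Standard
#' deviation uses the n-1 denominator. Gene order and the sample axis are
#' unchanged.
#'
#' @param x samples x genes matrix.
#' @param sd_min minimum across-sample standard deviation (TPM).
#' @param var_min minimum across-sample variance (TPM^2).
#' @return the filtered matrix.
#' @export
filter_informative_genes <- function(x, sd_min = 1, var_min = 1) {
  validate_expression(x)
  v <- apply(x, 2L, var)
  s <- sqrt(v)
  keep <- (s >= sd_min) & (v >= var_min)
  if (!any(keep))
    stop("no gene passes the informative-gene filter (sd >= ", sd_min,
         " and variance >= ", var_min, ")")
  x[, keep, drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member genes. Gzip input is accepted.
#'
#' @param path path to the GMT file.
#' @return a named list; each element has `description` and `genes`.
#' @export
read_gmt <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set '", fields[1L], "' is empty")
    if (fields[1L] %in% names(sets))
      stop("duplicate GMT set name: ", fields[1L])
    sets[[fields[1L]]] <- list(description = fields[2L], genes = genes)
  }
  if (!length(sets)) stop("no gene sets found in ", path)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-attribute table
#'
#' TSV with a `sample_id` column; remaining columns are typed by
#' `declared_types` (named character vector with values `"discrete"` or
#' `"continuous"`); undeclared columns default to continuous when every
#' non-missing value parses as a number, otherwise discrete. Rows for samples
#' absent from `sample_ids` are dropped with a warning. Missing values
#' (empty or `NA`) are preserved and excluded test-wise downstream.
#'
#' @param path path to the TSV file (optionally gzipped).
#' @param sample_ids optional character vector of expected sample ids.
#' @param declared_types optional named character vector of column types.
#' @return a list with `sample_ids`, `discrete` (data.frame of factors) and
#'   `continuous` (data.frame of numerics), each with one row per sample.
#' @export
read_attributes <- function(path, sample_ids = NULL, declared_types = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (!"sample_id" %in% colnames(tab))
    stop("attribute table must contain a 'sample_id' column")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in attribute table")
  if (!is.null(sample_ids)) {
    missing_rows <- !(tab$sample_id %in% sample_ids)
    if (any(missing_rows)) {
      warning(sum(missing_rows),
              " attribute row(s) refer to samples absent from the expression matrix; dropped")
      tab <- tab[!missing_rows, , drop = FALSE]
    }
  }
  ids <- tab$sample_id
  cols <- setdiff(colnames(tab), "sample_id")
  discrete <- list()
  continuous <- list()
  for (cn in cols) {
    vals <- tab[[cn]]
    vals[!nzchar(vals) | vals == "NA"] <- NA
    declared <- if (!is.null(declared_types) && cn %in% names(declared_types))
      declared_types[[cn]] else NA
    num <- suppressWarnings(as.numeric(vals))
    numeric_ok <- all(is.na(vals) | !is.na(num))
    type <- if (!is.na(declared)) declared else if (numeric_ok) "continuous" else "discrete"
    if (type == "continuous") {
      if (!numeric_ok)
        stop("column '", cn, "' declared continuous but contains non-numeric values")
      if (any(!is.na(num) & !is.finite(num)))
        stop("column '", cn, "' contains non-finite values")
      continuous[[cn]] <- num
    } else {
      discrete[[cn]] <- factor(vals)
    }
  }
  structure(list(
    sample_ids = ids,
    discrete = as.data.frame(discrete, optional = TRUE, stringsAsFactors = FALSE),
    continuous = as.data.frame(continuous, optional = TRUE)
  ), class = "attribute_table")
}
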