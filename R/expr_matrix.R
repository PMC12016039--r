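#' Construct an expression matrix
#'
#' The package's universal data container: a dense numeric matrix of genes
#' (rows) by observations (columns, either bulk samples or single cells),
#' carrying a `value_kind` attribute that records where the matrix sits in the
#' transformation chain: `"raw"` (non-negative input units such as FPKM, TPM,
#' RSEM counts or microarray intensities), `"log2"` (after `log2_shift()`), or
#' `"zscore"` (after `zscore_per_observation()`).
#'
#' @param values numeric matrix, genes x observations.
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   `rownames(values)`).
#' @param obs_ids character vector of unique sample or cell identifiers
#'   (defaults to `colnames(values)`).
#' @param value_kind one of `"raw"`, `"log2"`, `"zscore"`.
#' @return a numeric matrix with dimnames and a `value_kind` attribute.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        obs_ids = colnames(values),
                        value_kind = c("raw", "log2", "zscore")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop("expression matrix requires gene and observation identifiers",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("number of gene ids (", length(gene_ids),
         ") does not match number of rows (", nrow(values), ")", call. = FALSE)
  }
  if (length(obs_ids) != ncol(values)) {
    stop("number of observation ids (", length(obs_ids),
         ") does not match number of columns (", ncol(values), ")",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(obs_ids)) {
    stop("duplicate observation ids: ",
         paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, obs_ids)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (value_kind == "raw" && any(values < 0)) {
    stop("raw expression values must be non-negative; found minimum ",
         format(min(values)), call. = FALSE)
  }
  attr(values, "value_kind") <- value_kind
  values
}

#' Value kind of an expression matrix
#'
#' @param x an expression matrix built by [expr_matrix()].
#' @return `"raw"`, `"log2"` or `"zscore"` (assumed `"raw"` when unset).
#' @export
value_kind <- function(x) {
  vk <- attr(x, "value_kind")
  if (is.null(vk)) "raw" else vk
}

# internal: re-tag a derived matrix, keeping dimnames
set_value_kind <- function(x, kind) {
  attr(x, "value_kind") <- kind
  x
}

# internal: check the matrix is at the expected point in the chain
stop_unless_kind <- function(x, kind, what) {
  if (!identical(value_kind(x), kind)) {
    stop(what, " expects a ", kind, " matrix, got value_kind=", value_kind(x),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a labeled cohort
#'
#' Pairs an expression matrix with one MSI/MSS label per observation. The
#' label vector is matched to the matrix columns by name; every column must be
#' labeled and every label must correspond to a column.
#'
#' @param matrix an expression matrix (see [expr_matrix()]).
#' @param labels named character vector (names = observation ids, values in
#'   `"MSI"`/`"MSS"`), or an unnamed vector aligned with the matrix columns.
#' @return an object of class `msi_cohort`: list with elements `matrix` and
#'   `labels` (character vector aligned with `colnames(matrix)`).
#' @export
msi_cohort <- function(matrix, labels) {
  labels <- normalize_status(labels)
  if (is.null(names(labels))) {
    if (length(labels) != ncol(matrix)) {
      stop("unnamed labels must align with matrix columns", call. = FALSE)
    }
    names(labels) <- colnames(matrix)
  }
  missing <- setdiff(colnames(matrix), names(labels))
  if (length(missing)) {
    stop("no label for observation(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  labels <- labels[colnames(matrix)]
  structure(list(matrix = matrix, labels = labels), class = "msi_cohort")
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat("msi_cohort: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", sum(x$labels == "MSI"), " MSI / ",
      sum(x$labels == "MSS"), " MSS), value_kind=", value_kind(x$matrix),
      "\n", sep = "")
  invisible(x)
}

# internal: MSI-H is a clinical synonym for MSI; anything else is rejected
normalize_status <- function(status) {
  nm <- names(status)
  status <- toupper(trimws(as.character(status)))
  status[status == "MSI-H"] <- "MSI"
  bad <- setdiff(unique(status), c("MSI", "MSS"))
  if (length(bad)) {
    stop("unknown MSI status value(s): ", paste(bad, collapse = ", "),
         " (expected MSI, MSI-H or MSS)", call. = FALSE)
  }
  names(status) <- nm
  status
}

# internal: class counts used by selection and training; requires both classes
cohort_counts <- function(cohort) {
  m <- length(cohort$labels)
  n <- sum(cohort$labels == "MSI")
  if (n == 0L || n == m) {
    stop("cohort must contain both MSI and MSS samples (got ", n, " MSI of ",
         m, ")", call. = FALSE)
  }
  list(m = m, n = n)
}

# internal: restrict a cohort to a gene subset, preserving label pairing
subset_cohort_genes <- function(cohort, gene_ids) {
  mat <- cohort$matrix[gene_ids, , drop = FALSE]
  attr(mat, "value_kind") <- value_kind(cohort$matrix)
  structure(list(matrix = mat, labels = cohort$labels), class = "msi_cohort")
}
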