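#' Read an expression matrix
#'
#' Reads a dense TSV/CSV matrix (first column = gene symbol, first row =
#' observation ids) or a MatrixMarket triplet file with `genes.tsv` /
#' `barcodes.tsv` sidecars in the same directory. Values are validated as raw
#' (finite, non-negative) expression. Duplicate gene symbols — common when
#' microarray probes map many-to-one — are collapsed by keeping the row with
#' the highest mean (a message reports how many were dropped).
#'
#' @param path path to the matrix file (`.mtx` for MatrixMarket).
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param orientation `"genes_by_obs"` (default) or `"obs_by_genes"`; the
#'   latter transposes on read so the result is always genes x observations.
#' @return a raw expression matrix (see [expr_matrix()]).
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        orientation = c("genes_by_obs", "obs_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)

  if (format == "mtx") {
    values <- read_mtx_triplet(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    # validate the header up front: read.table silently mangles duplicates
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    head_lines <- head_lines[!grepl("^\\s*#", head_lines) & nzchar(head_lines)]
    if (!length(head_lines)) {
      stop("malformed header in ", path, ": no header line found",
           call. = FALSE)
    }
    hdr <- strsplit(head_lines[1L], sep, fixed = TRUE)[[1L]][-1L]
    if (anyDuplicated(hdr)) {
      stop("duplicate observation ids in ", path, ": ",
           paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
           call. = FALSE)
    }
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) {
      stop("malformed header in ", path,
           ": expected a gene column plus at least one observation column",
           call. = FALSE)
    }
    ids <- as.character(df[[1L]])
    num <- df[-1L]
    nonnum <- !vapply(num, is.numeric, logical(1))
    if (any(nonnum)) {
      stop("parse error in ", path, ": non-numeric values in column(s) ",
           paste(names(num)[nonnum], collapse = ", "), call. = FALSE)
    }
    values <- as.matrix(num)
    rownames(values) <- ids
  }

  if (orientation == "obs_by_genes") values <- t(values)
  values <- collapse_duplicate_genes(values)
  expr_matrix(values, value_kind = "raw")
}

# internal: extension-based format guess
guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", txt = "tsv", tab = "tsv",
         csv = "csv",
         mtx = "mtx",
         stop("cannot infer matrix format from extension '.", ext,
              "'; pass format= explicitly", call. = FALSE))
}

# internal: MatrixMarket coordinate file + genes.tsv/barcodes.tsv sidecars,
# genes as rows, 1-based indices (the dominant single-cell convention)
read_mtx_triplet <- function(path) {
  dir <- dirname(path)
  genes_path <- file.path(dir, "genes.tsv")
  barcodes_path <- file.path(dir, "barcodes.tsv")
  for (p in c(genes_path, barcodes_path)) {
    if (!file.exists(p)) {
      stop("missing MTX sidecar file: ", p, call. = FALSE)
    }
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    stop("MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecars (", length(genes), " genes, ",
         length(barcodes), " barcodes)", call. = FALSE)
  }
  dimnames(m) <- list(as.character(genes), as.character(barcodes))
  m
}

# internal: keep the highest-mean row among rows sharing a gene symbol
collapse_duplicate_genes <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  means <- rowMeans(values)
  keep <- unlist(lapply(split(seq_along(ids), ids), function(idx) {
    idx[which.max(means[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  message("collapsed ", length(ids) - length(keep),
          " duplicate gene row(s), keeping the highest-mean row per symbol")
  values[keep, , drop = FALSE]
}

#' Read an MSI/MSS label file
#'
#' Two-column delimited file (no header): observation id, status. `MSI-H` is
#' normalized to `MSI`. Lines starting with `#` are ignored.
#'
#' @param path path to the label file (tab- or comma-delimited).
#' @return named character vector, values in `"MSI"`/`"MSS"`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("label file ", path, " contains no labels",
                           call. = FALSE)
  parts <- strsplit(lines, "[\t,]")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[1L],
         ": expected two delimited columns", call. = FALSE)
  }
  ids <- trimws(vapply(parts, `[[`, character(1), 1L))
  status <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(normalize_status(status), ids)
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]: writes TSV/CSV with a `gene` first column, or a
#' MatrixMarket file plus `genes.tsv`/`barcodes.tsv` sidecars. Numeric text is
#' written at full double precision so a read-back reproduces the matrix to at
#' least 10 significant digits.
#'
#' @param matrix an expression matrix.
#' @param path output path (`.mtx` target directory must exist).
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @export
write_matrix <- function(matrix, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(unclass_matrix(matrix), sparse = TRUE), path)
    writeLines(rownames(matrix), file.path(dir, "genes.tsv"))
    writeLines(colnames(matrix), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(matrix),
                     format(unclass_matrix(matrix), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", colnames(matrix))
    ok <- tryCatch({
      utils::write.table(df, path, sep = sep, quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

# internal: drop the value_kind attribute for numeric work
unclass_matrix <- function(x) {
  attr(x, "value_kind") <- NULL
  x
}

#' Write MSI prediction results as TSV
#'
#' @param results data.frame with columns sample_id, msi_score, msi_status.
#' @param path output path.
#' @param header_lines optional provenance lines, written prefixed with `#`.
#' @export
write_predictions <- function(results, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
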