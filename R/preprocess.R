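#' Preprocessing recipe
#'
#' Parameters of the transformation chain applied before scoring. Bulk samples
#' go through `log2_shift()` then `zscore_per_observation()`; single-cell
#' samples are first quality-filtered (`cell_qc_filter()`) and dropout-imputed
#' (`impute_dropouts()`).
#'
#' @param do_log2,do_zscore logical; apply the log2(x+1) transform and the
#'   per-observation standardization (both on by default).
#' @param sc_min_detected_fraction minimum fraction of genes detected
#'   (value > 0) for a cell to count as high quality; default 0.20.
#' @param sc_min_cells if fewer than this many cells pass, fall back to the
#'   top cells by detected fraction; default 20.
#' @return an object of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(do_log2 = TRUE, do_zscore = TRUE,
                              sc_min_detected_fraction = 0.20,
                              sc_min_cells = 20L) {
  if (sc_min_detected_fraction < 0 || sc_min_detected_fraction > 1) {
    stop("sc_min_detected_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (sc_min_cells < 1L) stop("sc_min_cells must be >= 1", call. = FALSE)
  structure(list(do_log2 = isTRUE(do_log2), do_zscore = isTRUE(do_zscore),
                 sc_min_detected_fraction = sc_min_detected_fraction,
                 sc_min_cells = as.integer(sc_min_cells)),
            class = "preprocess_recipe")
}

#' Shifted log2 transform
#'
#' Adds 1 to every raw expression value and takes log2, the standard
#' variance-stabilizing step for FPKM/TPM-like input.
#'
#' @param matrix a raw expression matrix.
#' @return the matrix with `value_kind = "log2"`.
#' @export
log2_shift <- function(matrix) {
  stop_unless_kind(matrix, "raw", "log2_shift")
  set_value_kind(log2(unclass_matrix(matrix) + 1), "log2")
}

#' Per-observation standardization
#'
#' Centers and scales each observation (column) to mean 0 and population
#' standard deviation 1, so every sample's expression profile follows the same
#' scale regardless of platform. Zero-variance columns are mapped to all-zero
#' with a warning.
#'
#' @param matrix a log2 expression matrix with at least 2 genes.
#' @return the matrix with `value_kind = "zscore"`.
#' @export
zscore_per_observation <- function(matrix) {
  stop_unless_kind(matrix, "log2", "zscore_per_observation")
  if (nrow(matrix) < 2L) {
    stop("standardization needs at least 2 genes per observation",
         call. = FALSE)
  }
  x <- unclass_matrix(matrix)
  mu <- colMeans(x)
  centered <- sweep(x, 2L, mu)
  # population sd: divisor = number of genes, so the sd-equals-1 postcondition
  # holds exactly
  sds <- sqrt(colMeans(centered^2))
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance observation(s) mapped to all-zero z-scores: ",
            paste(utils::head(colnames(x)[flat], 5), collapse = ", "),
            call. = FALSE)
    sds[flat] <- 1
  }
  set_value_kind(sweep(centered, 2L, sds, "/"), "zscore")
}

#' Single-cell quality filter
#'
#' Keeps high-quality cells, defined as cells in which at least
#' `sc_min_detected_fraction` of genes are detected (expression > 0). If fewer
#' than `sc_min_cells` cells pass, all cells are ranked by detected fraction
#' (descending, stable in original column order) and the top
#' `min(sc_min_cells, n_cells)` are kept instead. Kept cells retain their
#' original column order.
#'
#' @param cells raw expression matrix whose columns are the cells of one
#'   sample.
#' @param recipe a [preprocess_recipe()].
#' @return the column subset of `cells` that passes QC.
#' @export
cell_qc_filter <- function(cells, recipe = preprocess_recipe()) {
  stop_unless_kind(cells, "raw", "cell_qc_filter")
  if (ncol(cells) == 0L) stop("no cells to filter", call. = FALSE)
  frac <- colMeans(unclass_matrix(cells) > 0)
  pass <- frac >= recipe$sc_min_detected_fraction
  if (sum(pass) >= recipe$sc_min_cells) {
    keep <- which(pass)
  } else {
    k <- min(recipe$sc_min_cells, ncol(cells))
    keep <- sort(order(-frac, seq_along(frac))[seq_len(k)])
  }
  out <- cells[, keep, drop = FALSE]
  set_value_kind(out, "raw")
}

#' Impute single-cell dropouts
#'
#' Replaces zeros (dropouts) in each cell by the average expression of that
#' cell's detected genes, the simple mean-substitution rule used ahead of the
#' log2/z-score chain. Two interpretation flags are exposed because the rule
#' is ambiguous in the general description: `mean_of` chooses whether the
#' average includes the zeros being replaced, and `per` chooses whether the
#' average is taken within the cell (default) or per gene across all cells of
#' the sample.
#'
#' @param cells raw expression matrix (columns = cells).
#' @param mean_of `"nonzero"` (default: mean of detected values) or `"all"`.
#' @param per `"cell"` (default) or `"sample"` (per-gene mean across cells).
#' @return the matrix with zeros imputed; nonzero entries are untouched.
#' @export
impute_dropouts <- function(cells, mean_of = c("nonzero", "all"),
                            per = c("cell", "sample")) {
  mean_of <- match.arg(mean_of)
  per <- match.arg(per)
  stop_unless_kind(cells, "raw", "impute_dropouts")
  x <- unclass_matrix(cells)
  if (per == "cell") {
    all_zero <- colSums(x > 0) == 0L
    if (any(all_zero)) {
      warning("cell(s) with no detected genes left unimputed: ",
              paste(utils::head(colnames(x)[all_zero], 5), collapse = ", "),
              call. = FALSE)
    }
    fill <- if (mean_of == "nonzero") {
      colSums(x) / pmax(colSums(x > 0), 1L)
    } else {
      colMeans(x)
    }
    zero <- x == 0
    x[zero] <- rep(fill, each = nrow(x))[zero]
    x[, all_zero] <- 0
  } else {
    all_zero <- rowSums(x > 0) == 0L
    if (any(all_zero)) {
      warning(sum(all_zero), " gene(s) with no detected values left unimputed",
              call. = FALSE)
    }
    fill <- if (mean_of == "nonzero") {
      rowSums(x) / pmax(rowSums(x > 0), 1L)
    } else {
      rowMeans(x)
    }
    zero <- x == 0
    x[zero] <- fill[row(x)][zero]
    x[all_zero, ] <- 0
  }
  set_value_kind(x, "raw")
}

#' Full bulk preprocessing chain
#'
#' @param matrix raw expression matrix.
#' @param recipe a [preprocess_recipe()].
#' @return z-scored matrix (or intermediate, if a step is disabled).
#' @export
preprocess_bulk <- function(matrix, recipe = preprocess_recipe()) {
  if (recipe$do_log2) matrix <- log2_shift(matrix)
  if (recipe$do_zscore) matrix <- zscore_per_observation(matrix)
  matrix
}

#' Full single-cell preprocessing chain
#'
#' QC filter, dropout imputation, then the bulk chain, applied to the cells of
#' one sample.
#'
#' @param cells raw expression matrix (columns = cells of one sample).
#' @param recipe a [preprocess_recipe()].
#' @param impute logical; apply [impute_dropouts()] (default TRUE).
#' @return preprocessed matrix of retained cells.
#' @export
preprocess_cells <- function(cells, recipe = preprocess_recipe(),
                             impute = TRUE) {
  cells <- cell_qc_filter(cells, recipe)
  if (impute) cells <- impute_dropouts(cells)
  preprocess_bulk(cells, recipe)
}
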