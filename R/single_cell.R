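#' Score the cells of one single-cell sample
#'
#' Runs the single-cell chain — quality filtering, dropout imputation, log2,
#' per-cell standardization — then scores every retained cell with the bulk
#' model and aggregates to a sample-level MSI score as the arithmetic mean of
#' the cell scores. The sample status is called by the model's Youden
#' threshold applied to the mean score.
#'
#' @param model an `msi_model`.
#' @param cells raw expression matrix, columns = cells of one sample.
#' @param recipe a [preprocess_recipe()]; defaults to the model's.
#' @param sample_id identifier carried into the result.
#' @param impute apply [impute_dropouts()] (default TRUE).
#' @return an object of class `sample_cell_result`: sample_id, cell_ids,
#'   cell_scores, sample_score, status, n_cells_input, n_cells_retained.
#' @export
score_sample_cells <- function(model, cells, recipe = model$recipe,
                               sample_id = "sample", impute = TRUE) {
  stop_unless_kind(cells, "raw", "score_sample_cells")
  n_in <- ncol(cells)
  kept <- cell_qc_filter(cells, recipe)
  if (impute) kept <- impute_dropouts(kept)
  preds <- predict(model, kept)
  res <- structure(list(
    sample_id = sample_id,
    cell_ids = preds$sample_id,
    cell_scores = stats::setNames(preds$msi_score, preds$sample_id),
    sample_score = mean(preds$msi_score),
    status = NA_character_,
    n_cells_input = n_in,
    n_cells_retained = ncol(kept)
  ), class = "sample_cell_result")
  res$status <- if (res$sample_score >= model$threshold) "MSI" else "MSS"
  res
}

#' @export
print.sample_cell_result <- function(x, ...) {
  cat("sample ", x$sample_id, ": ", x$n_cells_retained, "/", x$n_cells_input,
      " cells retained, mean MSI score ", format(round(x$sample_score, 4)),
      " -> ", x$status, "\n", sep = "")
  invisible(x)
}

#' Score a cohort of single-cell samples
#'
#' Applies [score_sample_cells()] independently per sample. A failure in one
#' sample is reported as a warning and flagged in the summary table; the rest
#' of the cohort still completes.
#'
#' @param model an `msi_model`.
#' @param samples named list of raw cell matrices (one per sample), or a list
#'   of `list(sample_id =, cells =)` entries.
#' @param recipe a [preprocess_recipe()]; defaults to the model's.
#' @param groups optional named vector mapping cell id to a group (e.g. cell
#'   type); per-group mean scores are attached to each sample result.
#' @return list with `results` (per-sample `sample_cell_result` or NULL on
#'   failure) and `summary` (data.frame: sample_id, sample_score, msi_status,
#'   n_cells_input, n_cells_retained, ok).
#' @export
score_cohort <- function(model, samples, recipe = model$recipe,
                         groups = NULL) {
  if (!length(samples)) stop("empty single-cell cohort", call. = FALSE)
  entries <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (is.list(s) && !is.null(s$cells)) {
      list(sample_id = s$sample_id, cells = s$cells)
    } else {
      sid <- names(samples)[i]
      if (is.null(sid) || !nzchar(sid)) sid <- paste0("sample", i)
      list(sample_id = sid, cells = s)
    }
  })
  results <- lapply(entries, function(e) {
    tryCatch({
      r <- score_sample_cells(model, e$cells, recipe, e$sample_id)
      if (!is.null(groups)) {
        grp <- groups[r$cell_ids]
        known <- !is.na(grp)
        r$group_scores <- if (any(known)) {
          tapply(r$cell_scores[known], grp[known], mean)
        } else numeric()
      }
      r
    }, error = function(err) {
      warning("sample ", e$sample_id, " failed: ", conditionMessage(err),
              call. = FALSE)
      NULL
    })
  })
  summary <- data.frame(
    sample_id = vapply(entries, `[[`, character(1), "sample_id"),
    sample_score = vapply(results, function(r)
      if (is.null(r)) NA_real_ else r$sample_score, numeric(1)),
    msi_status = vapply(results, function(r)
      if (is.null(r)) NA_character_ else r$status, character(1)),
    n_cells_input = vapply(results, function(r)
      if (is.null(r)) NA_integer_ else r$n_cells_input, integer(1)),
    n_cells_retained = vapply(results, function(r)
      if (is.null(r)) NA_integer_ else r$n_cells_retained, integer(1)),
    ok = !vapply(results, is.null, logical(1)),
    stringsAsFactors = FALSE
  )
  list(results = results, summary = summary)
}

#' Split a cell matrix into per-sample matrices
#'
#' @param cells raw matrix whose columns are cells from multiple samples.
#' @param sample_map named vector mapping cell id (barcode) to sample id.
#' @return named list of raw matrices, one per sample.
#' @export
split_cells_by_sample <- function(cells, sample_map) {
  missing <- setdiff(colnames(cells), names(sample_map))
  if (length(missing)) {
    stop("no sample assignment for cell(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sids <- sample_map[colnames(cells)]
  lapply(split(colnames(cells), sids), function(cols) {
    set_value_kind(cells[, cols, drop = FALSE], value_kind(cells))
  })
}
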