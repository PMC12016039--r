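#' Gene-selection thresholds
#'
#' Parameters of the four-stage informative-gene filter: rank-sum significance,
#' absolute log2 fold change, per-gene AUC, then a dual-model cross-validation
#' ranking whose top quantiles are intersected.
#'
#' @param p_max two-sided rank-sum significance level; default 0.01.
#' @param fc_min minimum absolute log2 fold change between group means;
#'   default 0.5.
#' @param auc_min minimum per-gene (direction-folded) AUC; default 0.65.
#' @param top_quantile fraction of the candidate CV rankings to intersect;
#'   default 0.25.
#' @param cv_folds number of stratified CV folds for the ranking stage;
#'   default 10 (reduced to the minority-class size when smaller).
#' @param low_expr_min_mean minimum mean raw expression for a gene to be kept
#'   by the blacklist stage; default 1.0 (the conventional 1-FPKM
#'   expressed/not-expressed boundary).
#' @param seed integer controlling CV fold assignment and classifier
#'   randomness.
#' @return an object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(p_max = 0.01, fc_min = 0.5, auc_min = 0.65,
                                 top_quantile = 0.25, cv_folds = 10L,
                                 low_expr_min_mean = 1.0, seed = 1L) {
  stopifnot(p_max > 0, p_max < 1, fc_min >= 0,
            auc_min >= 0.5, auc_min < 1,
            top_quantile > 0, top_quantile <= 1,
            cv_folds >= 2L, low_expr_min_mean >= 0)
  structure(list(p_max = p_max, fc_min = fc_min, auc_min = auc_min,
                 top_quantile = top_quantile, cv_folds = as.integer(cv_folds),
                 low_expr_min_mean = low_expr_min_mean,
                 seed = as.integer(seed)),
            class = "selection_thresholds")
}

# ribosomal (cytosolic and mitochondrial) and mitochondrially encoded genes,
# by human gene-symbol prefix; user-extensible via the patterns argument
default_blacklist_patterns <- function() {
  c("^RPL", "^RPS", "^MRPL", "^MRPS", "^MT-")
}

#' Blacklist and low-expression filter
#'
#' Removes ribosomal and mitochondrial genes (by symbol prefix) and genes
#' whose mean raw expression falls below `low_expr_min_mean`.
#'
#' @param cohort a labeled cohort with a raw-scale matrix.
#' @param thresholds a [selection_thresholds()].
#' @param patterns character vector of regular expressions defining the
#'   blacklist; defaults to ribosomal/mitochondrial prefixes.
#' @return the cohort restricted to retained genes.
#' @export
blacklist_filter <- function(cohort, thresholds = selection_thresholds(),
                             patterns = default_blacklist_patterns()) {
  stop_unless_kind(cohort$matrix, "raw", "blacklist_filter")
  genes <- rownames(cohort$matrix)
  black <- Reduce(`|`, lapply(patterns, grepl, x = genes))
  low <- rowMeans(unclass_matrix(cohort$matrix)) < thresholds$low_expr_min_mean
  keep <- !(black | low)
  if (!any(keep)) {
    stop("blacklist/low-expression filter removed every gene", call. = FALSE)
  }
  subset_cohort_genes(cohort, genes[keep])
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution when both groups have at most 8 tie-free values,
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param msi_values,mss_values numeric vectors of one gene's expression in
#'   the two groups.
#' @return two-sided p-value.
#' @export
ranksum_pvalue <- function(msi_values, mss_values) {
  if (!length(msi_values) || !length(mss_values)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- length(msi_values) <= 8L && length(mss_values) <= 8L &&
    !anyDuplicated(c(msi_values, mss_values))
  suppressWarnings(
    stats::wilcox.test(msi_values, mss_values, exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Absolute log2 fold change between group means
#'
#' `F = |log2(mean(msi) / mean(mss))|`. Both group means must be strictly
#' positive, which is why the selection pipeline evaluates this statistic on
#' the log2(x+1) scale rather than on per-sample z-scores (z-scored means can
#' be non-positive).
#'
#' @param msi_values,mss_values numeric vectors on a positive scale.
#' @return absolute log2 ratio of group means.
#' @export
fold_change <- function(msi_values, mss_values) {
  m1 <- mean(msi_values)
  m0 <- mean(mss_values)
  if (!is.finite(m1) || !is.finite(m0) || m1 <= 0 || m0 <= 0) {
    stop("fold change requires strictly positive group means; ",
         "evaluate it on the log2(x+1) scale, not on z-scores", call. = FALSE)
  }
  abs(log2(m1 / m0))
}

#' Single-gene ROC AUC, direction-folded
#'
#' Rank-based (Mann-Whitney) AUC of one gene's expression for separating MSI
#' from MSS, with midrank tie handling, folded as `max(a, 1 - a)` so down- and
#' up-regulated genes score symmetrically.
#'
#' @param msi_values,mss_values numeric vectors.
#' @return AUC in \code{[0.5, 1]}.
#' @export
gene_auc <- function(msi_values, mss_values) {
  a <- auc_rank(msi_values, mss_values)
  max(a, 1 - a)
}

# internal: Mann-Whitney AUC via midranks; positive group first
auc_rank <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Per-gene cross-validation scores
#'
#' Mean held-out accuracy of an RBF-kernel SVM and a 100-tree random forest,
#' each trained on the single gene's standardized values over stratified
#' folds. Fold assignment and forest randomness are fixed by
#' `thresholds$seed`, and the same folds are used for every gene.
#'
#' @param cohort labeled cohort on the z-score scale.
#' @param gene_id gene to evaluate.
#' @param thresholds a [selection_thresholds()].
#' @return named numeric vector `c(svm_cv = ..., rf_cv = ...)`.
#' @export
gene_cv_scores <- function(cohort, gene_id, thresholds = selection_thresholds()) {
  if (!gene_id %in% rownames(cohort$matrix)) {
    stop("gene not in cohort: ", gene_id, call. = FALSE)
  }
  y <- factor(cohort$labels, levels = c("MSS", "MSI"))
  if (min(table(y)) < 2L) {
    stop("each class needs at least 2 members for cross-validation",
         call. = FALSE)
  }
  x <- as.numeric(cohort$matrix[gene_id, ])
  folds <- with_seed(thresholds$seed,
                     stratified_folds(y, min(thresholds$cv_folds,
                                             min(table(y)))))
  acc <- with_seed(thresholds$seed + 1L, vapply(seq_len(max(folds)), function(f) {
    tr <- folds != f
    xtr <- matrix(x[tr], ncol = 1)
    xte <- matrix(x[!tr], ncol = 1)
    g <- 1 / max(stats::var(as.vector(xtr)), 1e-12)
    svm_fit <- e1071::svm(xtr, y[tr], type = "C-classification",
                          kernel = "radial", cost = 1, gamma = g,
                          scale = FALSE)
    rf_fit <- randomForest::randomForest(xtr, y[tr], ntree = 100L)
    c(mean(stats::predict(svm_fit, xte) == y[!tr]),
      mean(stats::predict(rf_fit, xte) == y[!tr]))
  }, numeric(2)))
  c(svm_cv = mean(acc[1L, ]), rf_cv = mean(acc[2L, ]))
}

# internal: stratified fold labels, deterministic under the active RNG state
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# internal: run code with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Select MSI-informative genes
#'
#' The full four-stage filter. Starting from a raw labeled cohort:
#' \enumerate{
#'   \item blacklist and low-expression removal (raw scale);
#'   \item two-sided Wilcoxon rank-sum test on per-sample z-scores,
#'     keep `p < p_max`;
#'   \item absolute log2 fold change of group means on the log2(x+1) scale,
#'     keep `> fc_min`;
#'   \item direction-folded per-gene AUC on z-scores, keep `> auc_min`
#'     (these survivors are the \emph{candidates});
#'   \item rank the candidates by SVM and by random-forest cross-validation
#'     accuracy (descending, gene id as tiebreak) and intersect the top
#'     `ceiling(top_quantile * n_candidates)` of the two rankings.
#' }
#'
#' @param cohort labeled cohort with a raw matrix.
#' @param thresholds a [selection_thresholds()].
#' @param patterns blacklist patterns, see [blacklist_filter()].
#' @return list with `genes` (character vector, in descending SVM-CV order),
#'   `stats` (one row per input gene: p_value, fold_change, auc, svm_cv,
#'   rf_cv, stage_passed), and `provenance` (thresholds plus cohort counts
#'   m, n).
#' @export
select_informative_genes <- function(cohort,
                                     thresholds = selection_thresholds(),
                                     patterns = default_blacklist_patterns()) {
  stop_unless_kind(cohort$matrix, "raw", "select_informative_genes")
  counts <- cohort_counts(cohort)
  all_genes <- rownames(cohort$matrix)
  stats_df <- data.frame(gene_id = all_genes, p_value = NA_real_,
                         fold_change = NA_real_, auc = NA_real_,
                         svm_cv = NA_real_, rf_cv = NA_real_,
                         stage_passed = "blacklist",
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- all_genes

  kept <- blacklist_filter(cohort, thresholds, patterns)
  surv <- rownames(kept$matrix)
  stats_df[surv, "stage_passed"] <- "ranksum"

  log2_mat <- log2_shift(kept$matrix)
  z_mat <- zscore_per_observation(log2_mat)
  is_msi <- kept$labels == "MSI"

  # stage 2: rank-sum on z-scores
  pvals <- apply(unclass_matrix(z_mat), 1L, function(v) {
    ranksum_pvalue(v[is_msi], v[!is_msi])
  })
  stats_df[surv, "p_value"] <- pvals
  surv <- surv[pvals < thresholds$p_max]
  stats_df[surv, "stage_passed"] <- "fold_change"

  # stage 3: fold change on the log2(x+1) scale
  fc <- vapply(surv, function(g) {
    v <- unclass_matrix(log2_mat)[g, ]
    fold_change(v[is_msi], v[!is_msi])
  }, numeric(1))
  stats_df[surv, "fold_change"] <- fc
  surv <- surv[fc > thresholds$fc_min]
  stats_df[surv, "stage_passed"] <- "auc"

  # stage 4: per-gene folded AUC on z-scores
  aucs <- vapply(surv, function(g) {
    v <- unclass_matrix(z_mat)[g, ]
    gene_auc(v[is_msi], v[!is_msi])
  }, numeric(1))
  stats_df[surv, "auc"] <- aucs
  candidates <- surv[aucs > thresholds$auc_min]
  stats_df[candidates, "stage_passed"] <- "candidate"

  if (!length(candidates)) {
    stop("no gene passed the AUC stage; relax p_max/fc_min/auc_min",
         call. = FALSE)
  }

  # stage 5: dual-model CV ranking over the candidates
  z_cohort <- structure(list(matrix = z_mat, labels = kept$labels),
                        class = "msi_cohort")
  cv <- t(vapply(candidates, function(g) {
    gene_cv_scores(z_cohort, g, thresholds)
  }, numeric(2)))
  stats_df[candidates, c("svm_cv", "rf_cv")] <- cv

  k <- ceiling(thresholds$top_quantile * length(candidates))
  top_svm <- candidates[order(-cv[, "svm_cv"], candidates)][seq_len(k)]
  top_rf <- candidates[order(-cv[, "rf_cv"], candidates)][seq_len(k)]
  final <- top_svm[top_svm %in% top_rf]
  if (!length(final)) {
    stop("empty intersection of the SVM and RF top-", thresholds$top_quantile,
         " rankings; relax top_quantile or the earlier thresholds",
         call. = FALSE)
  }
  stats_df[final, "stage_passed"] <- "informative"

  list(genes = final,
       stats = stats_df[, , drop = FALSE],
       provenance = list(thresholds = thresholds, m = counts$m, n = counts$n))
}

#' Write a gene-selection stats table
#'
#' @param selection result of [select_informative_genes()].
#' @param genes_path path for the informative gene list (one id per line).
#' @param stats_path optional path for the per-gene stats TSV.
#' @param header_lines optional provenance lines (prefixed `#`).
#' @export
write_selection <- function(selection, genes_path, stats_path = NULL,
                            header_lines = character()) {
  con <- file(genes_path, "w")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(selection$genes, con)
  close(con)
  if (!is.null(stats_path)) {
    con <- file(stats_path, "w")
    if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
    utils::write.table(selection$stats, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(genes_path)
}
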