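#' ROC AUC of MSI scores
#'
#' Rank-based (Mann-Whitney) area under the ROC curve with midrank tie
#' handling; MSI is the positive class throughout the package.
#'
#' @param scores numeric vector.
#' @param labels `"MSI"`/`"MSS"` per score.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_status(labels)
  is_msi <- labels == "MSI"
  if (!any(is_msi) || all(is_msi)) {
    stop("AUC requires both classes", call. = FALSE)
  }
  auc_rank(scores[is_msi], scores[!is_msi])
}

#' Confusion-matrix metrics for MSI status calls
#'
#' Accuracy, F1, precision, sensitivity and specificity with MSI as the
#' positive class. Ratios with a zero denominator are reported as 0 with a
#' warning so reports stay machine-parseable.
#'
#' @param statuses predicted statuses (`"MSI"`/`"MSS"`).
#' @param labels true statuses, aligned with `statuses`.
#' @param auc optional AUC to carry into the report.
#' @param threshold optional threshold used for the calls, recorded verbatim.
#' @return an object of class `msi_metrics` (list of the metrics plus
#'   `n_msi`, `n_mss` counts).
#' @export
confusion_metrics <- function(statuses, labels, auc = NA_real_,
                              threshold = NA_real_) {
  statuses <- normalize_status(statuses)
  labels <- normalize_status(labels)
  if (length(statuses) != length(labels)) {
    stop("statuses and labels have different lengths (", length(statuses),
         " vs ", length(labels), ")", call. = FALSE)
  }
  tp <- sum(statuses == "MSI" & labels == "MSI")
  fp <- sum(statuses == "MSI" & labels == "MSS")
  tn <- sum(statuses == "MSS" & labels == "MSS")
  fn <- sum(statuses == "MSS" & labels == "MSI")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " has a zero denominator; reported as 0", call. = FALSE)
      0
    } else num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  acc <- ratio(tp + tn, length(labels), "accuracy")
  f1 <- ratio(2 * prec * sens, prec + sens, "F1")
  structure(list(auc = auc, accuracy = acc, f1 = f1, precision = prec,
                 sensitivity = sens, specificity = spec,
                 n_msi = sum(labels == "MSI"), n_mss = sum(labels == "MSS"),
                 threshold = threshold),
            class = "msi_metrics")
}

#' @export
print.msi_metrics <- function(x, ...) {
  cat("MSI classification metrics (", x$n_msi, " MSI / ", x$n_mss,
      " MSS):\n", sep = "")
  for (f in c("auc", "accuracy", "f1", "precision", "sensitivity",
              "specificity")) {
    cat(sprintf("  %-12s %s\n", f,
                if (is.na(x[[f]])) "-" else format(round(x[[f]], 4))))
  }
  invisible(x)
}

#' Evaluate predictions against true labels
#'
#' @param predictions data.frame from [predict.msi_model()] (columns
#'   `sample_id`, `msi_score`, `msi_status`).
#' @param labels named vector of true statuses.
#' @return an `msi_metrics` report including AUC.
#' @export
evaluate_predictions <- function(predictions, labels) {
  labels <- normalize_status(labels)
  missing <- setdiff(predictions$sample_id, names(labels))
  if (length(missing)) {
    stop("no true label for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  truth <- labels[predictions$sample_id]
  confusion_metrics(predictions$msi_status, truth,
                    auc = roc_auc(predictions$msi_score, truth))
}
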