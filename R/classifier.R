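#' SMOTE minority oversampling
#'
#' Balances a two-class training set by synthesizing minority-class points:
#' each synthetic point is `x + u * (x_nn - x)` where `x` is a uniformly
#' chosen minority sample, `x_nn` one of its `k` nearest minority neighbors
#' (Euclidean), and `u ~ Uniform(0, 1)`. Majority samples and all original
#' rows are returned untouched, ahead of the synthetic rows.
#'
#' @param features numeric matrix, samples x genes.
#' @param labels character/factor vector of `"MSI"`/`"MSS"` per row.
#' @param k neighbor count (default 5, clamped to minority size - 1 with a
#'   warning).
#' @param seed integer seed; the result is deterministic given it.
#' @return list with `features` (original rows then synthetic), `labels`,
#'   and `n_synthetic`.
#' @export
smote_balance <- function(features, labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels), k >= 1L)
  tab <- table(labels)
  if (length(tab) != 2L) stop("SMOTE needs exactly two classes", call. = FALSE)
  if (tab[1L] == tab[2L]) {
    return(list(features = features, labels = labels, n_synthetic = 0L))
  }
  min_lab <- names(tab)[which.min(tab)]
  min_idx <- which(labels == min_lab)
  n_min <- length(min_idx)
  if (n_min < 2L) {
    stop("minority class has a single member; SMOTE has no neighbor to ",
         "interpolate with", call. = FALSE)
  }
  if (k > n_min - 1L) {
    warning("k = ", k, " exceeds minority size - 1; clamped to ", n_min - 1L,
            call. = FALSE)
    k <- n_min - 1L
  }
  n_syn <- as.integer(max(tab) - n_min)
  xmin <- features[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xmin))
  diag(d) <- Inf
  # k nearest minority neighbors of each minority point, ties by index
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k)])
  nn <- matrix(nn, nrow = k)
  had_names <- !is.null(rownames(features))
  synth <- with_seed(seed, {
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- sample.int(k, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    xb <- xmin[base, , drop = FALSE]
    xn <- xmin[nn[cbind(pick, base)], , drop = FALSE]
    xb + u * (xn - xb)
  })
  rownames(synth) <- if (had_names) {
    sprintf("%s_smote_%d", min_lab, seq_len(n_syn))
  }
  list(features = rbind(features, synth),
       labels = c(labels, rep(min_lab, n_syn)),
       n_synthetic = n_syn)
}

# ---- RBF-SVM core -----------------------------------------------------------
# The fitted SVM is reduced to its learned constants (support vectors, dual
# coefficients, intercept) so that scoring is a pure function of the model
# file: decision(x) = sum_i coef_i * exp(-gamma * ||sv_i - x||^2) - rho,
# oriented so positive means MSI, then mapped to a probability by a Platt
# sigmoid fitted on cross-validated decision values.

# internal: decision values of an RBF expansion for rows of X
rbf_decision <- function(sv, coefs, rho, gamma, X) {
  d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-gamma * d2) %*% coefs - rho)
}

# internal: fit e1071 svm and extract constants with an MSI-positive sign
fit_rbf_svm <- function(x, y, gamma, cost = 1) {
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  sv <- fit$SV
  coefs <- as.numeric(fit$coefs)
  dec <- rbf_decision(sv, coefs, fit$rho, gamma, x)
  sgn <- if (mean((dec > 0) == (y == "MSI")) >= 0.5) 1 else -1
  list(sv = sv, coefs = sgn * coefs, rho = sgn * fit$rho, gamma = gamma)
}

# internal: Platt sigmoid p = 1 / (1 + exp(A*f + B)) fitted on decision
# values f with MSI indicator y, using Platt's regularized targets
platt_fit <- function(f, y_msi) {
  np <- sum(y_msi)
  nn <- sum(!y_msi)
  t_i <- ifelse(y_msi, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1L] * f + par[2L]
    # stable cross-entropy for t*log(p) + (1-t)*log(1-p) with p = 1/(1+exp(z)):
    # loss = log(1+exp(z)) - (1-t)*z
    sum(pmax(z, 0) + log1p(exp(-abs(z))) - (1 - t_i) * z)
  }
  fit <- stats::optim(c(-1, log((nn + 1) / (np + 1))), nll,
                      method = "BFGS", control = list(maxit = 200L))
  c(A = fit$par[1L], B = fit$par[2L])
}

platt_prob <- function(f, A, B) 1 / (1 + exp(A * f + B))

#' Youden-index threshold
#'
#' Exhaustive search over candidate cutpoints — midpoints of adjacent distinct
#' sorted scores plus the 0 and 1 boundaries — for the threshold maximizing
#' `J(t) = sensitivity(t) + specificity(t) - 1`, where a score `>= t` calls
#' MSI. Ties in J are broken toward the larger threshold (higher specificity).
#'
#' @param scores numeric vector of MSI probabilities.
#' @param labels `"MSI"`/`"MSS"` per score; both classes must be present.
#' @return the selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- normalize_status(labels)
  is_msi <- labels == "MSI"
  if (!any(is_msi) || all(is_msi)) {
    stop("Youden threshold requires both classes", call. = FALSE)
  }
  s <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2)))
  j <- vapply(cand, function(t) {
    mean(scores[is_msi] >= t) + mean(scores[!is_msi] < t) - 1
  }, numeric(1))
  best <- max(j)
  if (best <= 0) {
    warning("no cutpoint achieves a positive Youden index; scores do not ",
            "separate the classes", call. = FALSE)
  }
  max(cand[j == best])
}

#' Train the MSI classification model
#'
#' Fits an RBF-kernel SVM (cost 1, kernel width `1 / (p * var(X))`) on
#' SMOTE-balanced training data, calibrates a Platt sigmoid on stratified
#' 5-fold cross-validated decision values, and sets the MSI/MSS call
#' threshold by the Youden index over the model's scores on the original
#' (pre-SMOTE) training samples.
#'
#' @param cohort labeled cohort, z-scored and restricted to (and ordered by)
#'   the informative gene list; columns = samples.
#' @param seed integer controlling SMOTE and fold assignment.
#' @param smote_k SMOTE neighbor count (default 5).
#' @param recipe the [preprocess_recipe()] recorded for prediction time.
#' @return an object of class `msi_model`.
#' @export
train_msi_model <- function(cohort, seed = 1L, smote_k = 5L,
                            recipe = preprocess_recipe()) {
  stop_unless_kind(cohort$matrix, "zscore", "train_msi_model")
  counts <- cohort_counts(cohort)
  genes <- rownames(cohort$matrix)
  x <- t(unclass_matrix(cohort$matrix))
  y <- cohort$labels

  bal <- smote_balance(x, y, k = smote_k, seed = seed)
  xb <- bal$features
  yb <- factor(bal$labels, levels = c("MSS", "MSI"))
  gamma <- 1 / (ncol(xb) * max(stats::var(as.vector(xb)), 1e-12))

  core <- fit_rbf_svm(xb, yb, gamma)

  # Platt calibration on out-of-fold decision values (5-fold, stratified)
  folds <- with_seed(seed + 1L, stratified_folds(yb, min(5L, min(table(yb)))))
  oof <- numeric(length(yb))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    sub <- fit_rbf_svm(xb[tr, , drop = FALSE], yb[tr], gamma)
    oof[!tr] <- rbf_decision(sub$sv, sub$coefs, sub$rho, gamma,
                             xb[!tr, , drop = FALSE])
  }
  platt <- platt_fit(oof, yb == "MSI")

  train_scores <- platt_prob(rbf_decision(core$sv, core$coefs, core$rho,
                                          gamma, x), platt["A"], platt["B"])
  threshold <- youden_threshold(train_scores, y)

  structure(list(
    format_version = "1.0",
    genes = genes,
    kernel = "radial",
    cost = 1,
    gamma = gamma,
    sv = unname(core$sv),
    coefs = core$coefs,
    rho = core$rho,
    platt_a = unname(platt["A"]),
    platt_b = unname(platt["B"]),
    threshold = threshold,
    recipe = recipe,
    training_summary = list(m = counts$m, n = counts$n, seed = as.integer(seed),
                            package_version = "0.1.0")
  ), class = "msi_model")
}

#' @export
print.msi_model <- function(x, ...) {
  cat("msi_model: ", length(x$genes), " genes, RBF SVM (gamma=",
      format(x$gamma, digits = 4), "), Youden threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

# internal: probability scores for a samples-x-genes feature matrix already
# aligned with model$genes
model_scores <- function(model, features) {
  platt_prob(rbf_decision(model$sv, model$coefs, model$rho, model$gamma,
                          features),
             model$platt_a, model$platt_b)
}

#' Predict MSI status for bulk samples
#'
#' Applies the model's preprocessing recipe — log2(x+1) and per-sample
#' standardization computed over \emph{all} genes in the input matrix — then
#' restricts to the model's gene panel, scores each sample, and calls MSI
#' when the score reaches the Youden threshold. Up to 10% of model genes may
#' be absent from the input; their z-scores are imputed as 0 (the
#' cohort-neutral value) with a warning. Above 10% the panel is considered
#' mismatched and an error names the missing genes.
#'
#' @param object an `msi_model`.
#' @param matrix a raw expression matrix (genes x samples).
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `msi_score`, `msi_status`.
#' @export
predict.msi_model <- function(object, matrix, ...) {
  stop_unless_kind(matrix, "raw", "predict.msi_model")
  missing <- setdiff(object$genes, rownames(matrix))
  if (length(missing) > 0.10 * length(object$genes)) {
    stop("input matrix lacks ", length(missing), " of ", length(object$genes),
         " model genes (> 10%): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...", call. = FALSE)
  }
  z <- preprocess_bulk(matrix, object$recipe)
  feat <- matrix(0, nrow = ncol(z), ncol = length(object$genes),
                 dimnames = list(colnames(z), object$genes))
  present <- setdiff(object$genes, missing)
  feat[, present] <- t(unclass_matrix(z)[present, , drop = FALSE])
  if (length(missing)) {
    warning("imputed z = 0 for ", length(missing),
            " model gene(s) absent from the input: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- model_scores(object, feat)
  data.frame(sample_id = colnames(z),
             msi_score = scores,
             msi_status = ifelse(scores >= object$threshold, "MSI", "MSS"),
             stringsAsFactors = FALSE)
}

#' Fit an MSI model from a raw cohort and a gene list
#'
#' Convenience wrapper matching prediction-time preprocessing: log2 and
#' per-sample z-score over all genes of the cohort, then restriction to the
#' informative genes, then [train_msi_model()].
#'
#' @param cohort raw labeled cohort.
#' @param genes informative gene ids (must all be present in the cohort).
#' @param seed integer seed.
#' @param recipe a [preprocess_recipe()].
#' @return an `msi_model`.
#' @export
fit_msi_model <- function(cohort, genes, seed = 1L,
                          recipe = preprocess_recipe()) {
  missing <- setdiff(genes, rownames(cohort$matrix))
  if (length(missing)) {
    stop("training cohort lacks informative gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- preprocess_bulk(cohort$matrix, recipe)
  zc <- msi_cohort(expr_matrix(unclass_matrix(z)[genes, , drop = FALSE],
                               value_kind = "zscore"),
                   cohort$labels)
  train_msi_model(zc, seed = seed, recipe = recipe)
}

#' Save an MSI model as versioned JSON
#'
#' All learned constants are inlined as plain numbers, so the file is
#' portable and diffable; [load_model()] restores a model that scores any
#' matrix identically to within floating-point text precision.
#'
#' @param model an `msi_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  payload <- unclass(model)
  payload$recipe <- unclass(payload$recipe)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load an MSI model from JSON
#'
#' @param path path written by [save_model()].
#' @return an `msi_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$format_version) || !identical(obj$format_version, "1.0")) {
    stop("unsupported model format version: ",
         if (is.null(obj$format_version)) "<missing>" else obj$format_version,
         call. = FALSE)
  }
  if (!identical(obj$kernel, "radial")) {
    stop("unknown kernel in model file: ", obj$kernel, call. = FALSE)
  }
  needed <- c("genes", "gamma", "sv", "coefs", "rho", "platt_a", "platt_b",
              "threshold", "recipe")
  absent <- needed[!needed %in% names(obj)]
  if (length(absent)) {
    stop("model file missing field(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  obj$sv <- matrix(as.numeric(obj$sv), ncol = length(obj$genes))
  obj$recipe <- do.call(preprocess_recipe, obj$recipe[
    c("do_log2", "do_zscore", "sc_min_detected_fraction", "sc_min_cells")])
  structure(obj, class = "msi_model")
}
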