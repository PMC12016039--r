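# Independent brute-force oracles used to check the rank-based statistics.
# These deliberately use naive enumeration, not the package's code paths.

# AUC by explicit pair counting: P(pos > neg) + 0.5 P(pos == neg)
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Youden threshold by explicit confusion tables at every candidate cutpoint
brute_youden <- function(scores, labels) {
  is_msi <- labels == "MSI"
  s <- sort(unique(scores))
  cand <- c(0, 1)
  if (length(s) > 1L) cand <- c(cand, (s[-1L] + s[-length(s)]) / 2)
  cand <- sort(unique(cand))
  best_j <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    tp <- sum(is_msi & scores >= t)
    fn <- sum(is_msi & scores < t)
    tn <- sum(!is_msi & scores < t)
    fp <- sum(!is_msi & scores >= t)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j || (j == best_j && t > best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (tie-free data only), using the
# conventional doubled-tail definition
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  w_all <- apply(sets, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  p <- if (w_obs > mid) {
    2 * mean(w_all >= w_obs)
  } else if (w_obs < mid) {
    2 * mean(w_all <= w_obs)
  } else 1
  min(p, 1)
}

# small labeled fixture builder: g genes x (n_msi + n_mss) raw cohort
tiny_cohort <- function(values, n_msi, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(values)))
  obs <- sprintf("s%d", seq_len(ncol(values)))
  labels <- rep(c("MSI", "MSS"), c(n_msi, ncol(values) - n_msi))
  msi_cohort(expr_matrix(values, gene_ids, obs, value_kind = "raw"),
             stats::setNames(labels, obs))
}

# strip the value_kind attribute for raw numeric comparisons
mat_values <- function(x) {
  attr(x, "value_kind") <- NULL
  x
}
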