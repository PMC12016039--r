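#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Baseline expression is
#' log-normal: gene g has raw value `exp(N(mu_g, sigma_g)) - 1` (clamped at
#' 0) with `mu_g ~ N(base_log_mean, 1)` and `sigma_g = base_log_sd`, an
#' FPKM/TPM-like continuous scale. A planted informative gene shifts its
#' log-mean by `delta * sigma_g` in MSI observations; half of the planted
#' genes (rounded down) are down-regulated instead, so direction folding is
#' always exercised.
#'
#' The defaults are the package's reference study conditions: 500 genes with
#' 20 planted informative ones, 60 MSI / 90 MSS bulk samples, effect size
#' delta = 2 log-scale standard deviations; single-cell samples of 200 cells
#' with 30% dropout, a 10% low-quality cell fraction, and per-sample MSI-like
#' cell fractions of 0.70-0.95 (MSI samples) versus 0-0.10 (MSS samples).
#'
#' @param n_genes,n_informative gene counts.
#' @param n_msi,n_mss bulk sample counts (for single-cell cohorts, sample
#'   counts per class).
#' @param delta effect size in units of the log-scale standard deviation.
#' @param base_log_mean,base_log_sd log-normal baseline parameters (natural
#'   log scale).
#' @param sc_cells_per_sample cells per single-cell sample.
#' @param sc_dropout_rate per-entry probability of a technical zero.
#' @param sc_lowq_fraction fraction of cells made low quality (only ~10% of
#'   genes detected) to exercise the QC filter.
#' @param sc_msi_fraction_range,sc_mss_fraction_range ranges the per-sample
#'   MSI-like cell fraction is drawn from, by sample class.
#' @param seed integer master seed; gene-level parameters depend only on
#'   `seed`, so bulk and single-cell cohorts from the same config share the
#'   same gene panel and truth set.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_informative = 20L,
                       n_msi = 60L, n_mss = 90L, delta = 2,
                       base_log_mean = 2, base_log_sd = 1,
                       sc_cells_per_sample = 200L, sc_dropout_rate = 0.30,
                       sc_lowq_fraction = 0.10,
                       sc_msi_fraction_range = c(0.70, 0.95),
                       sc_mss_fraction_range = c(0.00, 0.10),
                       seed = 1L) {
  stopifnot(n_informative <= n_genes, n_genes >= 1, n_msi >= 0, n_mss >= 0,
            n_msi + n_mss >= 1,
            delta >= 0, base_log_sd > 0,
            sc_dropout_rate >= 0, sc_dropout_rate < 1,
            sc_lowq_fraction >= 0, sc_lowq_fraction < 1,
            sc_cells_per_sample >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 n_msi = as.integer(n_msi), n_mss = as.integer(n_mss),
                 delta = delta, base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd,
                 sc_cells_per_sample = as.integer(sc_cells_per_sample),
                 sc_dropout_rate = sc_dropout_rate,
                 sc_lowq_fraction = sc_lowq_fraction,
                 sc_msi_fraction_range = sc_msi_fraction_range,
                 sc_mss_fraction_range = sc_mss_fraction_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: gene-level parameters, a function of the config seed alone
sim_gene_params <- function(config) {
  with_seed(config$seed, {
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    informative <- sort(sample(config$n_genes, config$n_informative))
    direction <- rep(1, config$n_informative)
    if (config$n_informative >= 2L) {
      down <- sample(config$n_informative, config$n_informative %/% 2L)
      direction[down] <- -1
    }
    list(gene_ids = gene_ids,
         mu = stats::rnorm(config$n_genes, config$base_log_mean, 1),
         sigma = rep(config$base_log_sd, config$n_genes),
         informative = informative,
         direction = stats::setNames(direction, gene_ids[informative]))
  })
}

# internal: one genes x n matrix of raw profiles; is_msi flags columns
sim_profiles <- function(params, config, is_msi, obs_ids) {
  ng <- length(params$mu)
  mu <- matrix(params$mu, nrow = ng, ncol = length(is_msi))
  shift <- config$delta * params$sigma[params$informative]
  dirs <- as.numeric(params$direction)
  mu[params$informative, is_msi] <-
    mu[params$informative, is_msi, drop = FALSE] + dirs * shift
  raw <- exp(mu + matrix(stats::rnorm(ng * length(is_msi)), nrow = ng) *
               params$sigma) - 1
  raw[raw < 0] <- 0
  dimnames(raw) <- list(params$gene_ids, obs_ids)
  raw
}

#' Simulate a labeled bulk cohort
#'
#' @param config a [sim_config()].
#' @param cohort_seed seed for the sampling noise only (default
#'   `config$seed + 1`). Gene-level parameters — baseline means, the planted
#'   gene set and its directions — depend on `config$seed` alone, so two
#'   calls differing only in `cohort_seed` yield independent train/test
#'   cohorts over the same gene panel.
#' @return list with `cohort` (an [msi_cohort()] of raw values) and `truth`
#'   (character vector of planted informative gene ids, never fed to the
#'   pipeline).
#' @export
simulate_bulk <- function(config = sim_config(),
                          cohort_seed = config$seed + 1L) {
  params <- sim_gene_params(config)
  m <- config$n_msi + config$n_mss
  obs_ids <- sprintf("S%03d", seq_len(m))
  labels <- stats::setNames(rep(c("MSI", "MSS"), c(config$n_msi, config$n_mss)),
                            obs_ids)
  raw <- with_seed(cohort_seed,
                   sim_profiles(params, config, labels == "MSI", obs_ids))
  list(cohort = msi_cohort(expr_matrix(raw, value_kind = "raw"), labels),
       truth = params$gene_ids[params$informative])
}

#' Simulate a labeled single-cell cohort
#'
#' Each sample holds `sc_cells_per_sample` cells; each cell is an MSI-like
#' profile with the sample's MSI-like fraction as probability (sample label =
#' MSI iff that fraction exceeds 0.5). Dropout zeroes each entry
#' independently with probability `sc_dropout_rate`, and a `sc_lowq_fraction`
#' of cells keep only ~10% of genes so the quality filter has work to do.
#' Gene-level parameters are shared with [simulate_bulk()] for the same
#' config seed.
#'
#' @param config a [sim_config()]; `n_msi`/`n_mss` count samples here.
#' @param msi_fractions optional explicit per-sample MSI-like cell fractions
#'   (overrides the class ranges; labels derived as fraction > 0.5).
#' @return list with `samples` (list of `list(sample_id, cells, label)`),
#'   `labels` (named vector), `fractions`, and `truth`.
#' @export
simulate_single_cell <- function(config = sim_config(), msi_fractions = NULL) {
  params <- sim_gene_params(config)
  with_seed(config$seed + 2L, {
    if (is.null(msi_fractions)) {
      msi_fractions <- c(
        stats::runif(config$n_msi, config$sc_msi_fraction_range[1L],
                     config$sc_msi_fraction_range[2L]),
        stats::runif(config$n_mss, config$sc_mss_fraction_range[1L],
                     config$sc_mss_fraction_range[2L]))
    }
    ns <- length(msi_fractions)
    sample_ids <- sprintf("SC%03d", seq_len(ns))
    labels <- stats::setNames(ifelse(msi_fractions > 0.5, "MSI", "MSS"),
                              sample_ids)
    samples <- lapply(seq_len(ns), function(j) {
      nc <- config$sc_cells_per_sample
      cell_ids <- sprintf("%s_C%03d", sample_ids[j], seq_len(nc))
      cell_is_msi <- stats::runif(nc) < msi_fractions[j]
      raw <- sim_profiles(params, config, cell_is_msi, cell_ids)
      drop <- matrix(stats::runif(length(raw)) < config$sc_dropout_rate,
                     nrow = nrow(raw))
      raw[drop] <- 0
      n_lowq <- floor(config$sc_lowq_fraction * nc)
      if (n_lowq > 0) {
        lowq <- sample(nc, n_lowq)
        kill <- matrix(stats::runif(nrow(raw) * n_lowq) > 0.10,
                       nrow = nrow(raw))
        raw[, lowq][kill] <- 0
      }
      list(sample_id = sample_ids[j],
           cells = expr_matrix(raw, value_kind = "raw"),
           label = unname(labels[j]))
    })
    list(samples = samples, labels = labels,
         fractions = stats::setNames(msi_fractions, sample_ids),
         truth = params$gene_ids[params$informative])
  })
}
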