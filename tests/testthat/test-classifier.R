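test_that("SMOTE balances class counts and keeps originals bit-exact", {
  set.seed(20)
  x <- matrix(rnorm(25 * 3), 25, 3,
              dimnames = list(sprintf("s%d", 1:25), c("a", "b", "c")))
  labels <- rep(c("MSI", "MSS"), c(5, 20))
  out <- smote_balance(x, labels, k = 3, seed = 20)
  expect_equal(out$n_synthetic, 15)
  expect_equal(as.integer(table(out$labels)), c(20L, 20L))
  expect_identical(out$features[1:25, ], x)
  expect_identical(out$labels[1:25], labels)
})

test_that("every synthetic point lies on a segment between minority points", {
  set.seed(21)
  x <- matrix(rnorm(12 * 2), 12, 2)
  labels <- rep(c("MSI", "MSS"), c(4, 8))
  out <- smote_balance(x, labels, k = 3, seed = 21)
  minority <- x[1:4, , drop = FALSE]
  synth <- out$features[13:16, , drop = FALSE]
  on_some_segment <- function(p) {
    for (i in 1:3) for (j in (i + 1):4) {
      a <- minority[i, ]
      b <- minority[j, ]
      d <- b - a
      u <- if (abs(d[1]) > 1e-12) (p[1] - a[1]) / d[1] else
        (p[2] - a[2]) / d[2]
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(a + u * d - p)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_some_segment)))
})

test_that("SMOTE degenerate inputs follow the contract", {
  x <- matrix(rnorm(20), 10, 2)
  expect_identical(
    smote_balance(x, rep(c("MSI", "MSS"), 5), seed = 1)$n_synthetic, 0L)
  expect_error(smote_balance(x, rep(c("MSI", "MSS"), c(1, 9)), seed = 1),
               "single member")
  expect_warning(
    out <- smote_balance(x, rep(c("MSI", "MSS"), c(3, 7)), k = 5, seed = 1),
    "clamped")
  expect_equal(as.integer(table(out$labels)), c(7L, 7L))
})

test_that("SMOTE is deterministic given the seed", {
  x <- matrix(rnorm(30), 15, 2)
  labels <- rep(c("MSI", "MSS"), c(5, 10))
  expect_identical(smote_balance(x, labels, k = 3, seed = 7),
                   smote_balance(x, labels, k = 3, seed = 7))
})

test_that("Youden threshold matches the worked example and the oracle", {
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9),
                                c("MSS", "MSS", "MSI", "MSI")), 0.5)
  expect_warning(
    t_inv <- youden_threshold(c(0.9, 0.8, 0.1, 0.2),
                              c("MSS", "MSS", "MSI", "MSI")),
    "do not separate")
  t_eq <- suppressWarnings(youden_threshold(rep(0.4, 6),
                                            rep(c("MSI", "MSS"), 3)))
  expect_true(t_eq %in% c(0, 1))

  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c("MSI", "MSS"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(suppressWarnings(youden_threshold(scores, labels)),
                 suppressWarnings(brute_youden(scores, labels)))
  }
  expect_error(youden_threshold(c(0.1, 0.9), c("MSI", "MSI")), "both classes")
})

# shared training fixture: simulator cohort, selected genes, fitted model
clf_fixture <- local({
  cfg <- sim_config(seed = 31)
  sim <- simulate_bulk(cfg)
  sel <- select_informative_genes(sim$cohort, selection_thresholds(seed = 31))
  model <- fit_msi_model(sim$cohort, sel$genes, seed = 31)
  list(cfg = cfg, sim = sim, sel = sel, model = model)
})

test_that("training on a separable cohort yields a near-perfect fit", {
  fx <- clf_fixture
  # with the full planted panel as features the fit is essentially perfect
  full_model <- fit_msi_model(fx$sim$cohort, fx$sim$truth, seed = 31)
  full_preds <- predict(full_model, fx$sim$cohort$matrix)
  expect_gte(roc_auc(full_preds$msi_score, fx$sim$cohort$labels), 0.99)
  # the selected subset still separates the training cohort cleanly
  preds <- predict(fx$model, fx$sim$cohort$matrix)
  expect_gte(roc_auc(preds$msi_score, fx$sim$cohort$labels), 0.95)
  expect_gt(fx$model$threshold, 0)
  expect_lt(fx$model$threshold, 1)
  expect_identical(fx$model$genes, fx$sel$genes)
})

test_that("held-out prediction from the same generator stays accurate", {
  fx <- clf_fixture
  test <- simulate_bulk(sim_config(n_msi = 40, n_mss = 60, seed = 31),
                        cohort_seed = 987654)
  preds <- predict(fx$model, test$cohort$matrix)
  expect_gte(roc_auc(preds$msi_score, test$cohort$labels), 0.95)
  # a sample scored twice gives identical scores
  expect_identical(predict(fx$model, test$cohort$matrix)$msi_score,
                   preds$msi_score)
  # status follows the threshold tie rule: score == threshold calls MSI
  expect_identical(preds$msi_status,
                   ifelse(preds$msi_score >= fx$model$threshold, "MSI", "MSS"))
})

test_that("label-permuted training carries no held-out signal", {
  fx <- clf_fixture
  set.seed(32)
  perm <- msi_cohort(fx$sim$cohort$matrix,
                     stats::setNames(sample(fx$sim$cohort$labels),
                                     names(fx$sim$cohort$labels)))
  null_model <- suppressWarnings(fit_msi_model(perm, fx$sel$genes, seed = 32))
  test <- simulate_bulk(sim_config(n_msi = 50, n_mss = 50, seed = 31),
                        cohort_seed = 13579)
  preds <- predict(null_model, test$cohort$matrix)
  expect_lt(abs(roc_auc(preds$msi_score, test$cohort$labels) - 0.5), 0.15)
})

test_that("retraining with the same seed is byte-identical on disk", {
  fx <- clf_fixture
  m2 <- fit_msi_model(fx$sim$cohort, fx$sel$genes, seed = 31)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  save_model(fx$model, p1)
  save_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("model JSON round-trips with scores preserved to 1e-9", {
  fx <- clf_fixture
  path <- tempfile(fileext = ".json")
  save_model(fx$model, path)
  back <- load_model(path)
  before <- predict(fx$model, fx$sim$cohort$matrix)
  after <- predict(back, fx$sim$cohort$matrix)
  expect_equal(after$msi_score, before$msi_score, tolerance = 1e-9)
  expect_identical(after$msi_status, before$msi_status)
})

test_that("corrupt or mismatched model files are rejected", {
  fx <- clf_fixture
  path <- tempfile(fileext = ".json")
  save_model(fx$model, path)

  txt <- readLines(path)
  trunc <- tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], trunc)
  expect_error(load_model(trunc), "parse")

  wrong_kernel <- tempfile(fileext = ".json")
  writeLines(sub('"radial"', '"sigmoid"', txt), wrong_kernel)
  expect_error(load_model(wrong_kernel), "kernel")

  wrong_version <- tempfile(fileext = ".json")
  writeLines(sub('"format_version": "1.0"', '"format_version": "9.9"', txt),
             wrong_version)
  expect_error(load_model(wrong_version), "version")
})

test_that("missing model genes are tolerated to 10% and refused beyond", {
  fx <- clf_fixture
  mat <- fx$sim$cohort$matrix
  ng <- length(fx$model$genes)
  # drop over half the panel
  drop_many <- fx$model$genes[seq_len(ceiling(ng / 2))]
  crippled <- expr_matrix(mat_values(mat)[setdiff(rownames(mat), drop_many), ],
                          value_kind = "raw")
  expect_error(predict(fx$model, crippled), drop_many[1])
  # models with >= 10 genes tolerate one missing gene with zero-imputation
  if (ng >= 10) {
    drop_one <- fx$model$genes[1]
    thinned <- expr_matrix(mat_values(mat)[setdiff(rownames(mat), drop_one), ],
                           value_kind = "raw")
    expect_warning(preds <- predict(fx$model, thinned), "imputed z = 0")
    expect_true(all(preds$msi_score >= 0 & preds$msi_score <= 1))
  }
})

test_that("scores are invariant to gene row order on identical panels", {
  fx <- clf_fixture
  mat <- fx$sim$cohort$matrix
  set.seed(33)
  shuffled <- expr_matrix(mat_values(mat)[sample(nrow(mat)), ],
                          value_kind = "raw")
  expect_equal(predict(fx$model, shuffled)$msi_score,
               predict(fx$model, mat)$msi_score, tolerance = 1e-12)
})
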