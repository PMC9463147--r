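test_that("SSM encoding applies the strict VAF filter and impact flag", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2", "S2"),
    gene = c("TP53", "KRAS", "KRAS", "TP53", "OFFPANEL", "APC"),
    vaf = c(0.04, 0.2, 0.5, 0.051, 0.9, 0.3),
    impact = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  X <- encode_ssm_features(calls, panel = c("TP53", "KRAS", "APC"))
  expect_equal(attr(X, "encoding"), "binary")
  expect_equal(X["S1", "TP53"], 0L)      # VAF 0.04 filtered
  expect_equal(X["S1", "KRAS"], 1L)      # two hits still 1
  expect_equal(X["S2", "TP53"], 1L)      # 0.051 > 0.05
  expect_equal(X["S2", "APC"], 0L)       # impact FALSE
  expect_false("OFFPANEL" %in% colnames(X))
  X2 <- encode_ssm_features(calls, panel = c("TP53", "KRAS", "APC"),
                            require_impact = FALSE)
  expect_equal(X2["S2", "APC"], 1L)
})

test_that("CNV encoding resolves overlaps by covered fraction", {
  panel <- data.frame(gene = c("INAMP", "NONE", "SPLIT"),
                      chrom = c("chr1", "chr2", "chr3"),
                      start = c(0, 0, 0), end = c(1e4, 1e4, 1e4))
  segs <- data.frame(
    sample_id = "S1",
    chrom = c("chr1", "chr3", "chr3"),
    start = c(0, 0, 7e3), end = c(1e6, 7e3, 1e4),
    call = c(1L, -1L, 1L))
  X <- encode_cnv_features(segs, panel)
  expect_equal(X["S1", "INAMP"], 1L)
  expect_equal(X["S1", "NONE"], 0L)
  expect_equal(X["S1", "SPLIT"], -1L)    # 70% deleted beats 30% amplified
  # exact tie goes neutral
  tie <- data.frame(sample_id = "S1", chrom = "chr3",
                    start = c(0, 5e3), end = c(5e3, 1e4),
                    call = c(-1L, 1L))
  Xt <- encode_cnv_features(tie, panel["SPLIT" == panel$gene, ])
  expect_equal(Xt["S1", "SPLIT"], 0L)
})

test_that("expression encoding is CPM on a log2 scale", {
  counts <- matrix(c(100L, 900L, 0L,
                     200L, 1800L, 0L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  X <- encode_expression_features(counts)
  expect_equal(X["A", "g1"], log2(100 * 1e6 / 1000 + 1))
  # doubling a sample's counts leaves its CPMs unchanged
  expect_equal(X["A", ], X["B", ], tolerance = 1e-12)
  # all-zero gene becomes the constant log2(pseudocount)
  expect_equal(unname(X[, "g3"]), rep(log2(1), 2))
  bad <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "A"))
  expect_error(encode_expression_features(bad), "library size")
})

test_that("the lasso path starts empty and orders entries by lambda", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("G", 1:10)))
  y <- as.numeric(scale(X[, "G3"])) + rnorm(n, 0, 0.3)
  m <- fit_lasso_signature(X, y, seed = 1)
  expect_s3_class(m, "signature_model")
  # all-zero solution at lambda_max
  beta_at_max <- as.matrix(m$cv$glmnet.fit$beta)[, 1]
  expect_true(all(beta_at_max == 0))
  # the true predictor enters first
  expect_equal(unname(m$entry_order["G3"]), 1L)
  expect_true("G3" %in% names(m$selected))
  expect_gt(m$train_r2, 0.8)
  # near-saturated lambda -> near least-squares on the selected support
  expect_error(fit_lasso_signature(X[1:5, ], y[1:5]), "folds")
  expect_error(fit_lasso_signature(X, rep(1, n)), "constant")
})

test_that("entry order and fit are deterministic under a fixed seed", {
  fc <- simulate_feature_cohort(n = 120, seed = 9)
  m1 <- suppressMessages(fit_lasso_signature(fc$X, fc$y, seed = 5))
  m2 <- suppressMessages(fit_lasso_signature(fc$X, fc$y, seed = 5))
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$entry_order, m2$entry_order)
  expect_identical(m1$lambda_opt, m2$lambda_opt)
})

test_that("predictions reproduce the training fit and map rows", {
  fc <- simulate_feature_cohort(n = 120, seed = 2)
  m <- suppressMessages(fit_lasso_signature(fc$X, fc$y, seed = 2))
  pred <- predict_ith(m, fc$X)
  r2 <- 1 - sum((fc$y - pred)^2) / sum((fc$y - mean(fc$y))^2)
  expect_equal(r2, m$train_r2, tolerance = 1e-12)
  # shuffling sample order permutes predictions identically
  idx <- sample(nrow(fc$X))
  expect_equal(unname(predict_ith(m, fc$X[idx, ])), unname(pred[idx]))
  expect_error(predict_ith(m, fc$X[, 1:3]), "missing")
})

test_that("evaluation reports Pearson r and explained variance", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_predictions(y, y)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$r2, 1)
  anti <- evaluate_predictions(y, -y + 6)
  expect_equal(anti$pearson_r, -1)
  expect_warning(flat <- evaluate_predictions(y, rep(2, 5)), "constant")
  expect_true(is.na(flat$pearson_r))
  expect_lte(flat$r2, 0)
  expect_error(evaluate_predictions(rep(1, 5), y), "zero variance")
})

test_that("signatures transfer across independent cohorts", {
  fc <- simulate_feature_cohort(seed = 3)
  m <- suppressMessages(fit_lasso_signature(fc$X, fc$y, seed = 3))
  ev_b <- transfer_evaluation(m, fc$X_b, fc$y_b)
  expect_gte(ev_b$pearson_r, 0.8)
  # transfer to the training cohort equals the training evaluation
  ev_a <- transfer_evaluation(m, fc$X, fc$y)
  expect_equal(ev_a$r2, m$train_r2, tolerance = 1e-12)
  # outcome with the signature zeroed: no transferable signal
  null_y <- withr::with_seed(99, rnorm(nrow(fc$X_b), 0, 0.5))
  expect_lt(abs(transfer_evaluation(m, fc$X_b, null_y)$pearson_r), 0.2)
})

test_that("signature models round-trip through JSON", {
  fc <- simulate_feature_cohort(n = 100, seed = 6)
  m <- suppressMessages(fit_lasso_signature(fc$X, fc$y, seed = 6))
  f <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, f)
  m2 <- read_signature_model(f)
  expect_equal(m2$selected, m$selected)
  expect_equal(m2$entry_order, m$entry_order)
  expect_equal(unname(predict_ith(m2, fc$X)), unname(predict_ith(m, fc$X)))
})
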