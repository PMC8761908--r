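test_that("metric panel matches hand-computed confusion arithmetic", {
  m <- compute_metrics(9, 4, 1, 1)
  expect_equal(round(m$accuracy, 2), 0.67)
  expect_equal(round(m$precision, 2), 0.69)
  expect_equal(round(m$recall, 2), 0.90)
  expect_equal(round(m$f1, 2), 0.78)
  expect_equal(round(m$specificity, 2), 0.20)
  expect_identical(m$recall, m$sensitivity)
  # perfect classifier
  p <- compute_metrics(10, 0, 5, 0, scores = c(rep(1, 10), rep(0, 5)),
                       truths = c(rep("SF", 10), rep("NSF", 5)))
  expect_true(all(unlist(p) == 1))
  # constant scores give midrank AUC 0.5
  q <- compute_metrics(5, 5, 0, 0, scores = rep(2, 10),
                       truths = rep(c("SF", "NSF"), 5))
  expect_equal(q$auc, 0.5)
  # undefined ratios are NA, never 0
  u <- compute_metrics(0, 0, 5, 5)
  expect_true(is.na(u$precision))
  expect_true(is.na(u$f1))
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
  expect_error(compute_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  withr::local_seed(21)
  for (i in 1:5) {
    sc <- rnorm(60)
    tr <- sample(c("SF", "NSF"), 60, replace = TRUE)
    a1 <- compute_metrics(1, 1, 1, 1, scores = sc, truths = tr)$auc
    a2 <- as.numeric(pROC::auc(pROC::roc(tr, sc, levels = c("NSF", "SF"),
                                         direction = "<", quiet = TRUE)))
    expect_equal(a1, a2)
  }
})

test_that("stratified folds are disjoint, covering, and class-balanced", {
  y <- c(rep("SF", 52), rep("NSF", 22))
  f <- stratified_folds(y, 5, seed = 2)
  expect_setequal(unique(f), 1:5)
  expect_equal(length(f), 74)
  for (k in 1:5) {
    expect_true(all(table(y[f == k]) >= 1))
    expect_true(sum(f == k) %in% 14:16)
  }
  expect_identical(f, stratified_folds(y, 5, seed = 2))
  expect_false(identical(f, stratified_folds(y, 5, seed = 3)))
  expect_error(stratified_folds(c("SF", "SF", "NSF"), 2, 1), "smaller class")
})

test_that("a planted informative feature is ranked first by both models", {
  for (family in c("gbdt", "svm")) {
    hits <- 0
    for (s in 1:10) {
      fm <- toy_feature_matrix(n_sf = 40, n_nsf = 40, n_feat = 10,
                               effect = 3, seed = s)
      model <- if (family == "gbdt") {
        oxceeg:::.fit_gbdt(fm$values, as.character(fm$labels), seed = s)
      } else {
        oxceeg:::.fit_svm(scale(fm$values), as.character(fm$labels), 1)
      }
      r <- rank_features(model, fm$feature_names)
      hits <- hits + (r$feature[1] == "f1")
    }
    expect_gte(hits, 9)
  }
})

test_that("duplicated feature columns get adjacent ranks deterministically", {
  fm <- toy_feature_matrix(n_sf = 30, n_nsf = 30, n_feat = 6, effect = 2,
                           seed = 4)
  X <- cbind(fm$values, f1_copy = fm$values[, "f1"])
  m <- oxceeg:::.fit_svm(scale(X), as.character(fm$labels), 1)
  r <- rank_features(m, colnames(X))
  pos <- match(c("f1", "f1_copy"), r$feature)
  expect_lte(abs(diff(pos)), 1)
  r2 <- rank_features(m, colnames(X))
  expect_identical(r, r2)
  expect_equal(nrow(head(r, 10)), 7)  # top-10 view capped by feature count
  expect_error(rank_features(lm(rnorm(5) ~ 1), "x"), "unsupported")
})

test_that("cross-validation reports satisfy the confusion-matrix identities", {
  fm <- toy_feature_matrix(n_sf = 26, n_nsf = 14, effect = 2, seed = 6)
  for (family in c("gbdt", "svm")) {
    rep <- run_cv(fm, model_config(family, seed = 11), smote_params(seed = 12))
    sizes <- table(rep$fold_assignment)
    for (fr in rep$folds) {
      cm <- fr$confusion
      expect_equal(sum(cm), unname(sizes[fr$fold_index]))
      m <- fr$metrics
      expect_equal(m$recall, m$sensitivity)
      if (!is.na(m$f1)) {
        expect_equal(m$f1, 2 * m$precision * m$recall /
                       (m$precision + m$recall))
      }
      expect_true(all(unlist(m)[!is.na(unlist(m))] >= 0))
      expect_true(all(unlist(m)[!is.na(unlist(m))] <= 1))
    }
    # report means are the arithmetic fold averages, not pooled metrics
    expect_equal(rep$means$accuracy,
                 mean(vapply(rep$folds, function(f) f$metrics$accuracy, 0)))
    # determinism under identical seeds
    rep2 <- run_cv(fm, model_config(family, seed = 11), smote_params(seed = 12))
    expect_equal(rep$means, rep2$means)
    expect_identical(vapply(rep$folds, `[[`, "", "state_checksum"),
                     vapply(rep2$folds, `[[`, "", "state_checksum"))
  }
})

test_that("a strong planted effect is recovered with high AUC", {
  fm <- toy_feature_matrix(n_sf = 26, n_nsf = 14, effect = 4, seed = 8)
  rep <- run_cv(fm, model_config("gbdt", seed = 3), smote_params(seed = 3))
  expect_gte(rep$means$auc, 0.9)
})

test_that("train-only state recomputation reproduces the fold checksums", {
  fm <- toy_feature_matrix(n_sf = 26, n_nsf = 14, effect = 1, seed = 10)
  for (family in c("gbdt", "svm")) {
    config <- model_config(family, seed = 21)
    smote <- smote_params(seed = 22)
    rep <- run_cv(fm, config, smote)
    folds <- stratified_folds(as.character(fm$labels), config$n_folds,
                              seed = config$seed)
    expect_identical(folds, rep$fold_assignment)
    for (fr in rep$folds) {
      tr <- folds != fr$fold_index
      fit <- oxceeg:::.fit_fold(fm$values[tr, , drop = FALSE],
                                as.character(fm$labels)[tr], config, smote,
                                oxceeg:::derive_seed(config$seed,
                                                     fr$fold_index))
      state <- list(scaler = fit$scaler, smote_X = fit$smote$X,
                    smote_y = fit$smote$y, rfe_selected = fit$selected)
      expect_identical(oxceeg:::.state_checksum(state), fr$state_checksum)
    }
  }
})

test_that("model configuration rejects invalid settings", {
  expect_error(model_config("gbdt", svm_c = 0), "svm_c")
  expect_error(model_config("svm", n_folds = 1), "n_folds")
  expect_error(run_cv(toy_feature_matrix(n_sf = 4, n_nsf = 3),
                      model_config("gbdt", n_folds = 5)), "smaller class")
})
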