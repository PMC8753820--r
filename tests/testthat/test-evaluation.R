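test_that("metrics follow the printed formulas and handle degenerate counts", {
  m <- classification_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1,
                            f_measure = 1, mcc = 1))
  # label-independent predictions on balanced data
  m0 <- classification_metrics(list(TP = 5, FP = 5, TN = 5, FN = 5))
  expect_equal(m0$mcc, 0)

  m1 <- classification_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m1$accuracy, 0.7)
  expect_equal(m1$precision, 0.75)
  expect_equal(m1$recall, 0.6)
  expect_equal(m1$f_measure, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m1$mcc, (3 * 4 - 1 * 2) / sqrt(5 * 5 * 4 * 6))

  # zero-denominator cases return 0 with warnings, not NaN
  w <- capture_warnings(
    m2 <- classification_metrics(list(TP = 0, FP = 0, TN = 4, FN = 2))
  )
  expect_match(w, "precision", all = FALSE)
  expect_equal(m2$precision, 0)
  expect_equal(m2$mcc, 0)
  expect_false(anyNA(unlist(m2)))
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("confusion counts match a brute-force recount", {
  set.seed(7)
  for (r in 1:10) {
    truth <- sample(c(-1, 1), 50, replace = TRUE)
    pred <- sample(c(-1, 1), 50, replace = TRUE)
    cc <- confusion_counts(pred, truth)
    expect_equal(cc$TP, sum(pred == 1 & truth == 1))
    expect_equal(cc$FN, sum(pred == -1 & truth == 1))
    expect_equal(cc$P + cc$N, 50)
    m <- suppressWarnings(classification_metrics(cc))
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("the two MCC denominator forms agree on an exhaustive count grid", {
  # all confusion tables with entries <= 20 (vectorized exhaustive sweep)
  g <- expand.grid(TP = 0:20, FP = 0:20, TN = 0:20, FN = 0:20)
  g <- g[g$TP + g$FP + g$TN + g$FN > 0, ]
  with(g, {
    P <- TP + FN; N <- TN + FP
    den_pn <- sqrt(P * N * (TP + FP) * (TN + FN))
    den_std <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    ok <- den_pn > 0
    mcc_pn <- (TP * TN - FP * FN)[ok] / den_pn[ok]
    mcc_std <- (TP * TN - FP * FN)[ok] / den_std[ok]
    expect_equal(mcc_pn, mcc_std, tolerance = 1e-12)
    expect_true(all(abs(mcc_pn) <= 1 + 1e-12))
  })
  # spot-check the package implementation against the standard form
  set.seed(8)
  for (r in 1:25) {
    cnt <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                            c("TP", "FP", "TN", "FN")))
    if (sum(unlist(cnt)) == 0) next
    m <- suppressWarnings(classification_metrics(cnt))
    den <- sqrt((cnt$TP + cnt$FP) * (cnt$TP + cnt$FN) *
                (cnt$TN + cnt$FP) * (cnt$TN + cnt$FN))
    exp_mcc <- if (den == 0) 0 else (cnt$TP * cnt$TN - cnt$FP * cnt$FN) / den
    expect_equal(m$mcc, exp_mcc)
  }
})

test_that("AUC equals the concordant-pair oracle and is rank-invariant", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(roc_auc(c(0, 1, 2, 3), c(1, 1, -1, -1)), 0)
  set.seed(9)
  for (r in 1:5) {
    n <- 200
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(-1, 1), n, replace = TRUE)
    pos <- which(labels == 1); neg <- which(labels == -1)
    # O(n^2) pair-counting oracle, ties count one half
    conc <- outer(scores[pos], scores[neg], ">") +
      0.5 * outer(scores[pos], scores[neg], "==")
    expect_equal(roc_auc(scores, labels), mean(conc))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(roc_auc(exp(scores) + 5, labels), roc_auc(scores, labels))
  }
  # independent reference implementation
  set.seed(19)
  scores <- rnorm(150); labels <- sample(c(-1, 1), 150, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(-1, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("average precision matches a step-by-step oracle", {
  expect_equal(average_precision(c(3, 2, 1), c(1, 1, -1)), 1)
  set.seed(10)
  for (r in 1:5) {
    n <- 60
    scores <- rnorm(n)  # continuous: no ties
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (sum(labels == 1) == 0) next
    o <- order(scores, decreasing = TRUE)
    y <- labels[o] == 1
    prec_at <- cumsum(y) / seq_len(n)
    oracle <- sum(prec_at[y]) / sum(y)  # recall increments of 1/n_pos
    expect_equal(average_precision(scores, labels), oracle)
  }
})

test_that("cross-validation folds are stratified, disjoint, and seeded", {
  inst <- simulate_hetnet(n_d = 30, n_t = 40, k_true = 3, seed = 4)
  lab <- inst$labels
  f1 <- combonet:::stratified_folds(lab, 5, seed = 42)
  f2 <- combonet:::stratified_folds(lab, 5, seed = 42)
  expect_identical(f1, f2)
  all_idx <- sort(unlist(f1))
  expect_equal(all_idx, seq_len(nrow(lab)))          # union = everything
  expect_equal(anyDuplicated(unlist(f1)), 0L)        # disjoint
  sizes <- lengths(f1)
  expect_lte(max(sizes) - min(sizes), 2L)            # balanced per class strata
  # class balance roughly preserved per fold
  for (f in f1) {
    expect_gt(sum(lab$label[f] == 1), 0)
    expect_gt(sum(lab$label[f] == -1), 0)
  }
  expect_error(combonet:::stratified_folds(
    combination_labels(c(1, 2), c(2, 3), c(1, -1), letters[1:3]), 10, 1),
    "fewer folds")
})

test_that("kfold_cv fits on train pairs only and reports means", {
  inst <- simulate_hetnet(n_d = 30, n_t = 40, k_true = 3, seed = 5)
  cv <- kfold_cv(inst$net, inst$labels,
                 train_config(k = 4, seed = 5, max_outer_iter = 10),
                 folds = 3, seed = 9)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$per_fold), 3L)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_equal(sum(cv$per_fold$n_test), nrow(inst$labels))
  expect_true(all(c("accuracy", "mcc", "auc", "ap") %in% names(cv$mean)))
  # JSON report writes and parses
  path <- tempfile(fileext = ".json")
  write_metrics_json(cv, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$per_fold$auc), 3L)
})
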