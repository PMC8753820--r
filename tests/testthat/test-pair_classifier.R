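test_that("pair features are symmetric and standardization is guarded", {
  expect_equal(pair_feature(c(1, 2), c(3, 4)), c(3, 8, 2, 2))
  set.seed(1)
  for (r in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pair_feature(x, y), pair_feature(y, x))
  }
  x <- rnorm(4)
  expect_equal(pair_feature(x, x), c(x * x, rep(0, 4)))
  expect_error(pair_feature(1:3, 1:4), "length mismatch")

  # aggregation: concatenation then column standardization
  W_d <- diag(2); W_t <- 2 * diag(2)
  raw <- cbind(W_d, W_t)
  emb <- aggregate_embedding(W_d, W_t)
  expect_equal(sweep(sweep(raw, 2, emb$center, "-"), 2, emb$scale, "/"),
               emb$E, ignore_attr = TRUE)
  set.seed(2)
  A <- matrix(runif(12), 6, 2); B <- matrix(runif(12), 6, 2)
  emb2 <- aggregate_embedding(A, B)
  expect_equal(unname(colMeans(emb2$E)), rep(0, 4))
  expect_equal(unname(apply(emb2$E, 2, sd)), rep(1, 4))
  # constant column stays at zero, no division blow-up
  A[, 1] <- 0.3
  emb3 <- aggregate_embedding(A, B)
  expect_equal(unname(emb3$E[, 1]), rep(0, 6))
  expect_true(all(is.finite(emb3$E)))
})

test_that("hinge loss follows the margin", {
  expect_equal(hinge_loss(2, 1), 0)
  expect_equal(hinge_loss(0, 1), 1)
  expect_equal(hinge_loss(0, -1), 1)
  expect_equal(hinge_loss(-1, 1), 2)
  expect_equal(hinge_loss(c(2, -1), c(1, 1)), c(0, 2))
  expect_error(hinge_loss(1, 0), "-1/\\+1")
})

test_that("SVM training is oriented, deterministic, and rejects one class", {
  set.seed(3)
  # linearly separable toy set
  X <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- rep(c(1, -1), each = 20)
  clf <- train_classifier(X, y, kernel = "linear", C = 10)
  pred <- ifelse(decision_scores(clf, X) > 0, 1, -1)
  expect_equal(pred, y)

  # analytic decision values equal the libsvm ones
  dv <- attr(predict(clf$model, X, decision.values = TRUE), "decision.values")
  expect_equal(decision_scores(clf, X), clf$orientation * as.numeric(dv),
               tolerance = 1e-10, ignore_attr = TRUE)

  # flipped labels negate the scores (linear kernel)
  clf_f <- train_classifier(X, -y, kernel = "linear", C = 10)
  expect_equal(decision_scores(clf_f, X), -decision_scores(clf, X),
               tolerance = 1e-6)

  # duplicating every sample leaves the linear decision function unchanged
  clf_d <- train_classifier(rbind(X, X), c(y, y), kernel = "linear", C = 10)
  expect_equal(decision_scores(clf_d, X), decision_scores(clf, X),
               tolerance = 1e-4)

  expect_error(train_classifier(X, rep(1, 40)), "both classes")
})

test_that("analytic decision values match libsvm for all SVM kernels", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- ifelse(X[, 1] + X[, 2] > 0, 1, -1)
  for (kern in c("linear", "polynomial", "rbf")) {
    clf <- train_classifier(X, y, kernel = kern)
    dv <- attr(predict(clf$model, X, decision.values = TRUE), "decision.values")
    expect_equal(decision_scores(clf, X), clf$orientation * as.numeric(dv),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("classifier subgradient matches finite differences through the chain", {
  set.seed(11)
  n_d <- 8; k <- 3
  W_d <- matrix(runif(n_d * k), n_d, k)
  W_t <- matrix(runif(n_d * k), n_d, k)
  drugs <- sprintf("d%d", 1:n_d)
  lab <- combination_labels(c(1, 2, 3, 5, 1, 4), c(2, 3, 4, 6, 7, 8),
                            c(1, -1, 1, -1, 1, -1), drugs)
  for (kern in c("linear", "polynomial", "rbf", "logistic")) {
    # train on jittered factors so no pair sits exactly on the margin,
    # where the hinge is non-differentiable and finite differences are
    # ill-defined
    set.seed(12)
    emb0 <- aggregate_embedding(W_d + 0.05 * matrix(runif(n_d * k), n_d, k),
                                W_t, train_drugs = c(lab$i, lab$j))
    Fm0 <- combonet:::pair_feature_matrix(emb0$E, lab$i, lab$j)
    clf <- train_classifier(Fm0, lab$label, kernel = kern)

    emb <- aggregate_embedding(W_d, W_t, train_drugs = c(lab$i, lab$j))
    Fm <- combonet:::pair_feature_matrix(emb$E, lab$i, lab$j)
    expect_gt(min(abs(1 - lab$label * decision_scores(clf, Fm))), 1e-4)

    sg <- classifier_subgradient(emb, clf, lab)
    lc <- function(Wd_new, Wt_new) {
      E <- sweep(sweep(cbind(Wd_new, Wt_new), 2, emb$center, "-"),
                 2, emb$scale, "/")
      F2 <- cbind(E[lab$i, ] * E[lab$j, ], abs(E[lab$i, ] - E[lab$j, ]))
      sum(hinge_loss(decision_scores(clf, F2), lab$label))
    }
    expect_lt(max_rel_err(sg$W_d, fd_grad(function(X) lc(X, W_t), W_d)), 1e-4)
    expect_lt(max_rel_err(sg$W_t, fd_grad(function(X) lc(W_d, X), W_t)), 1e-4)
  }
})

test_that("satisfied margins and uninvolved drugs contribute zero subgradient", {
  set.seed(13)
  n_d <- 6; k <- 2
  W_d <- matrix(runif(n_d * k), n_d, k)
  W_t <- matrix(runif(n_d * k), n_d, k)
  drugs <- sprintf("d%d", 1:n_d)
  lab <- combination_labels(c(1, 2), c(2, 3), c(1, -1), drugs)
  emb <- aggregate_embedding(W_d, W_t, train_drugs = c(lab$i, lab$j))
  Fm <- combonet:::pair_feature_matrix(emb$E, lab$i, lab$j)
  clf <- train_classifier(Fm, lab$label, kernel = "linear", C = 1)
  # scale the decision function far beyond the margin by a fake classifier:
  # all margins >= 1 <=> zero subgradient
  scores <- decision_scores(clf, Fm)
  if (all(1 - lab$label * scores <= 0)) {
    sg <- classifier_subgradient(emb, clf, lab)
    expect_equal(sg$W_d, matrix(0, n_d, k))
  }
  # drugs 4..6 appear in no pair: their rows are always zero
  sg <- classifier_subgradient(emb, clf, lab)
  expect_equal(sg$W_d[4:6, ], matrix(0, 3, k))
  expect_equal(sg$W_t[4:6, ], matrix(0, 3, k))
})

test_that("prediction is order-symmetric and survives persistence", {
  set.seed(14)
  n_d <- 10; k <- 3
  W_d <- matrix(runif(n_d * k), n_d, k)
  W_t <- matrix(runif(n_d * k), n_d, k)
  drugs <- sprintf("d%d", 1:n_d)
  lab <- combination_labels(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 1, -1, -1), drugs)
  emb <- aggregate_embedding(W_d, W_t, train_drugs = c(lab$i, lab$j))
  Fm <- combonet:::pair_feature_matrix(emb$E, lab$i, lab$j)
  clf <- train_classifier(Fm, lab$label)

  set.seed(15)
  pi_ <- sample(n_d, 100, replace = TRUE)
  pj <- sapply(pi_, function(i) sample(setdiff(1:n_d, i), 1))
  s_ij <- predict(clf, emb, cbind(pi_, pj))$score
  s_ji <- predict(clf, emb, cbind(pj, pi_))$score
  expect_equal(s_ij, s_ji)

  # empty pair list
  expect_equal(nrow(predict(clf, emb, matrix(0, 0, 2))), 0L)

  # persistence round trip reproduces scores exactly
  path <- tempfile(fileext = ".rds")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  expect_equal(predict(clf2, emb, cbind(pi_, pj))$score, s_ij)
})
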