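# Drug-pair feature construction, hinge-loss kernel classifier, and the
# classifier subgradient with respect to the embeddings (the coupling term
# of the joint objective).
#
# The decision function is phi(E_i, E_j) = f(pair_feature(E_i, E_j)) where f
# is a kernel SVM (or a logistic-loss linear model) on the symmetric pair
# feature [E_i * E_j, |E_i - E_j|].  SVM training is delegated to
# e1071/libsvm; the decision value and its gradient with respect to the
# feature vector are recomputed analytically here because joint learning
# needs d phi / d E, which libsvm does not expose.

#' Aggregate the two drug factor matrices into one embedding
#'
#' Concatenates the drug factors from the similarity network (`W_d`) and
#' from the drug-target network (`W_t`) row-wise into an `n_d x 2k` matrix,
#' then standardizes each column to zero mean and unit variance.  The
#' statistics are computed from the drugs appearing in training pairs only
#' (when `train_drugs` is given), so held-out pairs never influence the
#' transform; columns with (near-)zero variance are centered and left
#' unscaled.
#'
#' @param W_d,W_t nonnegative `n_d x k` factor matrices.
#' @param train_drugs optional integer vector of drug indices whose rows
#'   define the standardization statistics (default: all drugs).
#' @param center,scale optional precomputed statistics (vectors of length
#'   `2k`) overriding the computation, e.g. to transform new factors with
#'   the training-time statistics.
#' @return An object of class `drug_embedding`: list with the standardized
#'   matrix `E` (`n_d x 2k`), `center`, `scale` (the guarded divisor
#'   actually applied), and `k`.
#' @export
aggregate_embedding <- function(W_d, W_t, train_drugs = NULL,
                                center = NULL, scale = NULL) {
  if (!all(dim(W_d) == dim(W_t))) {
    stop("W_d and W_t must have identical shapes", call. = FALSE)
  }
  raw <- cbind(W_d, W_t)
  if (is.null(center) || is.null(scale)) {
    rows <- if (is.null(train_drugs)) seq_len(nrow(raw)) else unique(as.integer(train_drugs))
    sub <- raw[rows, , drop = FALSE]
    center <- colMeans(sub)
    sdev <- apply(sub, 2L, stats::sd)
    scale <- ifelse(!is.finite(sdev) | sdev < 1e-12, 1, sdev)
  }
  E <- sweep(sweep(raw, 2L, center, "-"), 2L, scale, "/")
  colnames(E) <- NULL
  structure(list(E = E, center = center, scale = scale, k = ncol(W_d)),
            class = "drug_embedding")
}

#' Symmetric pair feature of two drug embeddings
#'
#' Maps two embedding vectors to the concatenation of their elementwise
#' product and elementwise absolute difference.  Both blocks are invariant
#' under swapping the two drugs, so every downstream decision score is
#' order-symmetric by construction.
#'
#' @param e_i,e_j numeric vectors of equal length `d`.
#' @return Numeric vector of length `2d`.
#' @export
#' @examples
#' pair_feature(c(1, 2), c(3, 4))  # 3 8 2 2
pair_feature <- function(e_i, e_j) {
  if (length(e_i) != length(e_j)) {
    stop("embedding length mismatch", call. = FALSE)
  }
  c(e_i * e_j, abs(e_i - e_j))
}

pair_feature_matrix <- function(E, i, j) {
  Ei <- E[i, , drop = FALSE]
  Ej <- E[j, , drop = FALSE]
  cbind(Ei * Ej, abs(Ei - Ej))
}

#' Hinge loss of a decision score
#'
#' `max(0, 1 - label * score)`: zero when the pair is classified with a
#' margin of at least 1, linear in the violation otherwise.
#'
#' @param score numeric decision score(s).
#' @param label label(s) in `{-1, +1}`.
#' @return Nonnegative numeric vector.
#' @export
hinge_loss <- function(score, label) {
  if (any(label != 1 & label != -1)) stop("labels must be -1/+1", call. = FALSE)
  pmax(0, 1 - label * score)
}

#' Train the drug-pair classifier
#'
#' Fits a soft-margin kernel SVM (via \pkg{e1071}/libsvm) or a
#' logistic-loss linear model on pair features.  Kernels: `"linear"`,
#' `"polynomial"` (the default, degree 3, matching the best-performing
#' configuration), `"rbf"`, and `"logistic"` (a logistic-regression linear
#' model behind the same interface).
#'
#' @param features numeric matrix, one row per labeled pair.
#' @param labels vector in `{-1, +1}`, both classes present.
#' @param kernel kernel name (see above).
#' @param C soft-margin cost (SVM kernels only).
#' @param degree,gamma,coef0 kernel parameters; `gamma` defaults to
#'   `1 / ncol(features)`.
#' @return An object of class `pair_classifier`.
#' @export
train_classifier <- function(features, labels,
                             kernel = c("polynomial", "linear", "rbf", "logistic"),
                             C = 1, degree = 3, gamma = NULL, coef0 = 1) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (any(labels != 1L & labels != -1L)) stop("labels must be -1/+1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train the classifier", call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(features)

  if (kernel == "logistic") {
    y01 <- as.integer(labels == 1L)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, features), y01, family = stats::binomial())
    )
    beta <- fit$coefficients
    beta[!is.finite(beta)] <- 0
    obj <- list(kernel = kernel, beta = beta, dim = ncol(features))
  } else {
    svm_kernel <- switch(kernel, linear = "linear", polynomial = "polynomial",
                         rbf = "radial")
    y <- factor(ifelse(labels == 1L, "pos", "neg"), levels = c("pos", "neg"))
    model <- e1071::svm(x = features, y = y, type = "C-classification",
                        kernel = svm_kernel, cost = C, degree = degree,
                        gamma = gamma, coef0 = coef0, scale = FALSE,
                        probability = FALSE)
    dv <- attr(stats::predict(model, features[1L, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    orientation <- if (colnames(dv)[1L] == "pos/neg") 1 else -1
    obj <- list(kernel = kernel, model = model, orientation = orientation,
                C = C, degree = degree, gamma = gamma, coef0 = coef0,
                dim = ncol(features))
  }
  class(obj) <- "pair_classifier"
  obj
}

#' Decision scores of a trained pair classifier
#'
#' Evaluates `phi(x) = <theta, K(., x)>` analytically from the stored dual
#' coefficients and support vectors (or the logistic weight vector),
#' oriented so that a positive score predicts the synergistic class (+1).
#'
#' @param clf a [train_classifier()] result.
#' @param features numeric matrix of pair features (one row per pair).
#' @return Numeric vector of decision scores.
#' @export
decision_scores <- function(clf, features) {
  stopifnot(inherits(clf, "pair_classifier"))
  X <- as.matrix(features)
  if (ncol(X) != clf$dim) stop("feature width mismatch", call. = FALSE)
  if (clf$kernel == "logistic") {
    return(drop(cbind(1, X) %*% clf$beta))
  }
  m <- clf$model
  SV <- m$SV
  coefs <- as.numeric(m$coefs)
  raw <- switch(clf$kernel,
    linear = drop(X %*% (t(SV) %*% coefs)),
    polynomial = {
      G <- (clf$gamma * (X %*% t(SV)) + clf$coef0)^clf$degree
      drop(G %*% coefs)
    },
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * (X %*% t(SV))
      drop(exp(-clf$gamma * pmax(d2, 0)) %*% coefs)
    })
  clf$orientation * (raw - m$rho)
}

# d score / d x for every row of `features`; same orientation as
# decision_scores.
decision_gradient_features <- function(clf, features) {
  X <- as.matrix(features)
  if (nrow(X) == 0L) return(matrix(0, 0L, clf$dim))
  if (clf$kernel == "logistic") {
    return(matrix(clf$beta[-1L], nrow(X), clf$dim, byrow = TRUE))
  }
  m <- clf$model
  SV <- m$SV
  coefs <- as.numeric(m$coefs)
  G <- switch(clf$kernel,
    linear = {
      w <- drop(t(SV) %*% coefs)
      matrix(w, nrow(X), length(w), byrow = TRUE)
    },
    polynomial = {
      inner <- clf$gamma * (X %*% t(SV)) + clf$coef0
      weights <- sweep(inner^(clf$degree - 1), 2L, coefs, "*")
      clf$degree * clf$gamma * (weights %*% SV)
    },
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * (X %*% t(SV))
      K <- exp(-clf$gamma * pmax(d2, 0))
      KC <- sweep(K, 2L, coefs, "*")
      2 * clf$gamma * (KC %*% SV - X * rowSums(KC))
    })
  clf$orientation * G
}

#' Classifier subgradient with respect to the drug factors
#'
#' For each labeled pair with an active hinge (`1 - c_ij * phi > 0`),
#' accumulates `-c_ij * d phi / d E_i` and `-c_ij * d phi / d E_j`, routed
#' through the pair-feature map and the standardization transform, and
#' splits the result into the `W_d`-block and `W_t`-block columns.  The
#' classifier parameters are held fixed (alternating scheme): the gradient
#' flows only through the pair features.  Pairs with satisfied margins and
#' drugs appearing in no labeled pair contribute zero rows.
#'
#' @param emb an [aggregate_embedding()] result built from the current
#'   factors (its `center`/`scale` are the fixed transform).
#' @param clf a trained [train_classifier()].
#' @param labels a [combination_labels] object.
#' @return List with matrices `W_d` and `W_t` (`n_d x k` each): the
#'   subgradient of the summed hinge loss w.r.t. each factor (unweighted;
#'   the trainer scales by `lambda2`).
#' @export
classifier_subgradient <- function(emb, clf, labels) {
  stopifnot(inherits(emb, "drug_embedding"), inherits(clf, "pair_classifier"))
  E <- emb$E
  k <- emb$k
  d <- 2L * k
  n_d <- nrow(E)
  G_E <- matrix(0, n_d, d)
  if (nrow(labels) > 0L) {
    i <- labels$i; j <- labels$j; lab <- labels$label
    Fm <- pair_feature_matrix(E, i, j)
    scores <- decision_scores(clf, Fm)
    active <- (1 - lab * scores) > 0
    if (any(active)) {
      ia <- i[active]; ja <- j[active]; la <- lab[active]
      Gf <- decision_gradient_features(clf, Fm[active, , drop = FALSE])
      gp <- Gf[, seq_len(d), drop = FALSE]          # product block
      ga <- Gf[, d + seq_len(d), drop = FALSE]      # |difference| block
      sgn <- sign(E[ia, , drop = FALSE] - E[ja, , drop = FALSE])
      Gi <- -la * (gp * E[ja, , drop = FALSE] + ga * sgn)
      Gj <- -la * (gp * E[ia, , drop = FALSE] - ga * sgn)
      acc <- rowsum(rbind(Gi, Gj), group = c(ia, ja))
      G_E[as.integer(rownames(acc)), ] <- G_E[as.integer(rownames(acc)), ] + acc
    }
  }
  # back through standardization: E = (raw - center) / scale
  G_E <- sweep(G_E, 2L, emb$scale, "/")
  list(W_d = G_E[, seq_len(k), drop = FALSE],
       W_t = G_E[, k + seq_len(k), drop = FALSE])
}

# Summed hinge loss over labeled pairs for the current embedding/classifier.
classifier_loss <- function(emb, clf, labels) {
  if (nrow(labels) == 0L) return(0)
  Fm <- pair_feature_matrix(emb$E, labels$i, labels$j)
  sum(hinge_loss(decision_scores(clf, Fm), labels$label))
}

#' Score drug pairs with a trained classifier
#'
#' @param object a [train_classifier()] result.
#' @param emb an [aggregate_embedding()] result.
#' @param pairs two-column matrix or data frame of drug indices.
#' @param ... unused.
#' @return Data frame with columns `i`, `j`, `score`,
#'   `label` (`sign(score)`, with a zero score mapped to `-1`).  Pairs are
#'   scored symmetrically: `(i, j)` and `(j, i)` get identical scores.
#' @export
predict.pair_classifier <- function(object, emb, pairs, ...) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) {
    return(data.frame(i = integer(), j = integer(),
                      score = numeric(), label = integer()))
  }
  if (ncol(pairs) < 2L) stop("pairs must have two columns", call. = FALSE)
  i <- as.integer(pairs[, 1L]); j <- as.integer(pairs[, 2L])
  if (any(i < 1L | i > nrow(emb$E) | j < 1L | j > nrow(emb$E))) {
    stop("drug index out of range in pairs", call. = FALSE)
  }
  Fm <- pair_feature_matrix(emb$E, i, j)
  s <- decision_scores(object, Fm)
  data.frame(i = i, j = j, score = s, label = ifelse(s > 0, 1L, -1L))
}

#' @exportS3Method base::print
print.pair_classifier <- function(x, ...) {
  if (x$kernel == "logistic") {
    cat(sprintf("pair_classifier: logistic linear model, %d features\n", x$dim))
  } else {
    cat(sprintf("pair_classifier: %s kernel SVM (C = %g), %d support vectors\n",
                x$kernel, x$C, nrow(x$model$SV)))
  }
  invisible(x)
}

#' Persist / restore a trained pair classifier
#'
#' Saves the full classifier object (kernel specification plus support
#' vectors / weights) to a single RDS file so predictions are reproducible
#' after reload.
#'
#' @param clf a [train_classifier()] result.
#' @param path file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns the classifier.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pair_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "pair_classifier")) stop("not a pair_classifier file", call. = FALSE)
  clf
}
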