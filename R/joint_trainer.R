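# The alternating loop coupling embedding updates and classifier refits
# under the full objective
#
#   L = L_d + lambda1 * L_t + lambda2 * L_c
#
# Each outer iteration: (1) refit the pair classifier on the current pair
# features; (2) with the classifier held fixed, take one backtracking
# projected-gradient step per factor (W_d, H_d, W_t, H_t).  Backtracking
# guarantees the objective is non-increasing over the embedding phase of
# every iteration; convergence is declared when the relative change of the
# total loss falls below `tol`.

#' Training configuration
#'
#' @param k embedding dimension (default 140, the best-performing value on
#'   real-scale data; small synthetic instances use a smaller `k`).
#' @param lambda1 weight of the drug-target loss (default 1).
#' @param lambda2 weight of the classifier loss (default 1); `lambda2 = 0`
#'   gives purely unsupervised embedding.
#' @param lambda_sym weight of the ANLS tying penalty `||W_d - H_d||^2`
#'   (default 1).
#' @param kernel,C,degree,gamma,coef0 classifier settings, see
#'   [train_classifier()].
#' @param max_outer_iter maximum number of outer iterations (default 100).
#' @param tol relative-change convergence tolerance on the total loss
#'   (default 1e-4).
#' @param seed optional integer seed controlling factor initialization.
#' @param normalized_laplacian use the symmetric normalized PPI Laplacian.
#' @param bt_shrink,bt_c1,bt_max backtracking line-search parameters:
#'   step shrink factor, Armijo sufficient-decrease constant, and maximum
#'   number of halvings per step.
#' @param inner_steps maximum number of backtracking projected-gradient
#'   steps per factor within one outer iteration (default 50).  Each factor
#'   subproblem is driven close to its blockwise optimum between classifier
#'   refits, ANLS-style: the inner loop stops early once an accepted step
#'   improves the subobjective by less than `inner_tol` (relative).  Every
#'   inner step is Armijo-guarded, so the objective remains non-increasing
#'   over the embedding phase.
#' @param inner_tol relative-improvement cutoff for the inner loops
#'   (default 1e-6).
#' @param inner_steps_clf maximum inner steps for the two factor blocks
#'   coupled to the classifier term when `lambda2 > 0` (default: equal to
#'   `inner_steps`; lower values trade per-iteration hinge evaluations for
#'   more outer iterations).
#' @return A `train_config` list.
#' @export
train_config <- function(k = 140L, lambda1 = 1, lambda2 = 1, lambda_sym = 1,
                         kernel = "polynomial", C = 1, degree = 3,
                         gamma = NULL, coef0 = 1,
                         max_outer_iter = 100L, tol = 1e-4, seed = NULL,
                         normalized_laplacian = FALSE,
                         bt_shrink = 0.5, bt_c1 = 1e-4, bt_max = 30L,
                         inner_steps = 50L, inner_tol = 1e-6,
                         inner_steps_clf = inner_steps) {
  stopifnot(k >= 1L, lambda1 >= 0, lambda2 >= 0, lambda_sym >= 0, tol > 0,
            max_outer_iter >= 1L, bt_shrink > 0, bt_shrink < 1,
            inner_steps >= 1L)
  structure(list(k = as.integer(k), lambda1 = lambda1, lambda2 = lambda2,
                 lambda_sym = lambda_sym, kernel = kernel, C = C,
                 degree = degree, gamma = gamma, coef0 = coef0,
                 max_outer_iter = as.integer(max_outer_iter), tol = tol,
                 seed = seed, normalized_laplacian = normalized_laplacian,
                 bt_shrink = bt_shrink, bt_c1 = bt_c1,
                 bt_max = as.integer(bt_max),
                 inner_steps = as.integer(inner_steps),
                 inner_tol = inner_tol,
                 inner_steps_clf = as.integer(inner_steps_clf)),
            class = "train_config")
}

#' Evaluate the three loss components of the joint objective
#'
#' @param state an [embedding_state].
#' @param clf a trained [train_classifier()] (may be `NULL` when
#'   `lambda2 = 0` or no labels exist: the classifier term is then 0).
#' @param net a [hetnet].
#' @param labels a [combination_labels].
#' @param config a [train_config()].
#' @param L optional precomputed [build_laplacian()] (rebuilt otherwise).
#' @return List of class `embedding_losses` with `loss_d`, `loss_t`,
#'   `loss_c`, and `total = loss_d + lambda1 * loss_t + lambda2 * loss_c`.
#' @export
total_loss <- function(state, clf, net, labels, config, L = NULL) {
  if (is.null(L)) L <- build_laplacian(net$A_p, config$normalized_laplacian)
  ld <- loss_drug(net$S_d, state$W_d, state$H_d, config$lambda_sym)
  lt <- loss_target(net$B_t, state$W_t, state$H_t, L)
  lc <- 0
  if (config$lambda2 > 0 && !is.null(clf) && nrow(labels) > 0L) {
    emb <- aggregate_embedding(state$W_d, state$W_t,
                               train_drugs = c(labels$i, labels$j))
    lc <- classifier_loss(emb, clf, labels)
  }
  structure(list(loss_d = ld, loss_t = lt, loss_c = lc,
                 total = ld + config$lambda1 * lt + config$lambda2 * lc),
            class = "embedding_losses")
}

# Armijo backtracking projected-gradient step: accepts X+ = P(X - s g) when
# f(X+) <= f(X) - c1 <g, X - X+>; returns X unchanged if no step is accepted.
backtrack_step <- function(X, g, f_fun, f_old, step0, shrink, c1, max_bt) {
  step <- step0
  for (b in seq_len(max_bt)) {
    Xn <- pmax(X - step * g, 0)
    dec <- sum(g * (X - Xn))
    fn <- f_fun(Xn)
    if (is.finite(fn) && fn <= f_old - c1 * dec) {
      return(list(X = Xn, f = fn, step = step, accepted = TRUE))
    }
    step <- step * shrink
  }
  list(X = X, f = f_old, step = step0 * shrink, accepted = FALSE)
}

# Spectral-norm based initial step (1 / Lipschitz estimate of the quadratic
# part); cheap at these sizes.
lipschitz_step <- function(M, extra = 0) {
  l <- norm(crossprod(M), "2") + extra
  1 / max(l, 1e-8)
}

fit_internal <- function(net, labels, config, supervised) {
  S <- net$S_d
  B <- net$B_t
  n_d <- length(net$drugs)
  n_t <- length(net$targets)
  k <- config$k
  lam1 <- config$lambda1
  lam2 <- if (supervised) config$lambda2 else 0
  lam_s <- config$lambda_sym
  L <- build_laplacian(net$A_p, config$normalized_laplacian)
  L_norm <- norm(as.matrix(L$L), "2")

  use_clf <- lam2 > 0 && nrow(labels) > 0L
  if (use_clf && length(unique(labels$label)) < 2L) {
    stop("both label classes are required for joint training", call. = FALSE)
  }
  train_drugs <- unique(c(labels$i, labels$j))

  state <- init_factors(n_d, n_t, k, seed = config$seed, s_mean = mean(S),
                        drugs = net$drugs, targets = net$targets)
  W_d <- state$W_d; H_d <- state$H_d; W_t <- state$W_t; H_t <- state$H_t

  steps <- list(W_d = NULL, H_d = NULL, W_t = NULL, H_t = NULL)
  trace <- vector("list", config$max_outer_iter)
  prev_total <- NA_real_
  converged <- FALSE
  n_iter <- 0L
  clf <- NULL

  # hinge term under the transform/classifier frozen at refit time
  make_lc <- function(emb, clf) {
    function(W_d_new, W_t_new) {
      if (!use_clf) return(0)
      E <- sweep(sweep(cbind(W_d_new, W_t_new), 2L, emb$center, "-"),
                 2L, emb$scale, "/")
      Fm <- cbind(E[labels$i, , drop = FALSE] * E[labels$j, , drop = FALSE],
                  abs(E[labels$i, , drop = FALSE] - E[labels$j, , drop = FALSE]))
      sum(hinge_loss(decision_scores(clf, Fm), labels$label))
    }
  }

  for (it in seq_len(config$max_outer_iter)) {
    ## (1) classifier refit on current pair features
    emb <- aggregate_embedding(W_d, W_t, train_drugs = train_drugs)
    if (use_clf) {
      Fm <- pair_feature_matrix(emb$E, labels$i, labels$j)
      clf <- train_classifier(Fm, labels$label, kernel = config$kernel,
                              C = config$C, degree = config$degree,
                              gamma = config$gamma, coef0 = config$coef0)
    }
    lc_fun <- make_lc(emb, clf)
    # hinge subgradient w.r.t. current factors under the frozen transform
    subgrad_frozen <- function(W_d_cur, W_t_cur) {
      E <- sweep(sweep(cbind(W_d_cur, W_t_cur), 2L, emb$center, "-"),
                 2L, emb$scale, "/")
      emb_cur <- structure(list(E = E, center = emb$center,
                                scale = emb$scale, k = k),
                           class = "drug_embedding")
      classifier_subgradient(emb_cur, clf, labels)
    }

    ## (2) embedding phase, classifier fixed
    ld <- loss_drug(S, W_d, H_d, lam_s)
    lt <- loss_target(B, W_t, H_t, L)
    lc <- lc_fun(W_d, W_t)

    # -- W_d
    f_cur <- ld + lam2 * lc
    n_inner_w <- if (use_clf) min(config$inner_steps, config$inner_steps_clf) else config$inner_steps
    for (s in seq_len(n_inner_w)) {
      cg <- if (use_clf) subgrad_frozen(W_d, W_t)$W_d else NULL
      g <- grad_Wd(S, W_d, H_d, lam_s, clf_grad = cg, lambda2 = lam2)
      step0 <- if (is.null(steps$W_d)) lipschitz_step(H_d, lam_s) else steps$W_d * 2
      res <- backtrack_step(W_d, g, function(X) {
        loss_drug(S, X, H_d, lam_s) + lam2 * lc_fun(X, W_t)
      }, f_cur, step0, config$bt_shrink, config$bt_c1, config$bt_max)
      W_d <- res$X; steps$W_d <- res$step
      if (!res$accepted) break
      rel_gain <- (f_cur - res$f) / max(abs(f_cur), .Machine$double.eps)
      f_cur <- res$f
      if (rel_gain < config$inner_tol) break
    }
    ld <- loss_drug(S, W_d, H_d, lam_s)
    lc <- lc_fun(W_d, W_t)

    # -- H_d (does not feed the classifier)
    f_cur <- ld
    for (s in seq_len(config$inner_steps)) {
      g <- grad_Hd(S, W_d, H_d, lam_s)
      step0 <- if (is.null(steps$H_d)) lipschitz_step(W_d, lam_s) else steps$H_d * 2
      res <- backtrack_step(H_d, g, function(X) loss_drug(S, W_d, X, lam_s),
                            f_cur, step0, config$bt_shrink, config$bt_c1,
                            config$bt_max)
      H_d <- res$X; steps$H_d <- res$step
      if (!res$accepted) break
      rel_gain <- (f_cur - res$f) / max(abs(f_cur), .Machine$double.eps)
      f_cur <- res$f
      if (rel_gain < config$inner_tol) break
    }
    ld <- loss_drug(S, W_d, H_d, lam_s)

    # -- W_t
    f_cur <- lam1 * lt + lam2 * lc
    for (s in seq_len(n_inner_w)) {
      cg <- if (use_clf) subgrad_frozen(W_d, W_t)$W_t else NULL
      g <- grad_Wt(B, W_t, H_t, lam1, clf_grad = cg, lambda2 = lam2)
      step0 <- if (is.null(steps$W_t)) lipschitz_step(H_t, 0) / max(lam1, 1e-8)
               else steps$W_t * 2
      res <- backtrack_step(W_t, g, function(X) {
        lam1 * loss_target(B, X, H_t, L) + lam2 * lc_fun(W_d, X)
      }, f_cur, step0, config$bt_shrink, config$bt_c1, config$bt_max)
      W_t <- res$X; steps$W_t <- res$step
      if (!res$accepted) break
      rel_gain <- (f_cur - res$f) / max(abs(f_cur), .Machine$double.eps)
      f_cur <- res$f
      if (rel_gain < config$inner_tol) break
    }
    lt <- loss_target(B, W_t, H_t, L)
    lc <- lc_fun(W_d, W_t)

    # -- H_t (does not feed the classifier)
    f_cur <- lam1 * lt
    for (s in seq_len(config$inner_steps)) {
      g <- grad_Ht(B, W_t, H_t, L, lam1)
      step0 <- if (is.null(steps$H_t)) {
        1 / max(lam1 * (norm(crossprod(W_t), "2") + L_norm), 1e-8)
      } else steps$H_t * 2
      res <- backtrack_step(H_t, g, function(X) lam1 * loss_target(B, W_t, X, L),
                            f_cur, step0, config$bt_shrink, config$bt_c1,
                            config$bt_max)
      H_t <- res$X; steps$H_t <- res$step
      if (!res$accepted) break
      rel_gain <- (f_cur - res$f) / max(abs(f_cur), .Machine$double.eps)
      f_cur <- res$f
      if (rel_gain < config$inner_tol) break
    }
    lt <- loss_target(B, W_t, H_t, L)

    ## (3) record losses and test convergence
    total <- ld + lam1 * lt + lam2 * lc
    for (nm in c("ld", "lt", "lc", "total")) {
      if (!is.finite(get(nm))) {
        stop("non-finite loss term '", nm, "' at iteration ", it, call. = FALSE)
      }
    }
    trace[[it]] <- c(iter = it, loss_d = ld, loss_t = lt, loss_c = lc,
                     total = total)
    n_iter <- it
    if (!is.na(prev_total)) {
      rel <- abs(total - prev_total) / max(prev_total, .Machine$double.eps)
      if (rel < config$tol) {
        converged <- TRUE
        break
      }
    }
    prev_total <- total
  }

  state <- embedding_state(W_d, H_d, W_t, H_t)
  rownames(state$W_d) <- rownames(state$H_d) <- rownames(state$W_t) <- net$drugs
  rownames(state$H_t) <- net$targets
  trace <- as.data.frame(do.call(rbind, trace[seq_len(n_iter)]))
  list(state = state, trace = trace, n_iter = n_iter, converged = converged,
       L = L, train_drugs = train_drugs)
}

finalize_result <- function(core, net, labels, config, method) {
  # final embedding and classifier on the converged factors
  emb <- aggregate_embedding(core$state$W_d, core$state$W_t,
                             train_drugs = core$train_drugs)
  clf <- NULL
  if (nrow(labels) > 0L && length(unique(labels$label)) >= 2L) {
    Fm <- pair_feature_matrix(emb$E, labels$i, labels$j)
    clf <- train_classifier(Fm, labels$label, kernel = config$kernel,
                            C = config$C, degree = config$degree,
                            gamma = config$gamma, coef0 = config$coef0)
  }
  structure(list(state = core$state, clf = clf, emb = emb,
                 trace = core$trace, n_iter = core$n_iter,
                 converged = core$converged, config = config,
                 method = method, drugs = net$drugs),
            class = "train_result")
}

#' Fit the joint embedding-and-classification model
#'
#' Runs the alternating algorithm: refit the pair classifier on the current
#' embeddings, then take one backtracking projected-gradient step per
#' factor with the classifier fixed, until the relative change of the
#' total loss drops below `config$tol` or `config$max_outer_iter` is
#' reached.  Deterministic given `config$seed`.
#'
#' @param net a [hetnet].
#' @param labels a [combination_labels] with both classes present
#'   (training pairs only; held-out pairs must not be passed here).
#' @param config a [train_config()].
#' @return An object of class `train_result`: the final [embedding_state],
#'   the final classifier (`clf`), the standardized embedding (`emb`), the
#'   per-iteration loss trace (`trace`: columns `iter`, `loss_d`, `loss_t`,
#'   `loss_c`, `total`), `n_iter`, and `converged`.
#' @export
fit_joint <- function(net, labels, config = train_config()) {
  core <- fit_internal(net, labels, config, supervised = TRUE)
  finalize_result(core, net, labels, config, method = "joint")
}

#' Fit the independent-learning baseline
#'
#' Ablation of the joint scheme: the embedding is learned fully
#' unsupervised (`lambda2 = 0`, so no classifier-coupled updates), then a
#' single classifier is trained on the frozen embeddings.
#'
#' @inheritParams fit_joint
#' @return A `train_result` (its trace contains no classifier term:
#'   `loss_c` is 0 throughout).
#' @export
fit_independent <- function(net, labels, config = train_config()) {
  core <- fit_internal(net, labels, config, supervised = FALSE)
  finalize_result(core, net, labels, config, method = "independent")
}

#' @exportS3Method base::print
print.train_result <- function(x, ...) {
  cat(sprintf("train_result (%s learning): k = %d, %d iterations, %s\n",
              x$method, x$config$k, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final losses: drug %.4g, target %.4g, classifier %.4g, total %.4g\n",
              last$loss_d, last$loss_t, last$loss_c, last$total))
  invisible(x)
}

#' Score drug pairs with a fitted model
#'
#' @param object a [fit_joint()] / [fit_independent()] result.
#' @param pairs two-column matrix/data frame of drug indices, or a
#'   [combination_labels] object (its label column is ignored).
#' @param ... unused.
#' @return Data frame with `i`, `j`, `score`, `label`.
#' @export
predict.train_result <- function(object, pairs, ...) {
  if (is.null(object$clf)) stop("model has no trained classifier", call. = FALSE)
  if (inherits(pairs, "combination_labels")) {
    pairs <- cbind(pairs$i, pairs$j)
  }
  predict(object$clf, object$emb, pairs)
}

#' Write the loss trace as TSV
#'
#' One row per outer iteration with the three loss components and the
#' total, mirroring the convergence diagnostics of the method.
#'
#' @param result a `train_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
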