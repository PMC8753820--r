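# Loss terms and gradients of the two factorization sub-objectives:
#
#   drug network:   L_d = 1/2 ||S_d - W_d H_d'||_F^2 + lambda_sym/2 ||W_d - H_d||_F^2
#   drug-target:    L_t = 1/2 ||B_t - W_t H_t'||_F^2 + 1/2 tr(H_t' L H_t)
#
# The 1/2 convention is used uniformly so the analytic gradients below are
# exactly the matrix expressions obtained by differentiating the half-squared
# Frobenius norms; the constant is absorbed by the step size.  The symmetric
# factorization S ~ W W' is relaxed ANLS-style into S ~ W H' with a penalty
# pulling W toward H, which keeps each subproblem a nonnegative least squares.

fro2 <- function(X) sum(X * X)

#' Graph Laplacian of the PPI network
#'
#' Builds `L = D - A` (unnormalized, the default) or the symmetric
#' normalized variant `I - D^{-1/2} A D^{-1/2}` from the PPI adjacency
#' restricted to targeted proteins.  The quadratic form
#' `tr(H' L H) = 1/2 * sum_ij a_ij ||h_i - h_j||^2` penalizes embedding
#' differences across interacting proteins.
#'
#' @param A_p symmetric binary adjacency with zero diagonal (matrix or
#'   sparse `Matrix`).
#' @param normalized use the symmetric normalized Laplacian instead of
#'   `D - A` (isolated vertices get a zero row either way).
#' @return An object of class `laplacian`: list with the matrix `L`
#'   (sparse) and `degree`, the vector of row sums of `A_p`.
#' @export
build_laplacian <- function(A_p, normalized = FALSE) {
  A <- Matrix::Matrix(A_p, sparse = TRUE)
  if (!Matrix::isSymmetric(A, tol = 0)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  A <- methods::as(methods::as(A, "dMatrix"), "generalMatrix")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  d <- Matrix::rowSums(A)
  if (normalized) {
    inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
    Dm <- Matrix::Diagonal(x = inv_sqrt)
    L <- Matrix::Diagonal(x = as.numeric(d > 0)) - Dm %*% A %*% Dm
  } else {
    L <- Matrix::Diagonal(x = d) - A
  }
  structure(list(L = L, degree = d, normalized = normalized),
            class = "laplacian")
}

as_lap_matrix <- function(L) {
  if (inherits(L, "laplacian")) L$L else L
}

#' Drug-network factorization loss
#'
#' `1/2 ||S_d - W_d H_d'||_F^2 + lambda_sym/2 ||W_d - H_d||_F^2`, the ANLS
#' relaxation of the symmetric factorization `S_d ~ W_d W_d'`.  Equals
#' `1/2 ||S_d - W_d W_d'||_F^2` when `W_d = H_d`.
#'
#' @param S_d symmetric similarity matrix `n_d x n_d`.
#' @param W_d,H_d nonnegative `n_d x k` factors.
#' @param lambda_sym weight of the `||W_d - H_d||^2` tying penalty.
#' @return Nonnegative scalar.
#' @export
loss_drug <- function(S_d, W_d, H_d, lambda_sym = 1) {
  if (!all(dim(W_d) == dim(H_d)) || nrow(W_d) != nrow(S_d)) {
    stop("shape mismatch in loss_drug", call. = FALSE)
  }
  0.5 * fro2(S_d - W_d %*% t(H_d)) + 0.5 * lambda_sym * fro2(W_d - H_d)
}

#' Drug-target factorization loss with Laplacian regularization
#'
#' `1/2 ||B_t - W_t H_t'||_F^2 + 1/2 tr(H_t' L H_t)`; the trace term is
#' nonnegative by positive semidefiniteness of the graph Laplacian and
#' vanishes iff `H_t` is constant on every connected PPI component.
#'
#' @param B_t `n_d x n_t` incidence matrix.
#' @param W_t,H_t nonnegative factors (`n_d x k`, `n_t x k`).
#' @param L a [build_laplacian()] object (or a plain `n_t x n_t` matrix).
#' @return Nonnegative scalar.
#' @export
loss_target <- function(B_t, W_t, H_t, L) {
  Lm <- as_lap_matrix(L)
  if (nrow(W_t) != nrow(B_t) || nrow(H_t) != ncol(B_t) ||
      ncol(W_t) != ncol(H_t) || nrow(Lm) != nrow(H_t)) {
    stop("shape mismatch in loss_target", call. = FALSE)
  }
  0.5 * fro2(as.matrix(B_t - W_t %*% t(H_t))) +
    0.5 * sum(H_t * as.matrix(Lm %*% H_t))
}

#' Gradients of the factorization losses
#'
#' Analytic gradients of [loss_drug()] and [loss_target()] in full-matrix
#' form, plus the (scaled) classifier subgradient for the factors that feed
#' the pair classifier:
#' \describe{
#'   \item{`grad_Wd`}{`(W_d H_d' - S_d) H_d + lambda_sym (W_d - H_d) + lambda2 * clf_grad`}
#'   \item{`grad_Hd`}{`(H_d W_d' - S_d') W_d + lambda_sym (H_d - W_d)`}
#'   \item{`grad_Wt`}{`lambda1 (W_t H_t' - B_t) H_t + lambda2 * clf_grad`}
#'   \item{`grad_Ht`}{`lambda1 (H_t W_t' W_t - B_t' W_t + L H_t)`}
#' }
#' Each matches central finite differences of its loss term (with the
#' drug-target terms weighted by `lambda1`).
#'
#' @param S_d,B_t,W_d,H_d,W_t,H_t,lambda_sym as in [loss_drug()] /
#'   [loss_target()].
#' @param L a [build_laplacian()] object or matrix.
#' @param lambda1 weight of the drug-target loss in the joint objective.
#' @param lambda2 weight of the classifier loss; `clf_grad` is multiplied
#'   by it.
#' @param clf_grad classifier subgradient w.r.t. the rows of the factor
#'   (`NULL` means zero; see [classifier_subgradient()]).
#' @return Gradient matrix with the shape of the differentiated factor.
#' @name factor_gradients
NULL

#' @rdname factor_gradients
#' @export
grad_Wd <- function(S_d, W_d, H_d, lambda_sym = 1, clf_grad = NULL, lambda2 = 0) {
  if (!all(dim(W_d) == dim(H_d)) || nrow(W_d) != nrow(S_d)) {
    stop("shape mismatch in grad_Wd", call. = FALSE)
  }
  G <- (W_d %*% t(H_d) - S_d) %*% H_d + lambda_sym * (W_d - H_d)
  if (lambda2 != 0 && !is.null(clf_grad)) {
    if (!all(dim(clf_grad) == dim(W_d))) {
      stop("classifier gradient has wrong shape", call. = FALSE)
    }
    G <- G + lambda2 * clf_grad
  }
  G
}

#' @rdname factor_gradients
#' @export
grad_Hd <- function(S_d, W_d, H_d, lambda_sym = 1) {
  if (!all(dim(W_d) == dim(H_d)) || nrow(W_d) != nrow(S_d)) {
    stop("shape mismatch in grad_Hd", call. = FALSE)
  }
  (H_d %*% t(W_d) - t(S_d)) %*% W_d + lambda_sym * (H_d - W_d)
}

#' @rdname factor_gradients
#' @export
grad_Wt <- function(B_t, W_t, H_t, lambda1 = 1, clf_grad = NULL, lambda2 = 0) {
  if (nrow(W_t) != nrow(B_t) || nrow(H_t) != ncol(B_t) ||
      ncol(W_t) != ncol(H_t)) {
    stop("shape mismatch in grad_Wt", call. = FALSE)
  }
  G <- lambda1 * as.matrix((W_t %*% t(H_t) - B_t) %*% H_t)
  if (lambda2 != 0 && !is.null(clf_grad)) {
    if (!all(dim(clf_grad) == dim(W_t))) {
      stop("classifier gradient has wrong shape", call. = FALSE)
    }
    G <- G + lambda2 * clf_grad
  }
  G
}

#' @rdname factor_gradients
#' @export
grad_Ht <- function(B_t, W_t, H_t, L, lambda1 = 1) {
  Lm <- as_lap_matrix(L)
  if (nrow(W_t) != nrow(B_t) || nrow(H_t) != ncol(B_t) ||
      ncol(W_t) != ncol(H_t) || nrow(Lm) != nrow(H_t)) {
    stop("shape mismatch in grad_Ht", call. = FALSE)
  }
  lambda1 * as.matrix(H_t %*% (t(W_t) %*% W_t) - t(B_t) %*% W_t + Lm %*% H_t)
}

#' Projected gradient step onto the nonnegative orthant
#'
#' `max(X - step * grad, 0)` elementwise; the projection enforces the
#' nonnegativity constraints after every step.
#'
#' @param X current factor matrix.
#' @param grad gradient of the objective at `X`.
#' @param step positive step size.
#' @return Updated nonnegative matrix with the shape of `X`.
#' @export
projected_gradient_step <- function(X, grad, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step size must be a positive scalar", call. = FALSE)
  }
  pmax(X - step * grad, 0)
}

#' Random nonnegative initialization of the factor matrices
#'
#' All four factors are drawn i.i.d. uniform on `(0, s)` with
#' `s = sqrt(s_mean / k)` so that `W H'` has entries on the scale of the
#' mean similarity `s_mean` at initialization.
#'
#' @param n_d,n_t number of drugs / targeted proteins.
#' @param k embedding dimension (>= 1).
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @param s_mean target mean of the reconstructed similarity (default 0.5;
#'   pass `mean(S_d)` for a matched scale).
#' @param drugs,targets optional id vectors used as row names.
#' @return An [embedding_state].
#' @export
init_factors <- function(n_d, n_t, k, seed = NULL, s_mean = 0.5,
                         drugs = NULL, targets = NULL) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(max(s_mean, 1e-8) / k)
  rmat <- function(n) matrix(stats::runif(n * k, min = .Machine$double.eps, max = s), n, k)
  st <- embedding_state(rmat(n_d), rmat(n_d), rmat(n_d), rmat(n_t))
  if (!is.null(drugs)) {
    rownames(st$W_d) <- rownames(st$H_d) <- rownames(st$W_t) <- drugs
  }
  if (!is.null(targets)) rownames(st$H_t) <- targets
  st
}
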