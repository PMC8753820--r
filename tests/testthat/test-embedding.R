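test_that("Laplacian has zero row sums and the trace identity holds", {
  # two nodes, one edge
  L2 <- build_laplacian(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(as.matrix(L2$L), matrix(c(1, -1, -1, 1), 2, 2),
               ignore_attr = TRUE)
  # empty graph
  L0 <- build_laplacian(matrix(0, 3, 3))
  expect_equal(as.matrix(L0$L), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_error(build_laplacian(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")

  # tr(H'LH) = 1/2 sum_ij a_ij ||h_i - h_j||^2, brute-force pairwise sum
  A <- rand_adj(6, .4, seed = 9)
  L <- build_laplacian(A)
  expect_equal(unname(Matrix::rowSums(L$L)), rep(0, 6))
  set.seed(10)
  for (r in 1:5) {
    H <- matrix(runif(6 * 3), 6, 3)
    brute <- 0
    for (i in 1:6) for (j in 1:6) {
      brute <- brute + A[i, j] * sum((H[i, ] - H[j, ])^2)
    }
    expect_equal(sum(H * as.matrix(L$L %*% H)), brute / 2)
  }
  # triangle with one-hot rows: 3 undirected edges, each ||h_i - h_j||^2 = 2
  tri <- matrix(1, 3, 3) - diag(3)
  Ltri <- build_laplacian(tri)
  H1 <- diag(3)
  expect_equal(sum(H1 * as.matrix(Ltri$L %*% H1)), 6)
})

test_that("losses match naive double-loop evaluation", {
  inst <- rand_instance(5, 4, 3, seed = 21)
  lam_s <- 0.7
  # naive scalar-loop oracle for the drug term
  naive_d <- 0
  R <- inst$S[1:5, 1:5] - inst$W_d[1:5, ] %*% t(inst$H_d[1:5, ])
  for (i in 1:5) for (j in 1:5) naive_d <- naive_d + R[i, j]^2
  for (i in 1:5) for (q in 1:3) {
    naive_d <- naive_d + lam_s * (inst$W_d[i, q] - inst$H_d[i, q])^2
  }
  expect_equal(loss_drug(inst$S, inst$W_d, inst$H_d, lam_s), naive_d / 2)

  # exact factorization gives zero; zero factors give half the norm
  W <- matrix(runif(10), 5, 2)
  expect_equal(loss_drug(W %*% t(W), W, W, 1), 0)
  expect_equal(loss_drug(inst$S, inst$W_d * 0, inst$H_d * 0, 1),
               0.5 * sum(inst$S^2))

  # target term: naive evaluation including the trace
  L <- build_laplacian(inst$A)
  naive_t <- 0
  Rt <- as.matrix(inst$B - inst$W_t %*% t(inst$H_t))
  for (i in seq_len(nrow(Rt))) for (j in seq_len(ncol(Rt))) {
    naive_t <- naive_t + Rt[i, j]^2
  }
  n_t <- nrow(inst$A)
  for (i in seq_len(n_t)) for (j in seq_len(n_t)) {
    naive_t <- naive_t + 0.5 * inst$A[i, j] * sum((inst$H_t[i, ] - inst$H_t[j, ])^2)
  }
  expect_equal(loss_target(inst$B, inst$W_t, inst$H_t, L), naive_t / 2)

  # L = 0 reduces to the plain factorization residual
  expect_equal(loss_target(inst$B, inst$W_t, inst$H_t, matrix(0, n_t, n_t)),
               0.5 * sum(Rt^2))
})

test_that("analytic gradients match central finite differences", {
  inst <- rand_instance(8, 6, 3, seed = 33)
  L <- build_laplacian(inst$A)
  lam_s <- 1.3; lam1 <- 1.7

  g <- grad_Wd(inst$S, inst$W_d, inst$H_d, lam_s)
  expect_lt(max_rel_err(g, fd_grad(function(X) loss_drug(inst$S, X, inst$H_d, lam_s),
                                   inst$W_d)), 1e-5)
  g <- grad_Hd(inst$S, inst$W_d, inst$H_d, lam_s)
  expect_lt(max_rel_err(g, fd_grad(function(X) loss_drug(inst$S, inst$W_d, X, lam_s),
                                   inst$H_d)), 1e-5)
  g <- grad_Wt(inst$B, inst$W_t, inst$H_t, lam1)
  expect_lt(max_rel_err(g, fd_grad(function(X) lam1 * loss_target(inst$B, X, inst$H_t, L),
                                   inst$W_t)), 1e-5)
  g <- grad_Ht(inst$B, inst$W_t, inst$H_t, L, lam1)
  expect_lt(max_rel_err(g, fd_grad(function(X) lam1 * loss_target(inst$B, inst$W_t, X, L),
                                   inst$H_t)), 1e-5)

  # lambda_sym = 0, H fixed: the standard factorization gradient
  expect_equal(grad_Wd(inst$S, inst$W_d, inst$H_d, 0),
               (inst$W_d %*% t(inst$H_d) - inst$S) %*% inst$H_d)
  # W = H at a symmetric point: the two gradients coincide
  expect_equal(grad_Wd(inst$S, inst$W_d, inst$W_d, 1),
               grad_Hd(inst$S, inst$W_d, inst$W_d, 1))
  # term isolation: W_t = 0, B = 0 leaves only the Laplacian term
  expect_equal(grad_Ht(inst$B * 0, inst$W_t * 0, inst$H_t, L, lam1),
               lam1 * as.matrix(L$L %*% inst$H_t))
  # lambda1 = 0: zero matrix
  expect_equal(grad_Wt(inst$B, inst$W_t, inst$H_t, 0),
               matrix(0, 8, 3))
})

test_that("gradient vanishes at an exact factorization", {
  set.seed(44)
  W <- matrix(runif(8 * 3), 8, 3)
  S <- W %*% t(W)
  expect_lt(max(abs(grad_Wd(S, W, W, 1))), 1e-8)
  Ht <- matrix(runif(6 * 3), 6, 3)
  B <- W %*% t(Ht)
  expect_lt(max(abs(grad_Wt(B, W, Ht, 1))), 1e-8)
  expect_lt(max(abs(grad_Ht(B, W, Ht, matrix(0, 6, 6), 1))), 1e-8)
})

test_that("projected gradient step projects and descends", {
  set.seed(55)
  X <- matrix(runif(12), 4, 3)
  expect_equal(projected_gradient_step(X, X * 0, 0.1), X)
  expect_equal(projected_gradient_step(X * 0, X + 1, 0.5), X * 0)
  expect_error(projected_gradient_step(X, X, 0), "positive")
  expect_error(projected_gradient_step(X, X, -1), "positive")

  # small enough step strictly decreases the loss
  inst <- rand_instance(6, 5, 2, seed = 56)
  f0 <- loss_drug(inst$S[1:6, 1:6], inst$W_d[1:6, 1:2], inst$H_d[1:6, 1:2], 1)
  g <- grad_Wd(inst$S[1:6, 1:6], inst$W_d[1:6, 1:2], inst$H_d[1:6, 1:2], 1)
  Xn <- projected_gradient_step(inst$W_d[1:6, 1:2], g, 1e-3)
  expect_lt(loss_drug(inst$S[1:6, 1:6], Xn, inst$H_d[1:6, 1:2], 1), f0)
  expect_true(all(Xn >= 0))
})

test_that("factor initialization is seeded and strictly positive", {
  a <- init_factors(5, 4, 3, seed = 1)
  b <- init_factors(5, 4, 3, seed = 1)
  c <- init_factors(5, 4, 3, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$W_d > 0) && all(a$H_t > 0))
  expect_equal(dim(a$W_d), c(5L, 3L))
  expect_equal(dim(a$H_t), c(4L, 3L))
})

test_that("noiseless low-rank similarity is recovered by the factorization", {
  set.seed(66)
  W_star <- matrix(runif(20 * 3)^2, 20, 3)
  W_star <- W_star / sqrt(rowSums(W_star^2))
  S <- W_star %*% t(W_star)
  # best of 5 restarts of the pure drug-network objective
  B <- matrix(1, 20, 2); A <- matrix(0, 2, 2)
  net <- hetnet(S, B, A, sprintf("d%02d", 1:20), c("p1", "p2"))
  labs <- combination_labels(integer(), integer(), integer(), net$drugs)
  best <- Inf
  for (s in 1:5) {
    fit <- fit_independent(net, labs,
      train_config(k = 5, seed = s, lambda1 = 0, lambda2 = 0,
                   tol = 1e-9, max_outer_iter = 200))
    resid <- sum((S - fit$state$W_d %*% t(fit$state$H_d))^2)
    best <- min(best, resid)
  }
  expect_lt(best, 1e-3 * sum(S^2))
})
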