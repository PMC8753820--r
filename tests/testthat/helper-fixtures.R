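# Shared fixture builders and independent oracles for the test suite.

# central finite differences of f at X (elementwise)
fd_grad <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (p in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[p] <- Xp[p] + eps
    Xm[p] <- Xm[p] - eps
    G[p] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}

max_rel_err <- function(est, ref) {
  max(abs(est - ref)) / max(abs(ref), 1e-12)
}

# random valid similarity matrix
rand_sim <- function(n, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# random symmetric binary adjacency, zero diagonal
rand_adj <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- rbinom(sum(ut), 1L, p)
  A + t(A)
}

# small random problem instance for gradient checks
rand_instance <- function(n_d = 8, n_t = 6, k = 3, seed = 1) {
  set.seed(seed)
  list(S = rand_sim(n_d, seed),
       B = matrix(rbinom(n_d * n_t, 1L, 0.3), n_d, n_t),
       A = rand_adj(n_t, 0.3, seed + 1),
       W_d = matrix(runif(n_d * k), n_d, k),
       H_d = matrix(runif(n_d * k), n_d, k),
       W_t = matrix(runif(n_d * k), n_d, k),
       H_t = matrix(runif(n_t * k), n_t, k))
}

# tiny hetnet with 3 drugs / 3 targets, fully valid
tiny_hetnet <- function() {
  S <- matrix(c(1, .5, .2,
                .5, 1, .4,
                .2, .4, 1), 3, 3)
  B <- matrix(c(1, 0, 0,
                1, 1, 0,
                0, 1, 1), 3, 3, byrow = TRUE)
  A <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3)
  hetnet(S, B, A, c("a", "b", "c"), c("p1", "p2", "p3"))
}

# labels over the tiny net (both classes)
tiny_labels <- function() {
  combination_labels(c(1, 1, 2), c(2, 3, 3), c(1, -1, 1), c("a", "b", "c"))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# train/test split of a combination_labels object
split_labels <- function(labels, frac_test = 0.2, seed = 1) {
  set.seed(seed)
  n <- nrow(labels)
  test_idx <- sort(sample.int(n, round(frac_test * n)))
  list(train = combonet:::subset_labels(labels, setdiff(seq_len(n), test_idx)),
       test = combonet:::subset_labels(labels, test_idx))
}

# held-out AUC of a fitter on a planted instance
planted_holdout_auc <- function(seed, rho = 0, fitter = fit_joint,
                                n_d = 40, n_t = 80, k_true = 4, k = 6,
                                max_outer_iter = 100L, ...) {
  inst <- simulate_hetnet(n_d = n_d, n_t = n_t, k_true = k_true, rho = rho,
                          seed = seed, ...)
  sp <- split_labels(inst$labels, 0.2, seed + 1000)
  fit <- fitter(inst$net, sp$train,
                train_config(k = k, seed = seed,
                             max_outer_iter = max_outer_iter))
  pred <- predict(fit, sp$test)
  roc_auc(pred$score, sp$test$label)
}
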