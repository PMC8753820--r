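# Generator of heterogeneous networks with planted low-rank structure and
# planted combination labels.  The generator emulates the matrix structure
# assumed by the model -- a similarity matrix that is (noisy) low-rank
# symmetric nonnegative, a drug-target incidence driven by the same latent
# factors, a PPI network assortative in the protein factors, and pair
# labels that are a linear function of the same symmetric pair features
# the classifier uses -- not realistic pharmacology.

clip01 <- function(X) pmin(pmax(X, 0), 1)

#' Generate a planted-structure heterogeneous network instance
#'
#' Draws planted factors `W*_d` (`n_d x k_true`, rows scaled to unit
#' Euclidean norm), `W*_t`, `H*_t`, and builds
#' \describe{
#'   \item{`S_d`}{`clip01(W*_d W*_d' + sigma * symmetric Gaussian noise)`
#'     with unit diagonal.  Because the planted rows have unit norm, the
#'     noiseless similarity is an exact rank-`k_true` nonnegative cosine
#'     matrix whose diagonal is already 1, so the planted factors are an
#'     exact optimum of the symmetric factorization;}
#'   \item{`B_t`}{Bernoulli draws with probability proportional to
#'     `W*_t H*_t'` (calibrated to `b_density`; every drug keeps at least
#'     one target and every target at least one drug), where
#'     `W*_t = mix_dt * W*_d + (1 - mix_dt) * uniform`: target profiles
#'     correlate with drug similarity, as similar drugs tend to share
#'     targets;}
#'   \item{`A_p`}{Bernoulli edges with probability proportional to
#'     `H*_t H*_t'` (proteins with similar factor rows connect more
#'     often), calibrated to `ppi_density`,}
#' }
#' and labels `sign(<theta*, pair_feature(E*_i, E*_j)> - b)` over a random
#' sample of drug pairs, where `E*` is the standardized concatenation of
#' the planted drug factors, `theta*` is a random weight vector, and the
#' offset `b` is the score quantile giving the requested class balance.
#' Each label is flipped independently with probability `rho`.
#'
#' Default sizes give a desk-scale instance; the default class balance
#' (about 33% synergistic) mirrors the imbalance typical of curated
#' drug-combination screens.
#'
#' @param n_d,n_t number of drugs / proteins.
#' @param k_true planted rank (`<= min(n_d, n_t)`).
#' @param sigma similarity noise level (standard deviation).
#' @param rho label flip probability in \[0, 0.5).
#' @param pair_fraction fraction of the `choose(n_d, 2)` pairs that are
#'   labeled.
#' @param syn_fraction target fraction of synergistic (+1) labels.
#' @param b_density,ppi_density target mean density of `B_t` / `A_p`.
#' @param mix_dt weight in \[0, 1\] coupling the drug-target factors to the
#'   similarity factors (0 = independent layers).
#' @param seed integer seed; the instance is deterministic given it.
#' @return An object of class `planted_instance`: list with `net`
#'   ([hetnet]), `labels` ([combination_labels]), `truth` (planted
#'   `W_d`, `W_t`, `H_t`, `theta`, `threshold`), and `params`.
#' @export
simulate_hetnet <- function(n_d = 60L, n_t = 120L, k_true = 5L,
                            sigma = 0.05, rho = 0,
                            pair_fraction = 0.25,
                            syn_fraction = 5903 / 18126,
                            b_density = 0.08, ppi_density = 0.05,
                            mix_dt = 0.7, seed = 1L) {
  if (k_true > min(n_d, n_t)) stop("k_true must be <= min(n_d, n_t)", call. = FALSE)
  if (sigma < 0 || rho < 0 || rho >= 0.5) {
    stop("need sigma >= 0 and 0 <= rho < 0.5", call. = FALSE)
  }
  n_pairs_all <- choose(n_d, 2)
  m <- round(pair_fraction * n_pairs_all)
  if (m < 2) stop("pair_fraction too small: no pairs to label", call. = FALSE)
  set.seed(seed)

  drugs <- sprintf("D%03d", seq_len(n_d))
  prots <- sprintf("P%04d", seq_len(n_t))

  ## similarity layer: planted symmetric low-rank + clipped noise.
  ## Squared uniforms spread the cosine similarities over [0, 1); unit-norm
  ## rows make the noiseless S an exact rank-k_true matrix with diag 1.
  Wd_true <- matrix(stats::runif(n_d * k_true)^2, n_d, k_true)
  Wd_true <- Wd_true / sqrt(rowSums(Wd_true^2))
  S <- Wd_true %*% t(Wd_true)
  if (sigma > 0) {
    N <- matrix(stats::rnorm(n_d * n_d, sd = sigma), n_d, n_d)
    S <- S + (N + t(N)) / 2
  }
  S <- clip01(S)
  diag(S) <- 1

  ## drug-target layer: drug factors correlated with the similarity factors
  Wt_true <- mix_dt * Wd_true +
    (1 - mix_dt) * matrix(stats::runif(n_d * k_true), n_d, k_true)
  Ht_true <- matrix(stats::runif(n_t * k_true), n_t, k_true)
  M <- Wt_true %*% t(Ht_true)
  p_b <- pmin(b_density * M / mean(M), 1)
  B <- matrix(stats::rbinom(n_d * n_t, 1L, p_b), n_d, n_t)
  # keep the incidence well-posed: no empty drug rows or target columns
  for (i in which(rowSums(B) == 0L)) B[i, which.max(M[i, ])] <- 1L
  for (j in which(colSums(B) == 0L)) B[which.max(M[, j]), j] <- 1L

  ## PPI layer: assortative in the planted protein factors
  aff <- Ht_true %*% t(Ht_true)
  diag(aff) <- 0
  p_a <- pmin(ppi_density * aff / mean(aff[upper.tri(aff)]), 1)
  A <- matrix(0L, n_t, n_t)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1L, p_a[ut])
  A <- A + t(A)

  ## labels through the same pair-feature map the classifier uses
  raw <- cbind(Wd_true, Wt_true)
  ctr <- colMeans(raw)
  sdv <- apply(raw, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  E_true <- sweep(sweep(raw, 2L, ctr, "-"), 2L, sdv, "/")
  all_pairs <- which(upper.tri(matrix(0, n_d, n_d)), arr.ind = TRUE)
  sel <- sort(sample.int(nrow(all_pairs), m))
  pi_ <- all_pairs[sel, 1L]
  pj <- all_pairs[sel, 2L]
  theta <- stats::rnorm(4L * k_true)
  Fm <- cbind(E_true[pi_, , drop = FALSE] * E_true[pj, , drop = FALSE],
              abs(E_true[pi_, , drop = FALSE] - E_true[pj, , drop = FALSE]))
  score <- drop(Fm %*% theta)
  threshold <- stats::quantile(score, 1 - syn_fraction, names = FALSE)
  lab <- ifelse(score > threshold, 1L, -1L)
  if (rho > 0) {
    flip <- stats::runif(m) < rho
    lab[flip] <- -lab[flip]
  }

  net <- hetnet(S, B, A, drugs, prots)
  labels <- combination_labels(pi_, pj, lab, drugs)
  structure(list(net = net, labels = labels,
                 truth = list(W_d = Wd_true, W_t = Wt_true, H_t = Ht_true,
                              theta = theta, threshold = threshold,
                              center = ctr, scale = sdv),
                 params = list(n_d = n_d, n_t = n_t, k_true = k_true,
                               sigma = sigma, rho = rho,
                               pair_fraction = pair_fraction,
                               syn_fraction = syn_fraction,
                               b_density = b_density,
                               ppi_density = ppi_density,
                               mix_dt = mix_dt, seed = seed)),
            class = "planted_instance")
}

#' @exportS3Method base::print
print.planted_instance <- function(x, ...) {
  p <- x$params
  cat(sprintf("planted_instance: n_d = %d, n_t = %d, k_true = %d, sigma = %g, rho = %g, seed = %d\n",
              p$n_d, p$n_t, p$k_true, p$sigma, p$rho, p$seed))
  print(x$labels)
  invisible(x)
}

#' Write a planted instance as the five TSV input files
#'
#' Emits `similarity.tsv` (square dialect), `drug_target.tsv`, `ppi.tsv`,
#' `labels.tsv` and a `manifest.json` recording every generator parameter
#' and the seed, so the instance can be regenerated or re-read with
#' [read_hetnet()] / [read_labels()].
#'
#' @param instance a [simulate_hetnet()] result.
#' @param dir output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "planted_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- instance$net
  paths <- c(similarity = file.path(dir, "similarity.tsv"),
             drug_target = file.path(dir, "drug_target.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             labels = file.path(dir, "labels.tsv"),
             manifest = file.path(dir, "manifest.json"))

  con <- file(paths[["similarity"]], "w")
  writeLines(paste(c("id", net$drugs), collapse = "\t"), con)
  body <- apply(net$S_d, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(net$drugs, body, sep = "\t"), con)
  close(con)

  dt <- Matrix::which(net$B_t == 1, arr.ind = TRUE)
  dt <- dt[order(dt[, 1L], dt[, 2L]), , drop = FALSE]
  utils::write.table(data.frame(net$drugs[dt[, 1L]], net$targets[dt[, 2L]]),
                     paths[["drug_target"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ap <- Matrix::which(net$A_p == 1, arr.ind = TRUE)
  ap <- ap[ap[, 1L] < ap[, 2L], , drop = FALSE]
  ap <- ap[order(ap[, 1L], ap[, 2L]), , drop = FALSE]
  utils::write.table(data.frame(net$targets[ap[, 1L]], net$targets[ap[, 2L]]),
                     paths[["ppi"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  lab <- instance$labels
  drugs <- attr(lab, "drugs")
  utils::write.table(data.frame(drugs[lab$i], drugs[lab$j], lab$label),
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  jsonlite::write_json(instance$params, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Summary statistics of a planted instance
#'
#' Counts and drug-degree statistics of the labeled-pair network, overall
#' and per label class (a drug's degree is the number of labeled pairs it
#' participates in).
#'
#' @param instance a [simulate_hetnet()] result (or any list with `net`
#'   and `labels`).
#' @return List with `n_ddi`, `n_drugs`, `n_synergistic`,
#'   `n_antagonistic`, and `degree` -- a data frame (rows `all`,
#'   `synergistic`, `antagonistic`; columns `mean`, `median`, `max`).
#' @export
summarize_instance <- function(instance) {
  lab <- instance$labels
  n_d <- length(instance$net$drugs)
  deg_stats <- function(rows) {
    d <- tabulate(c(lab$i[rows], lab$j[rows]), nbins = n_d)
    d <- d[d > 0]
    if (length(d) == 0L) return(c(mean = 0, median = 0, max = 0))
    c(mean = mean(d), median = stats::median(d), max = max(d))
  }
  degree <- rbind(all = deg_stats(seq_len(nrow(lab))),
                  synergistic = deg_stats(which(lab$label == 1L)),
                  antagonistic = deg_stats(which(lab$label == -1L)))
  list(n_ddi = nrow(lab), n_drugs = n_d,
       n_synergistic = sum(lab$label == 1L),
       n_antagonistic = sum(lab$label == -1L),
       degree = as.data.frame(degree))
}
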