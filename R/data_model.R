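# Containers and file readers/writers for the heterogeneous drug-protein
# network, the labeled drug pairs, and the learned factor matrices.
#
# All external files are TSV (tab-separated, UTF-8, '#' comment lines
# ignored); drugs and proteins are identified by strings in files and by
# integer positions internally.

## ---- low-level TSV helpers -------------------------------------------------

read_tsv_table <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(first_data_line(path))) {
    return(data.frame())
  }
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    blank.lines.skip = TRUE, check.names = FALSE,
                    colClasses = "character")
}

first_data_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(NULL)
    if (!grepl("^\\s*(#|$)", line)) return(line)
  }
}

## ---- HetNet ----------------------------------------------------------------

#' Construct and validate a heterogeneous drug-protein network
#'
#' Bundles the three layers of the network: a dense symmetric drug-drug
#' similarity matrix `S_d` with entries in \[0, 1\] and unit diagonal, a
#' sparse binary drug-target incidence matrix `B_t`, and a sparse symmetric
#' binary protein-protein interaction (PPI) adjacency `A_p` restricted to
#' the targeted proteins.  All invariants are asserted here so every
#' downstream consumer can rely on them.
#'
#' @param S_d numeric `n_d x n_d` symmetric matrix, entries in \[0, 1\].
#'   The diagonal is forced to 1 (a drug is maximally self-similar).
#' @param B_t binary `n_d x n_t` matrix (dense or `Matrix` sparse);
#'   `B_t[i, j] = 1` iff protein `j` is a target of drug `i`.
#' @param A_p binary symmetric `n_t x n_t` matrix with zero diagonal:
#'   the PPI network restricted to the targeted proteins.
#' @param drugs character vector of unique drug identifiers (length `n_d`).
#' @param targets character vector of unique target protein identifiers
#'   (length `n_t`).
#' @return An object of class `hetnet`: a list with elements `S_d`
#'   (dense matrix), `B_t`, `A_p` (sparse `Matrix`), `drugs`, `targets`.
#' @seealso [read_hetnet()] to build one from files.
#' @export
hetnet <- function(S_d, B_t, A_p, drugs, targets) {
  S_d <- as.matrix(S_d)
  B_t <- methods::as(methods::as(Matrix::Matrix(B_t, sparse = TRUE), "dMatrix"), "generalMatrix")
  A_p <- methods::as(methods::as(Matrix::Matrix(A_p, sparse = TRUE), "dMatrix"), "generalMatrix")
  drugs <- as.character(drugs)
  targets <- as.character(targets)
  n_d <- length(drugs)
  n_t <- length(targets)

  if (anyDuplicated(drugs)) stop("duplicated drug identifiers", call. = FALSE)
  if (anyDuplicated(targets)) stop("duplicated target identifiers", call. = FALSE)
  if (!all(dim(S_d) == c(n_d, n_d))) {
    stop("S_d must be ", n_d, "x", n_d, call. = FALSE)
  }
  if (!all(dim(B_t) == c(n_d, n_t))) {
    stop("B_t must be ", n_d, "x", n_t, call. = FALSE)
  }
  if (!all(dim(A_p) == c(n_t, n_t))) {
    stop("A_p must be ", n_t, "x", n_t, call. = FALSE)
  }

  asym <- which(abs(S_d - t(S_d)) > 1e-8, arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    i <- asym[1L, 1L]; j <- asym[1L, 2L]
    stop(sprintf("similarity matrix not symmetric: (%s, %s) has %g vs %g",
                 drugs[i], drugs[j], S_d[i, j], S_d[j, i]), call. = FALSE)
  }
  S_d <- (S_d + t(S_d)) / 2
  # reject genuine violations; forgive floating-point dust from upstream
  # arithmetic (e.g. row-normalized factors whose diagonal is 1 + eps)
  if (any(S_d < -1e-9 | S_d > 1 + 1e-9)) {
    bad <- which(S_d < -1e-9 | S_d > 1 + 1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("similarity outside [0,1]: (%s, %s) = %g",
                 drugs[bad[1L]], drugs[bad[2L]], S_d[bad[1L], bad[2L]]),
         call. = FALSE)
  }
  S_d <- pmin(pmax(S_d, 0), 1)
  diag(S_d) <- 1

  if (!all(B_t@x %in% c(0, 1))) stop("B_t entries must be 0/1", call. = FALSE)
  if (!Matrix::isSymmetric(A_p, tol = 0)) {
    stop("A_p must be symmetric", call. = FALSE)
  }
  if (!all(A_p@x %in% c(0, 1))) stop("A_p entries must be 0/1", call. = FALSE)
  if (any(Matrix::diag(A_p) != 0)) stop("A_p must have zero diagonal", call. = FALSE)

  dimnames(S_d) <- list(drugs, drugs)
  dimnames(B_t) <- list(drugs, targets)
  dimnames(A_p) <- list(targets, targets)
  structure(list(S_d = S_d, B_t = B_t, A_p = A_p,
                 drugs = drugs, targets = targets),
            class = "hetnet")
}

#' @exportS3Method base::print
print.hetnet <- function(x, ...) {
  cat(sprintf("hetnet: %d drugs, %d targeted proteins\n",
              length(x$drugs), length(x$targets)))
  cat(sprintf("  drug-target edges: %d, PPI edges: %d\n",
              sum(x$B_t), sum(x$A_p) / 2))
  cat(sprintf("  mean off-diagonal similarity: %.4f\n",
              mean(x$S_d[upper.tri(x$S_d)])))
  invisible(x)
}

read_similarity_file <- function(path) {
  line1 <- first_data_line(path)
  if (is.null(line1)) stop("empty similarity file: ", path, call. = FALSE)
  cell1 <- strsplit(line1, "\t", fixed = TRUE)[[1L]][1L]
  if (cell1 == "" || tolower(cell1) == "id") {
    # square-matrix dialect: header row of drug ids, first column ids
    tab <- read_tsv_table(path, header = TRUE)
    ids <- as.character(tab[[1L]])
    S <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(S) <- "double"
    if (!identical(ids, colnames(S))) {
      stop("square similarity matrix: row and column ids differ", call. = FALSE)
    }
    dimnames(S) <- list(ids, ids)
    return(list(ids = ids, S = S))
  }
  # long dialect: drug, drug, similarity; symmetrized by max
  tab <- read_tsv_table(path, header = FALSE)
  if (ncol(tab) != 3L) {
    stop("long-form similarity file must have 3 columns", call. = FALSE)
  }
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  v <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(v)) stop("non-numeric similarity value in ", path, call. = FALSE)
  if (any(v < 0 | v > 1)) {
    k <- which(v < 0 | v > 1)[1L]
    stop(sprintf("similarity outside [0,1]: (%s, %s) = %g", a[k], b[k], v[k]),
         call. = FALSE)
  }
  ids <- unique(c(rbind(a, b)))
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(a, ids); ib <- match(b, ids)
  for (k in seq_along(v)) {
    S[ia[k], ib[k]] <- max(S[ia[k], ib[k]], v[k])
  }
  S <- pmax(S, t(S))
  diag(S) <- 1
  list(ids = ids, S = S)
}

read_edgelist <- function(path) {
  tab <- read_tsv_table(path, header = FALSE)
  if (nrow(tab) == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(tab) < 2L) stop("edge list must have 2 columns: ", path, call. = FALSE)
  data.frame(from = as.character(tab[[1L]]), to = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read a heterogeneous network from three TSV files
#'
#' @param sim_path drug-drug similarity file.  Two dialects are accepted:
#'   a long form of three columns (drug, drug, similarity), symmetrized by
#'   taking the maximum of the two directed entries; or a square matrix
#'   whose first line is a header starting with an empty cell or `id`
#'   followed by the drug ids, with ids repeated in the first column.
#' @param dt_path drug-target edge list (two columns: drug id, protein id).
#' @param ppi_path protein-protein interaction edge list (two columns).
#'   Edges touching proteins that are never targeted are dropped (with a
#'   message reporting the count): only the subgraph induced by targets
#'   enters the model, since non-target proteins influence no term of the
#'   objective.
#' @return A validated [hetnet]. The drug set is the union of drugs seen in
#'   the similarity and drug-target files (order of first appearance); the
#'   target set is the set of proteins appearing in `dt_path`.
#' @export
read_hetnet <- function(sim_path, dt_path, ppi_path) {
  sim <- read_similarity_file(sim_path)
  dt <- read_edgelist(dt_path)
  ppi <- read_edgelist(ppi_path)

  drugs <- unique(c(sim$ids, dt$from))
  targets <- unique(dt$to)
  if (length(targets) == 0L) stop("drug-target file has no edges", call. = FALSE)
  n_d <- length(drugs); n_t <- length(targets)

  S <- matrix(0, n_d, n_d, dimnames = list(drugs, drugs))
  S[sim$ids, sim$ids] <- sim$S
  diag(S) <- 1

  B <- Matrix::sparseMatrix(i = match(dt$from, drugs), j = match(dt$to, targets),
                            x = 1, dims = c(n_d, n_t))
  B@x[] <- pmin(B@x, 1)  # deduplicate repeated edges

  keep <- ppi$from %in% targets & ppi$to %in% targets & ppi$from != ppi$to
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " PPI edge(s) dropped (non-target protein or self-loop)")
  }
  ppi <- ppi[keep, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = match(c(ppi$from, ppi$to), targets),
                            j = match(c(ppi$to, ppi$from), targets),
                            x = 1, dims = c(n_t, n_t))
  if (length(A@x)) A@x[] <- pmin(A@x, 1)

  hetnet(S, B, A, drugs, targets)
}

## ---- CombinationLabels -----------------------------------------------------

#' Construct a set of labeled drug pairs
#'
#' Unordered drug pairs carrying a combination label: `+1` for a
#' synergistic/additive interaction, `-1` for antagonistic/suppressive.
#' Pairs never observed are implicitly unlabeled (treated as 0 by the
#' prediction function, never stored).
#'
#' @param i,j integer drug indices (1-based positions into `drugs`).
#' @param label integer vector in `{-1, +1}`.
#' @param drugs character vector of drug identifiers the indices refer to.
#' @return An object of class `combination_labels`: a data frame with
#'   columns `i`, `j` (with `i < j`), `label`, and attribute `drugs`.
#' @export
combination_labels <- function(i, j, label, drugs) {
  i <- as.integer(i); j <- as.integer(j); label <- as.integer(label)
  stopifnot(length(i) == length(j), length(i) == length(label))
  if (any(label != 1L & label != -1L)) {
    stop("labels must be -1 or +1", call. = FALSE)
  }
  if (any(i == j)) stop("self-pairs are not allowed", call. = FALSE)
  n_d <- length(drugs)
  if (length(i) && (min(i, j) < 1L || max(i, j) > n_d)) {
    stop("drug index out of range", call. = FALSE)
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  # conflicting duplicate labels are an input error; identical ones collapse
  lab_by_key <- split(label, key)
  bad <- names(lab_by_key)[vapply(lab_by_key, function(l) length(unique(l)) > 1L,
                                  logical(1L))]
  if (length(bad)) {
    idx <- as.integer(strsplit(bad[1L], " ", fixed = TRUE)[[1L]])
    stop(sprintf("conflicting labels for pair (%s, %s)",
                 drugs[idx[1L]], drugs[idx[2L]]), call. = FALSE)
  }
  out <- data.frame(i = lo[first], j = hi[first], label = label[first])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, drugs = as.character(drugs), class = c("combination_labels", "data.frame"))
}

#' @exportS3Method base::print
print.combination_labels <- function(x, ...) {
  cat(sprintf("combination_labels: %d pairs (%d synergistic, %d antagonistic) over %d drugs\n",
              nrow(x), sum(x$label == 1L), sum(x$label == -1L),
              length(attr(x, "drugs"))))
  invisible(x)
}

#' Read labeled drug pairs from a TSV file
#'
#' @param path TSV of three columns (drug id, drug id, label), no header;
#'   labels must be `-1` or `+1`.  The pair set is symmetric: `(a, b, +1)`
#'   and `(b, a, +1)` collapse to one stored pair; the same pair with
#'   conflicting labels is an error, as are self-pairs.
#' @param drugs character vector of known drug identifiers; any unknown id
#'   in the file is an error.
#' @return A [combination_labels] object.
#' @export
read_labels <- function(path, drugs) {
  tab <- read_tsv_table(path, header = FALSE)
  if (nrow(tab) == 0L) {
    return(combination_labels(integer(), integer(), integer(), drugs))
  }
  if (ncol(tab) != 3L) stop("label file must have 3 columns", call. = FALSE)
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  lab <- suppressWarnings(as.integer(tab[[3L]]))
  if (anyNA(lab) || any(lab != 1L & lab != -1L)) {
    k <- which(is.na(lab) | (lab != 1L & lab != -1L))[1L]
    stop(sprintf("label must be -1 or +1, got '%s' for pair (%s, %s)",
                 tab[[3L]][k], a[k], b[k]), call. = FALSE)
  }
  unknown <- setdiff(c(a, b), drugs)
  if (length(unknown)) {
    stop("unknown drug id(s) in label file: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(a == b)) {
    stop("self-pair in label file: ", a[which(a == b)[1L]], call. = FALSE)
  }
  combination_labels(match(a, drugs), match(b, drugs), lab, drugs)
}

## ---- EmbeddingState ---------------------------------------------------------

#' Construct an embedding state (the four factor matrices)
#'
#' Holds the nonnegative factors of the two factorizations: `W_d` and the
#' auxiliary `H_d` from the (relaxed) symmetric factorization of the drug
#' similarity matrix, and `W_t` (drug side) / `H_t` (protein side) from the
#' drug-target factorization.  All share the embedding dimension `k`.
#'
#' @param W_d,H_d nonnegative `n_d x k` matrices.
#' @param W_t nonnegative `n_d x k` matrix.
#' @param H_t nonnegative `n_t x k` matrix.
#' @return An object of class `embedding_state`.
#' @export
embedding_state <- function(W_d, H_d, W_t, H_t) {
  W_d <- as.matrix(W_d); H_d <- as.matrix(H_d)
  W_t <- as.matrix(W_t); H_t <- as.matrix(H_t)
  k <- ncol(W_d)
  if (k < 1L) stop("embedding dimension k must be >= 1", call. = FALSE)
  if (ncol(H_d) != k || ncol(W_t) != k || ncol(H_t) != k) {
    stop("all factors must share the embedding dimension k", call. = FALSE)
  }
  if (nrow(H_d) != nrow(W_d) || nrow(W_t) != nrow(W_d)) {
    stop("W_d, H_d, W_t must have one row per drug", call. = FALSE)
  }
  for (nm in c("W_d", "H_d", "W_t", "H_t")) {
    if (any(get(nm) < 0)) stop(nm, " must be nonnegative", call. = FALSE)
  }
  structure(list(W_d = W_d, H_d = H_d, W_t = W_t, H_t = H_t, k = k),
            class = "embedding_state")
}

#' @exportS3Method base::print
print.embedding_state <- function(x, ...) {
  cat(sprintf("embedding_state: %d drugs, %d proteins, k = %d\n",
              nrow(x$W_d), nrow(x$H_t), x$k))
  invisible(x)
}

write_factor_tsv <- function(M, path) {
  ids <- rownames(M)
  if (is.null(ids)) stop("factor matrix has no row identifiers", call. = FALSE)
  k <- ncol(M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", paste0("f", seq_len(k))), collapse = "\t"), con)
  body <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(ids, body, sep = "\t"), con)
}

read_factor_tsv <- function(path) {
  tab <- read_tsv_table(path, header = TRUE)
  ids <- as.character(tab[[1L]])
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  colnames(M) <- NULL  # columns are positional (f1..fk)
  M
}

#' Write / read an embedding state as TSV factor matrices
#'
#' Writes one TSV per factor (`W_d.tsv`, `H_d.tsv`, `W_t.tsv`, `H_t.tsv`)
#' with header `id f1 ... fk` and one row per drug/protein, at full decimal
#' precision so a write/read round trip is bit-identical.
#'
#' @param state an [embedding_state] whose matrices carry row names
#'   (drug/protein ids).
#' @param dir output directory (created if missing).
#' @return `write_embedding` returns the vector of file paths invisibly;
#'   `read_embedding` returns the reconstructed [embedding_state].
#' @export
write_embedding <- function(state, dir) {
  stopifnot(inherits(state, "embedding_state"))
  if (state$k < 1L) stop("degenerate embedding dimension", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- file.path(dir, c("W_d.tsv", "H_d.tsv", "W_t.tsv", "H_t.tsv"))
  write_factor_tsv(state$W_d, paths[1L])
  write_factor_tsv(state$H_d, paths[2L])
  write_factor_tsv(state$W_t, paths[3L])
  write_factor_tsv(state$H_t, paths[4L])
  invisible(paths)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(dir) {
  embedding_state(read_factor_tsv(file.path(dir, "W_d.tsv")),
                  read_factor_tsv(file.path(dir, "H_d.tsv")),
                  read_factor_tsv(file.path(dir, "W_t.tsv")),
                  read_factor_tsv(file.path(dir, "H_t.tsv")))
}
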