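# Drug-drug similarity from ATC code sets, binary structural fingerprints,
# or their probabilistic fusion.  All three pairwise measures map into
# [0, 1] and are symmetric in their arguments.

#' Jaccard similarity of two ATC code sets
#'
#' Drugs are annotated with codes from the Anatomical Therapeutic Chemical
#' (ATC) classification; the similarity of two drugs is the Jaccard index
#' of their code sets, `|intersection| / |union|`.  Codes are compared as
#' exact strings at the level supplied (no hierarchical truncation).
#'
#' @param codes_i,codes_j non-empty character vectors of ATC codes.
#' @return A number in \[0, 1\]; 1 iff the sets are equal.
#' @export
#' @examples
#' atc_similarity(c("A01", "B02", "C03"), c("B02", "C03", "D04"))  # 0.5
atc_similarity <- function(codes_i, codes_j) {
  codes_i <- unique(as.character(codes_i))
  codes_j <- unique(as.character(codes_j))
  if (length(codes_i) == 0L || length(codes_j) == 0L) {
    stop("Jaccard similarity is undefined for an empty ATC code set",
         call. = FALSE)
  }
  inter <- length(intersect(codes_i, codes_j))
  inter / (length(codes_i) + length(codes_j) - inter)
}

#' Chemical structure similarity of two binary fingerprints
#'
#' Tanimoto/Jaccard similarity over the set bits of two equal-length binary
#' molecular fingerprints (166-bit MACCS-style keys by default elsewhere):
#' `|A & B| / (|A| + |B| - |A & B|)` where `|.|` counts set bits.
#'
#' @param fp_i,fp_j binary vectors of equal length, each with at least one
#'   set bit.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' css_similarity(c(1, 1, 0, 0), c(0, 1, 1, 0))  # 1/3
css_similarity <- function(fp_i, fp_j) {
  if (length(fp_i) != length(fp_j)) {
    stop("fingerprint length mismatch: ", length(fp_i), " vs ", length(fp_j),
         call. = FALSE)
  }
  if (!all(fp_i %in% c(0, 1)) || !all(fp_j %in% c(0, 1))) {
    stop("fingerprints must be binary", call. = FALSE)
  }
  a <- sum(fp_i); b <- sum(fp_j)
  if (a == 0 || b == 0) {
    stop("all-zero fingerprint: similarity undefined", call. = FALSE)
  }
  inter <- sum(fp_i * fp_j)
  inter / (a + b - inter)
}

#' Probabilistic disjunction of two similarities
#'
#' Fuses an ATC similarity and a chemical-structure similarity into one
#' score by the probability-of-union (noisy-OR) formula
#' `1 - (1 - s_atc) * (1 - s_css)`.  The result is commutative and never
#' below either input.
#'
#' @param s_atc,s_css numbers in \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
fuse_disjunction <- function(s_atc, s_css) {
  if (any(s_atc < 0 | s_atc > 1) || any(s_css < 0 | s_css > 1)) {
    stop("similarities must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - s_atc) * (1 - s_css)
}

#' Build the full drug-drug similarity matrix
#'
#' Applies the chosen pairwise similarity to every drug pair, yielding the
#' symmetric matrix `S_d` with unit diagonal that seeds the drug-network
#' factorization.
#'
#' @param drugs character vector of drug ids (defines row/column order).
#' @param atc named list mapping each drug id to its non-empty character
#'   vector of ATC codes (required for modes `"atc"` and `"fused"`).
#' @param fingerprints matrix of 0/1 with one row per drug (row names =
#'   drug ids) (required for modes `"css"` and `"fused"`).
#' @param mode `"atc"`, `"css"`, or `"fused"` (probability disjunction of
#'   the two).
#' @return A symmetric `n_d x n_d` numeric matrix with unit diagonal and
#'   `dimnames` set to the drug ids.
#' @export
build_similarity_matrix <- function(drugs, atc = NULL, fingerprints = NULL,
                                    mode = c("atc", "css", "fused")) {
  mode <- match.arg(mode)
  drugs <- as.character(drugs)
  n <- length(drugs)

  need_atc <- mode %in% c("atc", "fused")
  need_fp <- mode %in% c("css", "fused")
  if (need_atc) {
    if (is.null(atc)) stop("mode '", mode, "' requires ATC annotations", call. = FALSE)
    missing <- setdiff(drugs, names(atc))
    empty <- drugs[vapply(atc[intersect(drugs, names(atc))], length, 1L) == 0L]
    missing <- union(missing, empty)
    if (length(missing)) {
      stop("missing or empty ATC annotation for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (need_fp) {
    if (is.null(fingerprints)) stop("mode '", mode, "' requires fingerprints", call. = FALSE)
    fingerprints <- as.matrix(fingerprints)
    missing <- setdiff(drugs, rownames(fingerprints))
    if (length(missing)) {
      stop("missing fingerprint for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    F <- fingerprints[drugs, , drop = FALSE]
    if (!all(F %in% c(0, 1))) stop("fingerprints must be binary", call. = FALSE)
    if (any(rowSums(F) == 0)) {
      stop("all-zero fingerprint for: ",
           paste(drugs[rowSums(F) == 0], collapse = ", "), call. = FALSE)
    }
  }

  S_atc <- NULL
  if (need_atc) {
    S_atc <- diag(1, n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          s <- atc_similarity(atc[[drugs[i]]], atc[[drugs[j]]])
          S_atc[i, j] <- S_atc[j, i] <- s
        }
      }
    }
  }
  S_css <- NULL
  if (need_fp) {
    inter <- F %*% t(F)
    sizes <- rowSums(F)
    S_css <- inter / (outer(sizes, sizes, "+") - inter)
    diag(S_css) <- 1
  }

  S <- switch(mode,
              atc = S_atc,
              css = S_css,
              fused = fuse_disjunction(S_atc, S_css))
  diag(S) <- 1
  dimnames(S) <- list(drugs, drugs)
  S
}

#' Read ATC annotations
#'
#' @param path TSV of two columns: drug id, pipe-separated ATC codes.
#'   Empty code sets are rejected (drugs without annotation must be handled
#'   upstream, never silently scored 0).
#' @return Named list of character vectors.
#' @export
read_atc <- function(path) {
  tab <- read_tsv_table(path, header = FALSE)
  if (ncol(tab) != 2L) stop("ATC file must have 2 columns", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated drug id in ATC file", call. = FALSE)
  codes <- strsplit(as.character(tab[[2L]]), "|", fixed = TRUE)
  codes <- lapply(codes, function(x) unique(x[nzchar(x)]))
  empty <- ids[vapply(codes, length, 1L) == 0L]
  if (length(empty)) {
    stop("empty ATC code set for: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  names(codes) <- ids
  codes
}

hex_to_bits <- function(hex, n_bits) {
  digits <- strtoi(strsplit(toupper(hex), "")[[1L]], base = 16L)
  if (anyNA(digits)) stop("invalid hex fingerprint: ", hex, call. = FALSE)
  bits <- as.integer(unlist(lapply(digits, function(d) {
    as.integer(bitwAnd(d, c(8L, 4L, 2L, 1L)) > 0L)
  })))
  if (length(bits) < n_bits) {
    stop("hex fingerprint too short for ", n_bits, " bits", call. = FALSE)
  }
  # MSB-first encoding, padded at the front up to a whole number of digits
  utils::tail(bits, n_bits)
}

#' Read binary molecular fingerprints
#'
#' @param path TSV of two columns: drug id, then either `n_bits`
#'   space-separated 0/1 values or a hex string (auto-detected; hex is
#'   decoded most-significant-bit first).
#' @param n_bits fingerprint length; defaults to 166, the MACCS key count.
#' @return Binary matrix with one row per drug (row names = drug ids).
#' @export
read_fingerprints <- function(path, n_bits = 166L) {
  tab <- read_tsv_table(path, header = FALSE)
  if (ncol(tab) != 2L) stop("fingerprint file must have 2 columns", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated drug id in fingerprint file", call. = FALSE)
  raw <- trimws(as.character(tab[[2L]]))
  M <- t(vapply(raw, function(s) {
    if (grepl(" ", s, fixed = TRUE)) {
      bits <- suppressWarnings(as.integer(strsplit(s, " +")[[1L]]))
      if (anyNA(bits) || !all(bits %in% 0:1)) {
        stop("fingerprint bits must be 0/1", call. = FALSE)
      }
      if (length(bits) != n_bits) {
        stop("fingerprint length ", length(bits), " != ", n_bits, call. = FALSE)
      }
      bits
    } else {
      hex_to_bits(s, n_bits)
    }
  }, integer(n_bits), USE.NAMES = FALSE))
  rownames(M) <- ids
  zero <- ids[rowSums(M) == 0L]
  if (length(zero)) {
    stop("all-zero fingerprint for: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  M
}
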