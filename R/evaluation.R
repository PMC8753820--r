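# Classification metrics and the stratified 10-fold cross-validation
# harness.  The split unit is the labeled pair: the network matrices carry
# no combination labels, so they are shared across folds and only the
# classifier term ever sees training labels.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth vectors in `{-1, +1}`.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`,
#'   `P = TP + FN`, `N = TN + FP`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    stop("predicted/truth must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!predicted %in% c(-1, 1)) || any(!truth %in% c(-1, 1))) {
    stop("labels must be -1/+1", call. = FALSE)
  }
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == -1)
  tn <- sum(predicted == -1 & truth == -1)
  fn <- sum(predicted == -1 & truth == 1)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 P = tp + fn, N = tn + fp),
            class = "confusion_counts")
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F-measure and the Matthews correlation
#' coefficient, with the MCC denominator written as
#' `sqrt(P * N * (TP+FP) * (TN+FN))` (algebraically identical to the
#' standard four-factor form since `P = TP + FN` and `N = TN + FP`).
#' Undefined ratios (zero denominators) return 0 with a warning rather
#' than `NaN`.
#'
#' @param counts a [confusion_counts()] result (or a list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Named list: `accuracy`, `precision`, `recall`, `f_measure`,
#'   `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total < 1L) stop("empty confusion counts", call. = FALSE)
  p <- tp + fn; n <- tn + fp
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, p, "recall")
  f_measure <- if (precision + recall == 0) {
    warning("zero denominator in f_measure; returning 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  denom <- sqrt(p) * sqrt(n) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) {
    warning("zero denominator in mcc; returning 0", call. = FALSE)
    0
  } else (tp * tn - fp * fn) / denom
  list(accuracy = accuracy, precision = precision, recall = recall,
       f_measure = f_measure, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (Mann-Whitney): the fraction of
#' (positive, negative) score pairs that are concordant, with ties counted
#' one half.  Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric decision scores.
#' @param labels vector in `{-1, +1}`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- labels == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Precision-weighted recall increments over the ranking by decreasing
#' score: `AP = sum_k (R_k - R_{k-1}) * P_k`.  Tied scores are grouped so
#' the result does not depend on their internal order.
#'
#' @inheritParams roc_auc
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- labels == 1
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("AP requires at least one positive", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- as.integer(pos[o])
  # evaluate at the end of each tie group
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  k <- grp_end
  prec <- tp / k
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign_class <- function(idx) {
    idx <- sample(idx)
    split(idx, rep_len(seq_len(folds), length(idx)))
  }
  pos <- which(labels$label == 1L)
  neg <- which(labels$label == -1L)
  if (length(pos) < folds || length(neg) < folds) {
    stop("need at least ", folds, " labeled pairs per class; ",
         "use fewer folds", call. = FALSE)
  }
  fp <- assign_class(pos); fn <- assign_class(neg)
  lapply(seq_len(folds), function(f) sort(c(fp[[f]], fn[[f]])))
}

subset_labels <- function(labels, idx) {
  combination_labels(labels$i[idx], labels$j[idx], labels$label[idx],
                     attr(labels, "drugs"))
}

#' Stratified k-fold cross-validation of the joint model
#'
#' Partitions the labeled pairs (not the drugs) into stratified folds; for
#' each fold the model is fitted on the training pairs only -- the held-out
#' pairs' labels are invisible to the classifier term -- and the held-out
#' pairs are scored.  The network matrices are shared across folds, as
#' they carry no combination labels.
#'
#' @param net a [hetnet].
#' @param labels a [combination_labels].
#' @param config a [train_config()].
#' @param folds number of folds (default 10).
#' @param seed integer seed fixing the partition.
#' @param fitter fitting function, [fit_joint()] (default) or
#'   [fit_independent()].
#' @return List of class `cv_result`: `per_fold` (data frame of metrics
#'   per fold, including `auc` and `ap`), `mean`, `sd`, and `folds` (the
#'   held-out index sets).
#' @export
kfold_cv <- function(net, labels, config = train_config(), folds = 10L,
                     seed = 1L, fitter = fit_joint) {
  fold_idx <- stratified_folds(labels, folds, seed)
  rows <- lapply(seq_along(fold_idx), function(f) {
    test_idx <- fold_idx[[f]]
    train <- subset_labels(labels, setdiff(seq_len(nrow(labels)), test_idx))
    test <- subset_labels(labels, test_idx)
    if (length(unique(train$label)) < 2L) {
      stop("a class is absent from the training pairs of fold ", f,
           "; use fewer folds", call. = FALSE)
    }
    fit <- fitter(net, train, config)
    pred <- predict(fit, test)
    m <- classification_metrics(confusion_counts(pred$label, test$label))
    c(fold = f, unlist(m),
      auc = roc_auc(pred$score, test$label),
      ap = average_precision(pred$score, test$label),
      n_test = nrow(test))
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2L, stats::sd),
                 folds = fold_idx),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d pairs)\n",
              nrow(x$per_fold), sum(x$per_fold$n_test)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-10s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param cv a [kfold_cv()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(cv, path) {
  out <- list(per_fold = cv$per_fold, mean = as.list(cv$mean),
              sd = as.list(cv$sd))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
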