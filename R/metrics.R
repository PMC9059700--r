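# Multi-label evaluation: macro precision/recall per class-averaged ratios,
# F1 as the harmonic mean of the macro averages, per-label Cohen's kappa
# (unweighted mean over the 8 labels), and macro trapezoidal ROC AUC.

#' Binarize prediction scores
#'
#' A bit is set when its score is greater than or equal to the threshold
#' (so a score of exactly 0.5 maps to 1 under the default).
#'
#' @param scores numeric vector or matrix of scores in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @return integer vector/matrix of 0/1 labels, same shape.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  out <- ifelse(scores >= threshold, 1L, 0L)
  if (is.matrix(scores)) matrix(out, nrow(scores), dimnames = dimnames(scores))
  else out
}

safe_ratio <- function(num, den, what) {
  bad <- den == 0
  if (any(bad))
    warning("degenerate ", what, " (0/0) for ", sum(bad),
            " label(s); defined as 0")
  out <- ifelse(bad, 0, num / den)
  out
}

kappa_label <- function(truth, pred) {
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- (sum(truth == 1) * sum(pred == 1) +
         sum(truth == 0) * sum(pred == 0)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(ifelse(po == 1, 1, 0))
  (po - pe) / (1 - pe)
}

auc_label <- function(truth, score) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  # trapezoidal ROC area == Mann-Whitney statistic with tie correction
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Multi-label classification metrics report
#'
#' Computes per-label confusion counts, macro-averaged precision and recall
#' (mean over the C = 8 labels of TP/(TP+FP) and TP/(TP+FN)), the F1 score
#' as the harmonic mean of those macro averages (a per-label-then-averaged
#' F1 is available via `f1_mode`), the unweighted mean of per-label Cohen's
#' kappa, and (when scores are supplied) the macro trapezoidal ROC AUC.
#' Degenerate per-label ratios (0/0) are defined as 0 with a warning; labels
#' with a single observed class are skipped in the AUC average with a
#' warning.
#'
#' @param y_true,y_pred binary matrices, records x labels (same shape).
#' @param scores optional numeric score matrix (records x labels) for AUC.
#' @param f1_mode `"macro_pr"` (harmonic mean of macro precision/recall,
#'   default) or `"per_label"` (mean of per-label F1).
#' @return object of class `metrics_report`: list with `counts` (per-label
#'   TP/FP/FN/TN data frame), `precision`, `recall`, `f1`, `kappa`, `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL,
                            f1_mode = c("macro_pr", "per_label")) {
  f1_mode <- match.arg(f1_mode)
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be binary")
  C <- ncol(y_true)
  tp <- colSums(y_true == 1 & y_pred == 1)
  fp <- colSums(y_true == 0 & y_pred == 1)
  fn <- colSums(y_true == 1 & y_pred == 0)
  tn <- colSums(y_true == 0 & y_pred == 0)
  prec_c <- safe_ratio(tp, tp + fp, "precision")
  rec_c <- safe_ratio(tp, tp + fn, "recall")
  precision <- mean(prec_c)
  recall <- mean(rec_c)
  f1 <- if (f1_mode == "macro_pr") {
    if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  } else {
    f1_c <- ifelse(prec_c + rec_c == 0, 0,
                   2 * prec_c * rec_c / (prec_c + rec_c))
    mean(f1_c)
  }
  kappa <- mean(vapply(seq_len(C), function(c)
    kappa_label(y_true[, c], y_pred[, c]), numeric(1)))
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (!all(dim(scores) == dim(y_true))) stop("scores shape mismatch")
    aucs <- vapply(seq_len(C), function(c)
      auc_label(y_true[, c], scores[, c]), numeric(1))
    if (anyNA(aucs))
      warning(sum(is.na(aucs)),
              " label(s) with a single observed class skipped in AUC")
    auc <- mean(aucs, na.rm = TRUE)
  }
  structure(list(
    counts = data.frame(label = colnames(y_true) %||% paste0("L", seq_len(C)),
                        TP = tp, FP = fp, FN = fn, TN = tn,
                        row.names = NULL),
    precision = precision, recall = recall, f1 = f1, kappa = kappa, auc = auc
  ), class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Multi-label metrics report\n")
  cat(sprintf("  macro precision %.*f | macro recall %.*f | F1 %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f1))
  cat(sprintf("  mean per-label Cohen's kappa %.*f | macro AUC %s\n",
              digits, x$kappa,
              if (is.na(x$auc)) "NA" else formatC(x$auc, digits = digits,
                                                  format = "f")))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Per-decision (challenge-granularity) score
#'
#' The fraction of correct per-record-per-label binary decisions: each of
#' the `records x labels` cells counts once. On a 500-record, 8-label test
#' configuration a submission with exactly one correct decision scores
#' 1/4000 = 0.00025.
#'
#' @param y_true,y_pred binary matrices of identical shape.
#' @return scalar in \[0, 1\].
#' @export
challenge_score <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch")
  mean(y_true == y_pred)
}
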