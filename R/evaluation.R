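#' Binary confusion matrix
#'
#' Tabulates true/false positives and negatives. Inputs may be 0/1
#' vectors, logicals, or label vectors with an explicit positive class.
#'
#' @param y_true,y_pred equal-length vectors of true and predicted labels.
#' @param positive the label counted as positive (default `1`).
#' @return An object of class `"confusion_matrix"` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must have equal positive length", call. = FALSE)
  }
  t_pos <- y_true == positive
  p_pos <- y_pred == positive
  structure(list(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                 fn = sum(t_pos & !p_pos), tn = sum(!t_pos & !p_pos)),
            class = "confusion_matrix")
}

#' Confusion matrix from explicit counts
#'
#' Convenience constructor for [compute_metrics()] when the counts are
#' already tabulated (e.g. from a published table).
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A `"confusion_matrix"` object.
#' @export
confusion_matrix_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)) |>
              stats::setNames(c("tp", "fp", "fn", "tn")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Confusion-matrix metric suite
#'
#' Computes accuracy, precision, recall (sensitivity/TPR), specificity
#' (TNR), false positive rate, F1, balanced accuracy and error rate from a
#' confusion matrix. A metric whose denominator is zero is reported as
#' `NA` (undefined), never coerced to 0.
#'
#' @param cm a [confusion_matrix()].
#' @param auc optional AUC to carry alongside (not derivable from counts).
#' @return A list of class `"classification_metrics"`.
#' @export
compute_metrics <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  bal <- if (!is.na(recall) && !is.na(specificity)) {
    (recall + specificity) / 2
  } else NA_real_
  structure(list(
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    specificity = specificity,
    fpr = div(fp, fp + tn),
    f1 = f1,
    balanced_accuracy = bal,
    error = (fp + fn) / total,
    auc = auc), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%-17s %s", names(v),
                    ifelse(is.na(v), "undefined", sprintf("%.4f", v))),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve over all score thresholds, with
#' tied scores grouped; numerically this equals the Mann-Whitney
#' concordance probability, computed here via midranks.
#'
#' @param y_true binary labels (0/1, logical, or labels with `positive`).
#' @param scores numeric scores, higher = more positive.
#' @param positive the positive label (default `1`).
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
roc_auc <- function(y_true, scores, positive = 1) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' FPR/TPR coordinates at every distinct score threshold (plus the (0,0)
#' and (1,1) endpoints), suitable for plotting or TSV export.
#'
#' @inheritParams roc_auc
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores, positive = 1) {
  pos <- y_true == positive
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tpr <- cumsum(p)[keep] / sum(pos)
  fpr <- cumsum(!p)[keep] / sum(!pos)
  data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Macro-average metrics across cascade stages
#'
#' Unweighted arithmetic mean of each metric over stages, skipping
#' undefined (`NA`) entries.
#'
#' @param per_stage non-empty list of [compute_metrics()] results.
#' @return A `"classification_metrics"` object of the means.
#' @export
stage_macro_average <- function(per_stage) {
  if (!length(per_stage)) stop("empty metrics list", call. = FALSE)
  nm <- names(per_stage[[1]])
  out <- lapply(nm, function(k) {
    v <- vapply(per_stage, function(m) as.numeric(m[[k]] %||% NA_real_),
                numeric(1))
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  names(out) <- nm
  structure(out, class = "classification_metrics")
}
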