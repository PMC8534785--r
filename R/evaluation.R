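#' Build a confusion matrix from counts
#'
#' The positive class is malignant throughout the package: a true positive
#' is a malignant lesion called malignant.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_matrix` object.
#' @export
#' @examples
#' confusion_matrix(24, 2, 18, 1)
confusion_matrix <- function(tp, fp, tn, fn) {
  for (v in list(tp, fp, tn, fn)) {
    if (!is_count(v)) stop_input("confusion-matrix counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  cat("Confusion matrix (positive class: malignant)\n")
  print(m)
  invisible(x)
}

#' Confusion matrix from label vectors
#'
#' @param truth,predicted Character or factor vectors of class labels.
#' @param positive Label treated as the positive class.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, predicted, positive = "malignant") {
  stopifnot(length(truth) == length(predicted))
  t_pos <- truth == positive
  p_pos <- predicted == positive
  confusion_matrix(
    tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
    tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos)
  )
}

#' Six confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, F1 `2TP/(2TP+FP+FN)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` and listed in the
#' `undefined` attribute rather than being coerced to zero.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f1`, `mcc`; attribute `undefined` names any
#'   metric with a zero denominator.
#' @export
#' @examples
#' compute_metrics(confusion_matrix(24, 2, 18, 1))
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop_input("cannot compute metrics from an all-zero confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  # Products can exceed integer range; work in doubles.
  mcc_den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  out <- tibble(
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    precision = prec,
    accuracy = (tp + tn) / total,
    # F1 inherits undefinedness from precision/sensitivity (harmonic mean)
    f1 = if (is.na(sens) || is.na(prec)) NA_real_ else
      ratio(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  )
  attr(out, "undefined") <- names(out)[vapply(out, is.na, logical(1))]
  out
}

#' F1 from precision and sensitivity
#'
#' The harmonic mean `2ps/(p+s)`. For any consistent confusion matrix this
#' equals the count form `2TP/(2TP+FP+FN)`.
#'
#' @param p Precision in (0, 1].
#' @param s Sensitivity (recall) in (0, 1].
#' @return The F1 score.
#' @export
#' @examples
#' f1_from_precision_sensitivity(0.92, 0.96)
f1_from_precision_sensitivity <- function(p, s) {
  stopifnot(all(p > 0 & p <= 1), all(s > 0 & s <= 1))
  2 * p * s / (p + s)
}
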