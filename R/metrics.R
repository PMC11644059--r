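#' Confusion matrix from true and predicted labels
#'
#' @param true,pred Integer class labels in `1..K`, equal length.
#' @param K Number of classes.
#' @return A `K x K` integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted classes.
#' @examples
#' confusion(c(1, 2), c(1, 2), K = 2)
#' @export
confusion <- function(true, pred, K) {
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length", call. = FALSE)
  }
  K <- as.integer(K)
  if (any(true < 1 | true > K) || any(pred < 1 | pred > K)) {
    stop(sprintf("labels must lie in 1..%d", K), call. = FALSE)
  }
  cm <- matrix(0L, K, K)
  tab <- table(factor(true, levels = seq_len(K)),
               factor(pred, levels = seq_len(K)))
  cm[] <- as.integer(tab)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest binary counts for one class
#'
#' Reduces a K-class confusion matrix to the TP/FN/FP/TN counts of class
#' `class_index` against the rest: TP is the diagonal entry, FN the rest of
#' its row, FP the rest of its column, TN everything else.
#'
#' @param cm A confusion matrix (rows true, columns predicted).
#' @param class_index Class in `1..K`.
#' @return Named integer vector `c(TP, FN, FP, TN)`; the four counts always
#'   sum to the total number of samples.
#' @export
binary_counts <- function(cm, class_index) {
  K <- nrow(cm)
  c <- as.integer(class_index)
  if (c < 1 || c > K) stop(sprintf("class_index must lie in 1..%d", K), call. = FALSE)
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Accuracy is the trace over the total. Sensitivity (recall, TP/(TP+FN))
#' and specificity (TN/(TN+FP)) are computed per class in the one-vs-rest
#' reduction and macro-averaged with equal class weight. A class never seen
#' among the true labels has undefined sensitivity: it is flagged
#' (`defined = FALSE`) and excluded from the macro mean.
#'
#' @param cm A confusion matrix (rows true, columns predicted) with a
#'   positive total.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `specificity` (macro means) and `per_class` (data frame
#'   with per-class values and the `defined` flag).
#' @examples
#' classification_metrics(matrix(c(8, 3, 2, 7), 2))  # accuracy 0.75
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is all zero", call. = FALSE)
  K <- nrow(cm)
  sens <- spec <- numeric(K)
  defined <- logical(K)
  for (c in seq_len(K)) {
    b <- binary_counts(cm, c)
    defined[c] <- (b["TP"] + b["FN"]) > 0
    sens[c] <- if (defined[c]) unname(b["TP"] / (b["TP"] + b["FN"])) else NA_real_
    spec[c] <- unname(b["TN"] / (b["TN"] + b["FP"]))
  }
  structure(
    list(accuracy = sum(diag(cm)) / total,
         sensitivity = mean(sens[defined]),
         specificity = mean(spec),
         per_class = data.frame(class = seq_len(K), sensitivity = sens,
                                specificity = spec, defined = defined)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro sensitivity %.4f | macro specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
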