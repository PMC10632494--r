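#' @include AllClasses.R
NULL

#' Confusion matrix from label vectors
#'
#' Entry (a, b) counts samples whose true class is a and predicted class b.
#'
#' @param trueLabels,predictedLabels equal-length character or factor
#'   vectors; every label must belong to \code{classes}
#' @param classes class vocabulary fixing row/column order
#' @return classes x classes integer matrix, rows = true, columns = predicted
#' @examples
#' confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, classes) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("true and predicted label vectors must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(trueLabels, predictedLabels)), classes)
  if (length(bad) > 0L)
    stop(sprintf("label(s) outside the class vocabulary: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- table(factor(trueLabels, levels = classes),
             factor(predictedLabels, levels = classes))
  matrix(as.integer(m), length(classes), length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Binary classification metrics from one-vs-rest counts
#'
#' Computes the five confusion-matrix metrics:
#' accuracy \eqn{= (TP+TN)/(TP+TN+FP+FN)},
#' sensitivity (recall) \eqn{= TP/(TP+FN)},
#' specificity \eqn{= TN/(TN+FP)},
#' precision \eqn{= TP/(TP+FP)}, and
#' F1 \eqn{= 2 \cdot precision \cdot recall / (precision + recall)}.
#' A ratio with a zero denominator is returned as 0 and flagged in
#' \code{degenerate}, keeping the report total without masking degenerate
#' evaluations.
#'
#' @param counts a \linkS4class{ConfusionCounts} with at least one nonzero
#'   count
#' @return named list: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f1}, and \code{degenerate}
#'   (named logical vector flagging zero-denominator metrics)
#' @examples
#' binaryMetrics(confusionCounts(tp = 9, fp = 2, tn = 8, fn = 1))
#' @export
binaryMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0L)
    stop("all-zero confusion counts: nothing was evaluated", call. = FALSE)
  safe <- function(num, den) if (den == 0L) c(0, TRUE) else c(num / den, FALSE)
  acc <- safe(tp + tn, total)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1den <- prec[1] + sens[1]
  f1 <- if (f1den == 0) c(0, TRUE) else c(2 * prec[1] * sens[1] / f1den, FALSE)
  list(accuracy = acc[1], sensitivity = sens[1], specificity = spec[1],
       precision = prec[1], f1 = f1[1],
       degenerate = c(accuracy = as.logical(acc[2]),
                      sensitivity = as.logical(sens[2]),
                      specificity = as.logical(spec[2]),
                      precision = as.logical(prec[2]),
                      f1 = as.logical(f1[2])))
}

#' One-vs-rest counts for a single class of a confusion matrix
#'
#' @param m square confusion matrix (rows = true, columns = predicted)
#' @param classIndex index of the positive class
#' @param classes optional class vocabulary for labeling
#' @return a \linkS4class{ConfusionCounts}
#' @export
oneVsRestCounts <- function(m, classIndex, classes = rownames(m)) {
  tp <- m[classIndex, classIndex]
  fn <- sum(m[classIndex, ]) - tp
  fp <- sum(m[, classIndex]) - tp
  tn <- sum(m) - tp - fn - fp
  confusionCounts(tp = tp, fp = fp, tn = tn, fn = fn,
                  class = if (is.null(classes)) as.character(classIndex)
                          else classes[classIndex])
}

#' Multi-class evaluation report
#'
#' Derives one-vs-rest \linkS4class{ConfusionCounts} per class from a
#' confusion matrix, computes the five metrics per class via
#' \code{\link{binaryMetrics}}, and macro-averages them (unweighted mean
#' across classes).
#'
#' @param m square confusion matrix matching \code{classes}
#' @param classes class vocabulary
#' @return an \linkS4class{EvaluationReport}
#' @examples
#' m <- confusionMatrix(rep(c("A", "B", "C"), each = 4),
#'                      rep(c("A", "B", "C"), each = 4), c("A", "B", "C"))
#' macroMetrics(multiclassReport(m, c("A", "B", "C")))
#' @export
multiclassReport <- function(m, classes) {
  if (nrow(m) != ncol(m))
    stop("confusion matrix must be square", call. = FALSE)
  if (nrow(m) != length(classes))
    stop("matrix dimension must match the class vocabulary", call. = FALSE)
  per <- lapply(seq_along(classes), function(ci) {
    cc <- oneVsRestCounts(m, ci, classes)
    bm <- binaryMetrics(cc)
    data.frame(class = classes[ci], tp = cc@tp, fp = cc@fp, tn = cc@tn,
               fn = cc@fn, accuracy = bm$accuracy, sensitivity = bm$sensitivity,
               specificity = bm$specificity, precision = bm$precision,
               f1 = bm$f1, degPrecision = bm$degenerate["precision"],
               degSensitivity = bm$degenerate["sensitivity"],
               degSpecificity = bm$degenerate["specificity"],
               row.names = NULL)
  })
  perClass <- do.call(rbind, per)
  macro <- c(accuracy = mean(perClass$accuracy),
             sensitivity = mean(perClass$sensitivity),
             specificity = mean(perClass$specificity),
             precision = mean(perClass$precision),
             f1 = mean(perClass$f1))
  dimnames(m) <- list(true = classes, predicted = classes)
  new("EvaluationReport", matrix = m, classes = as.character(classes),
      perClass = perClass, macro = macro)
}

#' Evaluate predictions directly from label vectors
#'
#' Convenience wrapper: confusion matrix plus multi-class report in one
#' call.
#'
#' @inheritParams confusionMatrix
#' @return an \linkS4class{EvaluationReport}
#' @export
evaluatePredictions <- function(trueLabels, predictedLabels,
                                classes = sort(unique(as.character(trueLabels)))) {
  multiclassReport(confusionMatrix(trueLabels, predictedLabels, classes),
                   classes)
}
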