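# Confusion-matrix metrics for the stage classifiers.  Positive class:
# R + T at stage 1 (the negative class is N), R at stage 2 (negative T).
# Metrics are computed on labelled voxels only, never on whole grids.

#' Evaluate a classifier on a labelled test set
#'
#' Thresholds predicted probabilities at 0.5 (ties positive), forms the
#' 2x2 confusion matrix and reports accuracy, sensitivity (recall of the
#' positive class), specificity, precision and F1.  Two F1 variants are
#' given: `f1` is the binary harmonic mean of precision and sensitivity for
#' the positive class; `f1_macro` averages the per-class F1 of both
#' classes.  Metrics undefined on a single-class test set are reported as
#' `NA`, never as zero.
#'
#' @param model a fitted model with a `predict(..., type = "prob")` method,
#'   or a numeric vector of probabilities.
#' @param test a `stage_dataset` (or, if `model` is numeric, the 0/1 truth
#'   vector).
#' @return An object of class `classifier_metrics`.
#' @examples
#' m <- evaluate_metrics(c(.9, .8, .2, .6), c(1, 1, 0, 0))
#' m$accuracy
#' @export
evaluate_metrics <- function(model, test) {
  if (is.numeric(model)) {
    p <- model
    y <- if (inherits(test, "stage_dataset")) test$y else test
  } else {
    stopifnot(inherits(test, "stage_dataset"))
    if (!length(test$y)) stopf("evaluate_metrics: empty test set")
    p <- predict(model, test, type = "prob")
    y <- test$y
  }
  pred <- as.integer(p >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  # macro-F1: average of positive-class F1 and negative-class F1
  prec0 <- rat(tn, tn + fn); sens0 <- spec
  f1_0 <- if (is.na(prec0) || is.na(sens0) || prec0 + sens0 == 0) NA_real_
  else 2 * prec0 * sens0 / (prec0 + sens0)
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = sens, specificity = spec, precision = prec,
    f1 = f1, f1_macro = mean(c(f1, f1_0)),
    confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                       dimnames = list(truth = c("0", "1"),
                                       predicted = c("0", "1")))),
    class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat("<classifier_metrics>\n")
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "precision",
                  "f1", "f1_macro")])
  print(round(100 * v, 3))
  cat("confusion (rows truth, cols predicted):\n")
  print(x$confusion)
  invisible(x)
}
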