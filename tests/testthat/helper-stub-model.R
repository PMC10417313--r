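predict.stub_model <- function(object, newdata, type = "prob", ...) {
  x <- if (inherits(newdata, "stage_dataset")) newdata$x else newdata
  n <- if (is.matrix(x)) nrow(x) else 1L
  p <- rep(object$probs, length.out = n)
  if (type == "class") as.integer(p >= 0.5) else p
}
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
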