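# Grad-CAM for the 1D-CNN models: gradient-weighted activations of the
# final convolutional block (its pooled feature maps), rectified, upsampled
# to the input length and min-max scaled.  Explains which ppm regions drive
# a decision.

#' Grad-CAM relevance map for one spectrum
#'
#' Computes the gradient of the class score with respect to the final
#' convolutional block's pooled activations, combines gradients and
#' activations into a per-position relevance, rectifies (negative evidence
#' is discarded), upsamples to the input length and min-max scales to
#' `[0, 1]` (an all-zero raw map stays all-zero).  For the single-sigmoid
#' head, the score of the positive class is the pre-sigmoid logit and the
#' score of the negative class is its negation.
#'
#' Two combination rules are offered.  `"gradient_x_activation"` (default)
#' rectifies the elementwise product of gradient and activation summed
#' over filters; for a global-average-pooling head it coincides with the
#' original formulation, and for the flatten-plus-dense head used here it
#' is the faithful attribution.  `"average_gradient"` is the original
#' recipe (per-filter weights as position-averaged gradients, then a
#' rectified weighted activation sum); on flatten heads it can misplace
#' relevance because averaging discards the position structure of the
#' gradient, so it is provided for comparison rather than as the default.
#'
#' @param model a fitted `cnn1d` model.
#' @param spectrum numeric vector of length `input_length` (preprocessed
#'   the same way as training data).
#' @param target_class `"positive"` (the class the sigmoid points at:
#'   tumour at stage 1, responding at stage 2) or `"negative"`.
#' @param upsample `"linear"` (default) or `"nearest"`.
#' @param method relevance combination rule, see Details.
#' @return An object of class `activation_map`: `values` (length equal to
#'   the input), `target_class`, and `source_layer`.
#' @export
grad_cam <- function(model, spectrum,
                     target_class = c("positive", "negative"),
                     upsample = c("linear", "nearest"),
                     method = c("gradient_x_activation",
                                "average_gradient")) {
  target_class <- match.arg(target_class)
  upsample <- match.arg(upsample)
  method <- match.arg(method)
  if (!inherits(model, "cnn1d") || is.null(model$params))
    stopf("grad_cam: needs a trained cnn1d model (with convolutional layers)",
          class = "mrsinet_unsupported_model")
  arch <- model$arch
  X <- matrix(spectrum, nrow = 1)
  if (ncol(X) != arch$input_length)
    stopf("grad_cam: spectrum length %d but the model expects %d",
          ncol(X), arch$input_length)
  fw <- forward_cnn(model$params, arch, X, want_cache = TRUE)
  d <- fw$final_dim                              # (L_final, C_final, 1)
  A <- matrix(fw$blocks[[length(fw$blocks)]]$pool$out, d[1], d[2])
  # d(score)/d(flat), score = pre-sigmoid logit (negated for the negative
  # class); dropout is inactive at inference so the chain is dense-only.
  sgn <- if (target_class == "positive") 1 else -1
  dA1 <- sgn * t(model$params$W2)                # 1 x dense_units
  dH <- dA1 * leaky_grad(fw$H, arch$leaky_slope)
  dflat <- dH %*% t(model$params$W1)             # 1 x (L_final*C_final)
  G <- matrix(dflat, d[1], d[2])                 # gradient w.r.t. A
  raw <- if (method == "average_gradient") {
    w <- colMeans(G)                             # one weight per filter
    pmax(0, as.numeric(A %*% w))                 # rectified weighted sum
  } else {
    pmax(0, rowSums(G * A))                      # rectified grad x act
  }
  xi <- seq(0, 1, length.out = length(raw))
  xo <- seq(0, 1, length.out = arch$input_length)
  up <- if (upsample == "linear") approx(xi, raw, xout = xo)$y
  else raw[pmin(length(raw), pmax(1L, round(xo * (length(raw) - 1)) + 1L))]
  rng <- range(up)
  values <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1])
  else if (rng[2] == 0) up                       # all-zero stays all-zero
  else rep(1, length(up))
  structure(list(values = values, target_class = target_class,
                 source_layer = sprintf("conv_block_%d_pooled",
                                        length(arch$conv_filters))),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d points, class %s, source %s, max at %d\n",
              length(x$values), x$target_class, x$source_layer,
              which.max(x$values)))
  invisible(x)
}

#' Class-average spectrum and relevance overlay
#'
#' Pointwise means of a set of same-class spectra and of their Grad-CAM
#' maps — the summary used to display where a model looks when deciding a
#' class.
#'
#' @param spectra matrix of spectra (rows), all of one class.
#' @param maps list of [grad_cam()] maps aligned with the rows of
#'   `spectra` (or a matrix of map values in rows).
#' @return List with `mean_spectrum` and `mean_map`.
#' @export
class_average_overlay <- function(spectra, maps) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (nrow(spectra) == 0) stopf("class_average_overlay: empty input")
  mv <- if (is.list(maps))
    do.call(rbind, lapply(maps, function(m)
      if (inherits(m, "activation_map")) m$values else m))
  else maps
  if (nrow(mv) != nrow(spectra) || ncol(mv) != ncol(spectra))
    stopf("class_average_overlay: spectra and maps are not aligned")
  list(mean_spectrum = colMeans(spectra), mean_map = colMeans(mv))
}

#' Average Grad-CAM relevance of a model over a set of spectra
#'
#' Convenience wrapper: one [grad_cam()] per row, then the class-average
#' overlay.
#'
#' @param model fitted `cnn1d`.
#' @param spectra matrix of (preprocessed) spectra in rows.
#' @param target_class passed to [grad_cam()].
#' @return As [class_average_overlay()].
#' @export
gradcam_class_average <- function(model, spectra,
                                  target_class = "positive") {
  maps <- lapply(seq_len(nrow(spectra)), function(i)
    grad_cam(model, spectra[i, ], target_class))
  class_average_overlay(spectra, maps)
}
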