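# The 1D-CNN classifier: architecture description, model construction,
# training with early stopping, prediction, and random hyperparameter
# search over the discrete architecture vocabulary.

FILTER_CHOICES <- c(16L, 48L, 80L, 112L, 144L)   # 16..144 step 32
KERNEL_CHOICES <- c(3L, 6L, 9L, 12L)             # 3..12 step 3
DENSE_CHOICES <- seq(64L, 512L, by = 64L)        # 64..512 step 64

#' Describe a 1D-CNN architecture
#'
#' Two to four convolutional blocks, each a length-preserving (same-padding,
#' stride 1) 1D convolution with LeakyReLU activation followed by max
#' pooling of size 2, then flatten, dropout, one LeakyReLU dense layer,
#' dropout, and a single sigmoid output unit.  Weights use He-normal
#' initialisation.
#'
#' @param conv_filters integer vector (length 2-4) of filters per block.
#' @param conv_kernels kernel sizes, same length as `conv_filters`.
#' @param dense_units units of the hidden dense layer.
#' @param dropout_rate dropout fraction applied to the flattened vector and
#'   to the dense activations (training only); default 0.5.
#' @param leaky_slope negative-side slope of the LeakyReLU (default 0.01).
#' @param input_length spectrum length (default 692).
#' @param strict if `TRUE` (default) hyperparameters must belong to the
#'   tuning vocabulary (filters 16-144 step 32, kernels 3-12 step 3, dense
#'   64-512 step 64); if `FALSE` out-of-vocabulary values only warn.
#' @return An object of class `cnn_architecture`.
#' @examples
#' arch <- cnn_architecture(c(80, 112, 112), c(12, 9, 3), 192)
#' architecture_shapes(arch)
#' @export
cnn_architecture <- function(conv_filters, conv_kernels, dense_units,
                             dropout_rate = 0.5, leaky_slope = 0.01,
                             input_length = 692L, strict = TRUE) {
  conv_filters <- as.integer(conv_filters)
  conv_kernels <- as.integer(conv_kernels)
  dense_units <- as.integer(dense_units)
  nb <- length(conv_filters)
  if (nb < 2L || nb > 4L)
    stopf("cnn_architecture: need 2-4 conv blocks (got %d)", nb)
  if (length(conv_kernels) != nb)
    stopf("cnn_architecture: %d filter entries but %d kernel sizes",
          nb, length(conv_kernels))
  if (!is.finite(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stopf("cnn_architecture: dropout_rate must be in [0, 1)")
  oov <- c(
    if (!all(conv_filters %in% FILTER_CHOICES)) "filters",
    if (!all(conv_kernels %in% KERNEL_CHOICES)) "kernel sizes",
    if (!dense_units %in% DENSE_CHOICES) "dense units")
  if (length(oov)) {
    msg <- sprintf("cnn_architecture: %s outside the search vocabulary",
                   paste(oov, collapse = ", "))
    if (strict) stopf("%s (use strict = FALSE to allow)", msg) else warning(msg)
  }
  structure(list(conv_filters = conv_filters, conv_kernels = conv_kernels,
                 dense_units = dense_units, dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope,
                 input_length = as.integer(input_length)),
            class = "cnn_architecture")
}

#' Default architecture of the normal-vs-tumour (stage 1) classifier
#'
#' Convolutions 80/k12, 112/k9, 112/k3 with a 192-unit dense layer; pooled
#' lengths 692, 346, 173, 86 and a 9632-long flattened vector.  Its tuned
#' Adam learning rate companion is 0.00081 (see [train_config()]).
#' @return A `cnn_architecture`.
#' @export
stage1_architecture <- function() {
  cnn_architecture(c(80L, 112L, 112L), c(12L, 9L, 3L), 192L)
}

#' Default architecture of the responding-vs-unresponsive (stage 2) classifier
#'
#' Convolutions 144/k9, 48/k6, 112/k3 with a 448-unit dense layer; the same
#' 9632-long flattened vector as stage 1.  Tuned learning rate: 0.00075.
#' @return A `cnn_architecture`.
#' @export
stage2_architecture <- function() {
  cnn_architecture(c(144L, 48L, 112L), c(9L, 6L, 3L), 448L)
}

#' Layer-by-layer output sizes of an architecture
#'
#' Convolutions preserve length (same padding); each pooling halves it
#' (floor).  The flattened length is the final pooled length times the
#' final filter count.
#'
#' @param arch a [cnn_architecture()].
#' @return List with `conv_lengths` (input length to each conv block),
#'   `pooled_lengths` (after each pooling) and `flatten`.
#' @export
architecture_shapes <- function(arch) {
  L <- arch$input_length
  conv_in <- integer(0); pooled <- integer(0)
  for (i in seq_along(arch$conv_filters)) {
    conv_in <- c(conv_in, L)
    L <- L %/% 2L
    pooled <- c(pooled, L)
  }
  list(conv_lengths = conv_in, pooled_lengths = pooled,
       flatten = L * arch$conv_filters[length(arch$conv_filters)])
}

#' Build an (untrained) 1D-CNN model handle
#'
#' @param arch a [cnn_architecture()].
#' @return An object of class `cnn1d` holding the architecture; weights are
#'   created by [train_model()] from its config seed.
#' @export
build_cnn <- function(arch) {
  stopifnot(inherits(arch, "cnn_architecture"))
  structure(list(arch = arch, params = NULL, history = NULL, cfg = NULL),
            class = "cnn1d")
}

#' Training configuration for the 1D-CNN
#'
#' @param learning_rate Adam learning rate, within the tuned range
#'   `[1e-4, 1e-2]`.  The tuned values are 0.00081 for the stage-1 model
#'   and 0.00075 for stage 2.
#' @param batch_size minibatch size (default 32).
#' @param max_epochs epoch cap (default 100).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 10); best-validation weights are restored.
#' @param min_delta smallest validation-loss decrease counted as an
#'   improvement by the patience counter (default 1e-4), so training stops
#'   once gains become negligible.
#' @param seed integer seed governing initialisation, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.00081, batch_size = 32L,
                         max_epochs = 100L, early_stop_patience = 10L,
                         min_delta = 1e-4, seed = 1L) {
  if (!is.finite(learning_rate) ||
      learning_rate < 1e-4 || learning_rate > 1e-2)
    stopf("train_config: learning_rate must lie in [1e-4, 1e-2] (got %g)",
          learning_rate)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier on a stage dataset
#'
#' Generic over the model handle: [build_cnn()] products train by
#' minibatch Adam on binary cross-entropy with early stopping on validation
#' loss (best weights restored); [build_baseline()] products dispatch to
#' their library fitters.  Training is deterministic given `cfg$seed` on a
#' single thread.
#'
#' @param model a model handle.
#' @param train,val `stage_dataset`s (validation may be `NULL` for
#'   baselines).
#' @param cfg a [train_config()].
#' @return A fitted model object.
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  UseMethod("train_model")
}

#' @export
train_model.cnn1d <- function(model, train, val, cfg = train_config()) {
  arch <- model$arch
  stopifnot(inherits(train, "stage_dataset"), inherits(val, "stage_dataset"))
  if (!length(train$y) || !length(val$y))
    stopf("train_model: empty training or validation set")
  if (ncol(train$x) != arch$input_length)
    stopf("train_model: features have length %d but the architecture expects %d",
          ncol(train$x), arch$input_length)
  X <- train$x; y <- train$y
  with_seed(cfg$seed, {
    params <- init_cnn_params(arch)
    state <- adam_new(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), val_accuracy = numeric())
    wait <- 0L
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = cfg$batch_size)
      ep_loss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + cfg$batch_size - 1L, nrow(X))]
        fw <- forward_cnn(params, arch, X[idx, , drop = FALSE],
                          training = TRUE, want_cache = TRUE)
        loss <- bce_loss(fw$logits, y[idx])
        if (!is.finite(loss))
          stopf("train_model: non-finite loss at epoch %d (lr %g too high?)",
                ep, cfg$learning_rate)
        ep_loss <- ep_loss + loss * length(idx)
        gr <- backward_cnn(params, arch, X[idx, , drop = FALSE], y[idx], fw)
        r <- adam_step(params, gr, state, cfg$learning_rate)
        params <- r$params; state <- r$state
      }
      vl <- forward_cnn(params, arch, val$x)$logits
      val_loss <- bce_loss(vl, val$y)
      val_acc <- mean(as.integer(vl >= 0) == val$y)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / nrow(X),
                                     val_loss = val_loss,
                                     val_accuracy = val_acc))
      # an epoch only counts as an improvement (and becomes the restored
      # checkpoint) when validation loss drops by more than min_delta —
      # this also keeps the restored weights at the plateau point instead
      # of drifting into extreme-margin configurations on separable data
      if (val_loss < best$loss - (cfg$min_delta %||% 0)) {
        best <- list(loss = val_loss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    structure(list(arch = arch, params = best$params, history = hist,
                   cfg = cfg, best_epoch = best$epoch,
                   stage = train$stage),
              class = c("cnn1d_fit", "cnn1d"))
  })
}

#' Predict from a fitted 1D-CNN
#'
#' @param object a fitted `cnn1d` model.
#' @param newdata matrix of spectra (rows), a single spectrum, or a
#'   `stage_dataset`.
#' @param type `"prob"` (sigmoid probability of the positive class),
#'   `"class"` (0/1 at threshold 0.5, ties positive) or `"logit"`.
#' @param ... unused.
#' @return Numeric (or integer) vector, one value per spectrum.
#' @export
predict.cnn1d <- function(object, newdata,
                          type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  if (is.null(object$params))
    stopf("predict: model has not been trained (run train_model first)")
  X <- if (inherits(newdata, "stage_dataset")) newdata$x else
    if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != object$arch$input_length)
    stopf("predict: spectra of length %d but the model expects %d",
          ncol(X), object$arch$input_length)
  z <- forward_cnn(object$params, object$arch, X)$logits
  switch(type, logit = z, prob = sigmoid(z),
         class = as.integer(sigmoid(z) >= 0.5))   # ties go positive
}

#' @export
print.cnn1d <- function(x, ...) {
  sh <- architecture_shapes(x$arch)
  cat("<cnn1d> 1D convolutional classifier\n")
  for (i in seq_along(x$arch$conv_filters))
    cat(sprintf("  conv%d: %3d filters, kernel %2d (length %d -> pool -> %d)\n",
                i, x$arch$conv_filters[i], x$arch$conv_kernels[i],
                sh$conv_lengths[i], sh$pooled_lengths[i]))
  cat(sprintf("  flatten %d -> dropout %.2g -> dense %d -> dropout -> sigmoid\n",
              sh$flatten, x$arch$dropout_rate, x$arch$dense_units))
  if (!is.null(x$params))
    cat(sprintf("  trained: %d epochs run, best at epoch %d (val loss %.4g)\n",
                nrow(x$history), x$best_epoch, min(x$history$val_loss)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.cnn1d_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.cnn1d_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Hyperparameter search space for the 1D-CNN
#'
#' The discrete architecture vocabulary (2-4 conv layers, filters 16-144
#' step 32, kernels 3-12 step 3, dense 64-512 step 64) with a log-uniform
#' learning-rate range of `[1e-4, 1e-2]`.
#'
#' @param n_layers,filters,kernels,dense_units candidate values.
#' @param lr_range learning-rate bounds (sampled log-uniformly).
#' @param n_trials number of random-search trials.
#' @param seed integer seed.
#' @return An object of class `search_space`.
#' @export
search_space <- function(n_layers = 2:4, filters = FILTER_CHOICES,
                         kernels = KERNEL_CHOICES,
                         dense_units = DENSE_CHOICES,
                         lr_range = c(1e-4, 1e-2),
                         n_trials = 20L, seed = 1L) {
  structure(list(n_layers = n_layers, filters = filters, kernels = kernels,
                 dense_units = dense_units, lr_range = lr_range,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "search_space")
}

#' Draw one candidate configuration from a search space
#'
#' Uniform over the discrete choices; learning rate log-uniform over
#' `lr_range`.  Used by [random_search()]; exported so the sampling
#' distribution itself is testable.
#'
#' @param space a [search_space()].
#' @param seed integer seed.
#' @param input_length spectrum length.
#' @return List with `arch` (a `cnn_architecture`) and `learning_rate`.
#' @export
sample_candidate <- function(space, seed, input_length = 692L) {
  pick <- function(v, n) v[sample.int(length(v), n, replace = TRUE)]
  with_seed(seed, {
    nl <- pick(space$n_layers, 1)
    arch <- cnn_architecture(
      pick(space$filters, nl), pick(space$kernels, nl),
      pick(space$dense_units, 1), input_length = input_length)
    lr <- exp(runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
    list(arch = arch, learning_rate = lr)
  })
}

#' Random search over 1D-CNN hyperparameters
#'
#' Samples `space$n_trials` candidate configurations, trains each on the
#' fitting data, and returns the one maximising validation F1 (positive
#' class) together with the full trial log.  Failed trials are skipped and
#' recorded.
#'
#' @param space a [search_space()].
#' @param train,val `stage_dataset`s.
#' @param base_cfg a [train_config()] providing batch size, epoch cap,
#'   patience and seed; the learning rate is sampled per trial.
#' @return List with `arch`, `cfg` (best), `model` (best fit) and `trials`
#'   (data frame log).
#' @export
random_search <- function(space, train, val, base_cfg = train_config()) {
  if (space$n_trials < 1) stopf("random_search: n_trials must be >= 1")
  seeds <- child_seeds(space$seed, space$n_trials)
  trials <- data.frame()
  best <- NULL
  for (tr in seq_len(space$n_trials)) {
    cand <- sample_candidate(space, seeds[tr],
                             input_length = ncol(train$x))
    cfg <- train_config(cand$learning_rate, base_cfg$batch_size,
                        base_cfg$max_epochs, base_cfg$early_stop_patience,
                        seed = base_cfg$seed)
    rec <- data.frame(
      trial = tr,
      layers = length(cand$arch$conv_filters),
      filters = paste(cand$arch$conv_filters, collapse = "/"),
      kernels = paste(cand$arch$conv_kernels, collapse = "/"),
      dense = cand$arch$dense_units,
      learning_rate = cand$learning_rate,
      val_f1 = NA_real_, status = "ok", stringsAsFactors = FALSE)
    fit <- tryCatch(train_model(build_cnn(cand$arch), train, val, cfg),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rec$status <- conditionMessage(fit)
    } else {
      m <- evaluate_metrics(fit, val)
      rec$val_f1 <- m$f1
      if (is.null(best) || (is.finite(m$f1) && m$f1 > best$f1))
        best <- list(arch = cand$arch, cfg = cfg, model = fit, f1 = m$f1)
    }
    trials <- rbind(trials, rec)
  }
  if (is.null(best))
    stopf("random_search: every trial failed; see the trial log")
  list(arch = best$arch, cfg = best$cfg, model = best$model, trials = trials)
}
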