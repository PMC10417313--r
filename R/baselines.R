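# Baseline classifier families the 1D-CNN is benchmarked against.  Each
# family is fitted by the established library (glmnet, e1071, ranger,
# xgboost); `tuned = TRUE` sets the hyperparameters found by the original
# random search: LR C = 545.6 with elastic-net penalty, SVM C = 10 with a
# Gaussian kernel of gamma 0.5, RF with 1000 trees of depth <= 40, XGBoost
# with 100 rounds, learning rate 0.1, column subsample 0.75, depth 12.

BASELINE_FAMILIES <- c("LR", "SVM", "RF", "XGBoost")

#' Build a baseline classifier handle
#'
#' @param family one of `"LR"`, `"SVM"`, `"RF"`, `"XGBoost"`.
#' @param tuned use the tuned hyperparameters above (`TRUE`, default) or
#'   the library defaults (recorded in the handle for the run log).
#' @return An object of class `baseline_model`; fit it with
#'   [train_model()].
#' @export
build_baseline <- function(family, tuned = TRUE) {
  if (!family %in% BASELINE_FAMILIES)
    stopf("build_baseline: unknown family '%s'; options: %s",
          family, paste(BASELINE_FAMILIES, collapse = ", "))
  params <- if (tuned) switch(family,
    LR = list(C = 545.6, penalty = "elasticnet", alpha = 0.5),
    SVM = list(C = 10, kernel = "radial", gamma = 0.5),
    RF = list(n_trees = 1000L, max_depth = 40L),
    XGBoost = list(n_rounds = 100L, learning_rate = 0.1,
                   colsample_bytree = 0.75, max_depth = 12L)
  ) else switch(family,
    LR = list(C = 1, penalty = "lasso", alpha = 1),
    SVM = list(C = 1, kernel = "radial", gamma = NULL),  # 1/p at fit time
    RF = list(n_trees = 500L, max_depth = NULL),
    XGBoost = list(n_rounds = 100L, learning_rate = 0.3,
                   colsample_bytree = 1, max_depth = 6L))
  structure(list(family = family, tuned = tuned, params = params,
                 fit = NULL),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s (%s)%s\n", x$family,
              if (x$tuned) "tuned" else "library defaults",
              if (is.null(x$fit)) ", untrained" else ", fitted"))
  str(x$params, give.attr = FALSE, comp.str = "  ")
  invisible(x)
}

#' @export
train_model.baseline_model <- function(model, train, val = NULL,
                                       cfg = train_config()) {
  x <- train$x; y <- train$y; p <- model$params
  fit <- switch(model$family,
    LR = {
      # sklearn-style C maps to lambda = 1 / (n * C) in glmnet's scaling;
      # fit a short decreasing path ending at the target so the coordinate
      # descent warm-starts properly, then predict at the target lambda
      lambda <- 1 / (nrow(x) * p$C)
      path <- exp(seq(log(lambda * 1e3), log(lambda), length.out = 30))
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = p$alpha,
                            lambda = path, standardize = FALSE)
      attr(fit, "target_lambda") <- lambda
      fit
    },
    SVM = {
      g <- p$gamma %||% (1 / ncol(x))
      # scale = FALSE: gamma applies to the UL2 features themselves
      with_seed(cfg$seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = p$kernel,
                   cost = p$C, gamma = g, probability = TRUE,
                   scale = FALSE))
    },
    RF = {
      xm <- x
      colnames(xm) <- paste0("V", seq_len(ncol(xm)))
      ranger::ranger(
        x = xm, y = factor(y, levels = c(0, 1)), num.trees = p$n_trees,
        max.depth = p$max_depth %||% 0, probability = TRUE,
        seed = cfg$seed, num.threads = 1)
    },
    XGBoost = xgboost::xgb.train(
      params = list(eta = p$learning_rate,
                    colsample_bytree = p$colsample_bytree,
                    max_depth = p$max_depth,
                    objective = "binary:logistic", nthread = 1,
                    seed = cfg$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = p$n_rounds, verbose = 0))
  model$fit <- fit
  model$stage <- train$stage
  class(model) <- c("baseline_fit", "baseline_model")
  model
}

#' Predict from a fitted baseline classifier
#'
#' @param object a fitted `baseline_model`.
#' @param newdata spectra matrix or `stage_dataset`.
#' @param type `"prob"` or `"class"` (threshold 0.5, ties positive).
#' @param ... unused.
#' @return Numeric vector of positive-class probabilities or 0/1 classes.
#' @export
predict.baseline_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$fit))
    stopf("predict: baseline model has not been trained")
  x <- if (inherits(newdata, "stage_dataset")) newdata$x else newdata
  p <- switch(object$family,
    LR = as.numeric(predict(object$fit, newx = x, type = "response",
                            s = attr(object$fit, "target_lambda"))),
    SVM = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RF = {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(df)))
      predict(object$fit, data = df, num.threads = 1)$predictions[, "1"]
    },
    XGBoost = predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  p <- unname(p)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Nearest-centroid reference classifier
#'
#' A transparent, deterministic baseline: class centroids of the training
#' spectra; prediction by smaller Euclidean distance, converted to a score
#' in (0, 1) via the signed distance difference.  Used as the comparison
#' method in phantom map evaluations and as the class-separability check.
#'
#' @param train a `stage_dataset`.
#' @return An object of class `nearest_centroid` usable with `predict`.
#' @export
nearest_centroid <- function(train) {
  structure(list(
    mu0 = colMeans(train$x[train$y == 0, , drop = FALSE]),
    mu1 = colMeans(train$x[train$y == 1, , drop = FALSE]),
    stage = train$stage), class = "nearest_centroid")
}

#' @export
predict.nearest_centroid <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "stage_dataset")) newdata$x else newdata
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  d0 <- sqrt(rowSums(sweep(x, 2, object$mu0)^2))
  d1 <- sqrt(rowSums(sweep(x, 2, object$mu1)^2))
  p <- sigmoid(d0 - d1)          # closer to centroid 1 => p > 0.5
  if (type == "prob") p else as.integer(p >= 0.5)
}
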