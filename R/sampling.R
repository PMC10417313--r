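# Subject-level splitting, stage-dataset assembly and SMOTE balancing.
# The cardinal rule is leakage avoidance: every voxel of a subject lands on
# exactly one side of the split.

#' Split a cohort into train and test subjects
#'
#' The split is by subject — all of a subject's grids and voxels fall on one
#' side — so no information leaks from test animals into training.  The test
#' count is the subject count times `test_fraction`, rounded to the nearest
#' integer (28 subjects at 0.25 give a 21/7 split).
#'
#' @param cohort an `mrsi_cohort`.
#' @param test_fraction fraction of subjects held out, in (0, 1).
#' @param seed integer seed.
#' @return An object of class `split_plan` with `train_subjects`,
#'   `test_subjects` and the seed.
#' @export
split_cohort <- function(cohort, test_fraction = 0.25, seed = 1L) {
  ids <- subject_ids(cohort)
  if (length(ids) < 2) stopf("split_cohort: need at least 2 subjects")
  if (!is.finite(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stopf("split_cohort: test_fraction must be in (0, 1)")
  n_test <- round(length(ids) * test_fraction)
  if (n_test < 1 || n_test >= length(ids))
    stopf("split_cohort: fraction %g leaves an empty side for %d subjects",
          test_fraction, length(ids))
  test <- with_seed(seed, sample(ids, n_test))
  structure(list(train_subjects = sort(setdiff(ids, test)),
                 test_subjects = sort(test), seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test subjects (seed %d)\n",
              length(x$train_subjects), length(x$test_subjects), x$seed))
  invisible(x)
}

# Flatten a cohort's labelled voxels into a feature table.
cohort_voxels <- function(cohort, subjects = subject_ids(cohort)) {
  xs <- list(); prov <- list()
  for (s in cohort$subjects) {
    if (!s$id %in% subjects) next
    for (gi in seq_along(s$grids)) {
      g <- s$grids[[gi]]
      keep <- which(g$labels != "unknown")
      if (!length(keep)) next
      xs[[length(xs) + 1L]] <- g$spectra[keep, , drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(
        subject = s$id, grid = gi,
        row = (keep - 1L) %/% g$cols, col = (keep - 1L) %% g$cols,
        label = g$labels[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(xs)) return(list(x = NULL, prov = NULL))
  list(x = do.call(rbind, xs), prov = do.call(rbind, prov))
}

new_stage_dataset <- function(x, y, prov, stage) {
  structure(list(x = x, y = y, provenance = prov, stage = stage),
            class = "stage_dataset")
}

#' @export
print.stage_dataset <- function(x, ...) {
  cat(sprintf("<stage_dataset> stage %s: %d rows (%d positive, %d negative)\n",
              x$stage, length(x$y), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' Assemble the train/test datasets for one cascade stage
#'
#' Stage `"N_vs_RT"` pits normal voxels (negative class) against tumour
#' voxels of either kind (R or T, positive).  Stage `"R_vs_T"` uses only
#' tumour voxels, with responding (R) positive and unresponsive (T)
#' negative.  Unknown-labelled voxels never appear.  Spectra are UL2
#' normalised here so every model consumes identically preprocessed input;
#' each returned row is traceable to its (subject, grid, voxel).
#'
#' @param cohort an `mrsi_cohort`.
#' @param plan a [split_cohort()] plan.
#' @param stage `"N_vs_RT"` or `"R_vs_T"`.
#' @return List of two `stage_dataset`s: `train` and `test`.
#' @export
assemble_stage <- function(cohort, plan, stage = c("N_vs_RT", "R_vs_T")) {
  stage <- match.arg(stage)
  stopifnot(inherits(plan, "split_plan"))
  mk <- function(subjects) {
    cv <- cohort_voxels(cohort, subjects)
    if (is.null(cv$x))
      stopf("assemble_stage: no labelled voxels among subjects %s",
            paste(subjects, collapse = ", "))
    if (stage == "N_vs_RT") {
      y <- as.integer(cv$prov$label %in% c("R", "T"))
      x <- cv$x; prov <- cv$prov
    } else {
      keep <- cv$prov$label %in% c("R", "T")
      x <- cv$x[keep, , drop = FALSE]; prov <- cv$prov[keep, , drop = FALSE]
      y <- as.integer(prov$label == "R")
    }
    if (!length(y) || sum(y == 0L) == 0L || sum(y == 1L) == 0L)
      stopf("assemble_stage(%s): a class is empty (negatives %d, positives %d)",
            stage, sum(y == 0L), sum(y == 1L), class = "mrsinet_class_error")
    new_stage_dataset(preprocess_spectra(x, cohort$axis), y, prov, stage)
  }
  list(train = mk(plan$train_subjects), test = mk(plan$test_subjects))
}

#' Balance a training dataset with SMOTE
#'
#' Synthetic Minority Oversampling: grows the minority class up to the
#' majority count by interpolating each synthetic row between a random
#' minority row `x` and one of its `k_neighbors` nearest minority
#' neighbours `x_nn` (Euclidean): `x + u * (x_nn - x)` with `u ~ U[0, 1)`.
#' Majority rows pass through unchanged; only training data should ever be
#' balanced.  With `renormalize = TRUE` (default) synthetic rows are
#' rescaled to unit length so the UL2 invariant the models rely on holds.
#'
#' @param train a `stage_dataset` (training side only).
#' @param k_neighbors neighbour pool size (default 5).
#' @param seed integer seed.
#' @param renormalize rescale synthetic rows to unit L2 norm?
#' @return A balanced `stage_dataset`; synthetic rows carry provenance
#'   subject `"synthetic"`.
#' @export
smote_balance <- function(train, k_neighbors = 5L, seed = 1L,
                          renormalize = TRUE) {
  stopifnot(inherits(train, "stage_dataset"))
  n1 <- sum(train$y == 1); n0 <- sum(train$y == 0)
  if (n1 == n0) return(train)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  xm <- train$x[train$y == minority, , drop = FALSE]
  nm <- nrow(xm)
  if (nm < k_neighbors + 1)
    stopf(paste0("smote_balance: minority class has %d rows but k_neighbors=%d",
                 " needs at least %d; use a smaller k"),
          nm, k_neighbors, k_neighbors + 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- vapply(seq_len(nm), function(i) order(d[i, ])[seq_len(k_neighbors)],
               integer(k_neighbors))
  nn <- if (k_neighbors == 1L) matrix(nn, ncol = 1L) else t(nn)
  synth <- with_seed(seed, {
    base <- sample.int(nm, need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, need, replace = TRUE))]
    u <- runif(need)
    xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  if (renormalize) synth <- ul2_normalize(synth)
  prov_s <- data.frame(subject = "synthetic", grid = NA_integer_,
                       row = NA_integer_, col = NA_integer_,
                       label = if (train$stage == "N_vs_RT") {
                         if (minority == 1L) "T" else "N"
                       } else {
                         if (minority == 1L) "R" else "T"
                       }, stringsAsFactors = FALSE)
  new_stage_dataset(rbind(train$x, synth),
                    c(train$y, rep(minority, need)),
                    rbind(train$provenance, prov_s[rep(1, need), ]),
                    train$stage)
}

# Subject-level sub-split of a training dataset for validation during
# fitting/tuning (the held-out test set is never touched here).
validation_split <- function(train, val_fraction = 0.2, seed = 1L) {
  subs <- unique(train$provenance$subject)
  n_val <- max(1L, round(length(subs) * val_fraction))
  if (n_val >= length(subs)) n_val <- length(subs) - 1L
  if (n_val < 1L) {                      # single subject: split by rows
    idx <- with_seed(seed, sample.int(length(train$y)))
    cut <- max(1L, round(length(idx) * val_fraction))
    vi <- idx[seq_len(cut)]
  } else {
    vs <- with_seed(seed, sample(subs, n_val))
    vi <- which(train$provenance$subject %in% vs)
  }
  list(
    fit = new_stage_dataset(train$x[-vi, , drop = FALSE], train$y[-vi],
                            train$provenance[-vi, , drop = FALSE], train$stage),
    val = new_stage_dataset(train$x[vi, , drop = FALSE], train$y[vi],
                            train$provenance[vi, , drop = FALSE], train$stage))
}
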