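# The two-stage decision cascade and nosologic (colour-coded) map
# construction: stage 1 separates normal parenchyma from tumour, stage 2
# splits the tumour voxels into responding and unresponsive.

new_nosologic_map <- function(class, rows, cols, p1, p2) {
  stopifnot(all(class %in% names(CLASS_COLOURS)))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 class = class, colour = unname(CLASS_COLOURS[class]),
                 p1 = p1, p2 = p2),
            class = "nosologic_map")
}

#' Classify every voxel of a grid into a nosologic map
#'
#' The stage-1 model scores all voxels (including unknown-labelled ones —
#' the map colours the full grid).  Voxels with stage-1 probability of
#' tumour below 0.5 are finalised as N (blue); the stage-2 model scores
#' only the remainder, assigning R (green) at probability >= 0.5 and T
#' (red) otherwise.  Ties at exactly 0.5 go to the positive class at both
#' stages.  Stage-2 scores of voxels finalised at stage 1 are recorded as
#' `NA` — a voxel never carries both a final N class and a stage-2 score.
#'
#' @param grid an `mrsi_grid`.
#' @param model_stage1,model_stage2 fitted classifiers trained on the same
#'   axis and preprocessing.
#' @return A `nosologic_map` with per-voxel `class`, `colour` and audit
#'   scores `p1`, `p2`.
#' @export
classify_grid <- function(grid, model_stage1, model_stage2) {
  stopifnot(inherits(grid, "mrsi_grid"))
  n_in <- if (inherits(model_stage1, "cnn1d"))
    model_stage1$arch$input_length else ncol(grid$spectra)
  if (ncol(grid$spectra) != n_in)
    stopf("classify_grid: %d-point spectra but the model expects %d",
          ncol(grid$spectra), n_in)
  x <- preprocess_spectra(grid$spectra, grid$axis)
  p1 <- predict(model_stage1, x, type = "prob")
  tumour <- p1 >= 0.5
  cls <- rep("N", length(p1))
  p2 <- rep(NA_real_, length(p1))
  if (any(tumour)) {
    p2t <- predict(model_stage2, x[tumour, , drop = FALSE], type = "prob")
    cls[tumour] <- ifelse(p2t >= 0.5, "R", "T")
    p2[tumour] <- p2t
  }
  new_nosologic_map(cls, grid$rows, grid$cols, p1, p2)
}

#' @export
print.nosologic_map <- function(x, ...) {
  cat(sprintf("<nosologic_map> %dx%d voxels\n", x$rows, x$cols))
  print(table(class = x$class))
  invisible(x)
}

#' Class assignments of a map as a rows x cols matrix
#' @param map a `nosologic_map`.
#' @export
map_matrix <- function(map) {
  matrix(map$class, map$rows, map$cols, byrow = TRUE)
}

#' Plot a nosologic map
#'
#' Renders the colour-coded grid (blue N, red T, green R), row 0 at the
#' top, matching the stored orientation.
#'
#' @param x a `nosologic_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.nosologic_map <- function(x, ...) {
  m <- map_matrix(x)
  z <- matrix(match(m, names(CLASS_COLOURS)), x$rows, x$cols)
  graphics::image(seq_len(x$cols), seq_len(x$rows),
                  t(z[x$rows:1, , drop = FALSE]),
                  col = unname(CLASS_COLOURS), zlim = c(1, 3),
                  xlab = "col", ylab = "row", axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Classify an ordered longitudinal series of grids
#'
#' Produces one nosologic map per timepoint plus a per-day summary of the
#' responding fraction — the proportion of voxels classed R among the
#' non-N (tumour) voxels — to track the response trajectory over therapy.
#'
#' @param grids list of `mrsi_grid`s ordered by acquisition day.
#' @param model_stage1,model_stage2 fitted stage classifiers.
#' @return List with `maps` (one per timepoint) and `summary`, a data
#'   frame of `day`, `n_tumour`, `r_fraction`.
#' @export
classify_longitudinal <- function(grids, model_stage1, model_stage2) {
  if (!length(grids)) stopf("classify_longitudinal: empty grid list")
  maps <- lapply(grids, classify_grid, model_stage1, model_stage2)
  summ <- do.call(rbind, Map(function(g, m) {
    nt <- sum(m$class != "N")
    data.frame(day = if (is.na(g$day)) NA_integer_ else g$day,
               n_tumour = nt,
               r_fraction = if (nt == 0) NA_real_ else
                 sum(m$class == "R") / nt)
  }, grids, maps))
  list(maps = maps, summary = summ)
}
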