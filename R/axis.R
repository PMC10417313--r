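#' Chemical-shift axis of an MR spectrum
#'
#' Defines the ppm grid a spectrum lives on.  Points are stored in ascending
#' ppm order: index `i` (1-based) maps to
#' `ppm_min + (i - 1) * (ppm_max - ppm_min) / (n_points - 1)`.
#' Spectroscopy plots conventionally run right-to-left; that is display
#' only — storage is always ascending.  The default axis is the 692-point
#' window from 0 to 4.5 ppm used throughout the package, which concentrates
#' the diagnostically relevant metabolites and avoids the residual water
#' signal near 4.75 ppm.
#'
#' @param n_points number of points (>= 2).
#' @param ppm_min,ppm_max axis limits in ppm, `ppm_min < ppm_max`.
#' @return An object of class `ppm_axis`.
#' @examples
#' ax <- ppm_axis()
#' range(ppm_values(ax))
#' @export
ppm_axis <- function(n_points = 692L, ppm_min = 0, ppm_max = 4.5) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stopf("ppm_axis: n_points must be an integer >= 2 (got %s)", n_points)
  if (!is.finite(ppm_min) || !is.finite(ppm_max) || ppm_min >= ppm_max)
    stopf("ppm_axis: need finite ppm_min < ppm_max (got %s, %s)",
          ppm_min, ppm_max)
  structure(list(n_points = n_points, ppm_min = ppm_min, ppm_max = ppm_max),
            class = "ppm_axis")
}

#' @export
print.ppm_axis <- function(x, ...) {
  cat(sprintf("<ppm_axis> %d points, %.4g to %.4g ppm (stored ascending)\n",
              x$n_points, x$ppm_min, x$ppm_max))
  invisible(x)
}

#' Ascending ppm values of an axis
#' @param axis a [ppm_axis()].
#' @return numeric vector of length `axis$n_points`.
#' @export
ppm_values <- function(axis) {
  stopifnot(inherits(axis, "ppm_axis"))
  seq(axis$ppm_min, axis$ppm_max, length.out = axis$n_points)
}

#' Index of the axis point nearest a ppm position
#' @param axis a [ppm_axis()].
#' @param ppm numeric vector of ppm positions (must lie within the axis).
#' @return integer vector of 1-based indices.
#' @export
ppm_index <- function(axis, ppm) {
  stopifnot(inherits(axis, "ppm_axis"))
  if (any(ppm < axis$ppm_min | ppm > axis$ppm_max))
    stopf("ppm_index: position outside axis range [%g, %g]",
          axis$ppm_min, axis$ppm_max)
  step <- (axis$ppm_max - axis$ppm_min) / (axis$n_points - 1)
  as.integer(round((ppm - axis$ppm_min) / step)) + 1L
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$ppm_min - b$ppm_min) < tol && abs(a$ppm_max - b$ppm_max) < tol
}
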