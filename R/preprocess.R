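# Spectral windowing and unit-length (UL2) normalisation — applied
# identically at train and inference time.

#' Window a spectrum onto a target ppm axis
#'
#' Restricts a raw spectrum to the target ppm range (closed interval) and
#' resamples it onto the target grid by linear interpolation.  When the
#' target axis equals the raw axis the spectrum is returned unchanged.  The
#' canonical use is cutting a 2048-point acquisition spanning 13.3 ppm down
#' to the 692-point 0-4.5 ppm analysis window.
#'
#' @param raw numeric vector (one spectrum) or matrix (spectra in rows).
#' @param raw_axis [ppm_axis()] the raw data lives on.
#' @param target_axis [ppm_axis()] to resample onto; its range must lie
#'   within the raw range.
#' @return Windowed spectrum/spectra with `target_axis$n_points` columns.
#' @export
window_spectrum <- function(raw, raw_axis, target_axis = ppm_axis()) {
  stopifnot(inherits(raw_axis, "ppm_axis"), inherits(target_axis, "ppm_axis"))
  if (target_axis$ppm_min < raw_axis$ppm_min - 1e-9 ||
      target_axis$ppm_max > raw_axis$ppm_max + 1e-9)
    stopf("window_spectrum: target range [%g, %g] outside raw range [%g, %g]",
          target_axis$ppm_min, target_axis$ppm_max,
          raw_axis$ppm_min, raw_axis$ppm_max, class = "mrsinet_domain_error")
  xr <- ppm_values(raw_axis); xt <- ppm_values(target_axis)
  if (is.matrix(raw)) {
    if (ncol(raw) != raw_axis$n_points)
      stopf("window_spectrum: %d columns but raw axis has %d points",
            ncol(raw), raw_axis$n_points)
    return(t(apply(raw, 1, function(s) approx(xr, s, xout = xt)$y)))
  }
  if (length(raw) != raw_axis$n_points)
    stopf("window_spectrum: length %d but raw axis has %d points",
          length(raw), raw_axis$n_points)
  approx(xr, raw, xout = xt)$y
}

#' Unit-length (UL2) normalisation
#'
#' Scales each spectrum to unit Euclidean norm, removing arbitrary intensity
#' scale so that classifiers see shape only.  Idempotent and scale-invariant.
#'
#' @param s numeric vector, or matrix with one spectrum per row.
#' @return Same shape as `s`, each spectrum with L2 norm 1.
#' @examples
#' ul2_normalize(c(3, 4))   # 0.6 0.8
#' @export
ul2_normalize <- function(s) {
  if (is.matrix(s)) {
    nrm <- sqrt(rowSums(s^2))
    if (any(nrm == 0))
      stopf("ul2_normalize: all-zero spectrum in row(s) %s",
            paste(which(nrm == 0), collapse = ", "),
            class = "mrsinet_degenerate_error")
    return(s / nrm)
  }
  nrm <- sqrt(sum(s^2))
  if (nrm == 0)
    stopf("ul2_normalize: cannot normalise an all-zero spectrum",
          class = "mrsinet_degenerate_error")
  s / nrm
}

#' Spectral alignment hook
#'
#' Phantom spectra are generated pre-aligned, so the default alignment is
#' the identity.  The hook exists so a frequency-alignment step for real
#' acquisitions can be slotted in without touching the rest of the pipeline.
#'
#' @param s spectrum vector or matrix of spectra.
#' @param axis the [ppm_axis()] (unused by the identity hook).
#' @return `s` unchanged.
#' @export
align_spectra <- function(s, axis = ppm_axis()) s

# Shared preprocessing applied before any model sees a spectrum.
preprocess_spectra <- function(s, axis = ppm_axis()) {
  ul2_normalize(align_spectra(s, axis))
}
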