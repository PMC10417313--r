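# Synthetic MRSI phantom: Lorentzian/Gaussian metabolite peaks on the 692-point
# 0-4.5 ppm axis, three tissue-class signatures (N/T/R), spatial grid layouts
# with a tumour disc, optional responding sub-region and an unknown border rim.

#' Describe one metabolite resonance
#'
#' @param name metabolite label (free text, e.g. `"Cr"`).
#' @param center peak position in ppm.
#' @param linewidth full width at half maximum in ppm (> 0).
#' @param shape `"lorentzian"` (default; the natural MRS lineshape) or
#'   `"gaussian"`.
#' @return A one-row data frame usable as a building block of a
#'   [class_signature()].
#' @export
metabolite_peak <- function(name, center, linewidth = 0.06,
                            shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.finite(linewidth) || linewidth <= 0)
    stopf("metabolite_peak: linewidth must be > 0 (got %s)", linewidth)
  data.frame(name = name, center = center, linewidth = linewidth,
             shape = shape, stringsAsFactors = FALSE)
}

#' Spectral signature of one tissue class
#'
#' A signature is a set of metabolite peaks with mean amplitudes and a
#' between-voxel amplitude spread; a voxel of that class is a draw of
#' amplitudes around those means.
#'
#' @param class_label `"N"`, `"T"` or `"R"`.
#' @param peaks data frame of peaks ([metabolite_peak()] rows, row-bound).
#' @param mean_amp numeric vector of mean amplitudes (>= 0), one per peak
#'   (arbitrary units — UL2 normalisation removes the absolute scale).
#' @param sd_amp between-voxel standard deviations (default 8% of the mean).
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(class_label, peaks, mean_amp,
                            sd_amp = 0.08 * mean_amp) {
  if (!class_label %in% c("N", "T", "R"))
    stopf("class_signature: class_label must be one of N, T, R (got %s)",
          class_label, class = "mrsinet_class_error")
  if (nrow(peaks) != length(mean_amp) || length(mean_amp) != length(sd_amp))
    stopf("class_signature: peaks, mean_amp and sd_amp lengths differ")
  if (any(mean_amp < 0)) stopf("class_signature: mean amplitudes must be >= 0")
  structure(list(class_label = class_label, peaks = peaks,
                 mean_amp = as.numeric(mean_amp),
                 sd_amp = as.numeric(sd_amp)),
            class = "class_signature")
}

#' Default tissue-class signatures
#'
#' Encodes the qualitative metabolic contrasts between normal parenchyma (N),
#' unresponsive/control tumour (T) and tumour responding to temozolomide (R)
#' in the GL261 glioblastoma model: N shows high creatine (3.04/2.93 ppm) and
#' N-acetyl aspartate (~2.02 ppm); T shows high mobile lipids/lactate (1.34,
#' flanked by 1.21 and 1.40 ppm) with depressed NAA and creatine; R shows
#' intermediate lipids/lactate shifted to 1.23 and 0.80/0.83 ppm, elevated
#' myo-inositol/glycine at 3.54 ppm and a broad polyunsaturated fatty-acid
#' signal around 2.7-2.9 ppm.  Absolute amplitudes are arbitrary units.
#'
#' @return Named list of three [class_signature()] objects (`N`, `T`, `R`).
#' @export
default_signatures <- function() {
  n_pk <- rbind(
    metabolite_peak("Cr",  3.04), metabolite_peak("Cr/GSH", 2.93),
    metabolite_peak("NAA", 2.02), metabolite_peak("Cho", 3.21),
    metabolite_peak("mI",  3.54), metabolite_peak("ML", 1.30))
  t_pk <- rbind(
    metabolite_peak("ML/Lac", 1.34), metabolite_peak("ML", 1.21),
    metabolite_peak("ML", 1.40),     metabolite_peak("ML", 0.90),
    metabolite_peak("NAA", 2.02),    metabolite_peak("Cr", 3.04),
    metabolite_peak("Cr/GSH", 2.93), metabolite_peak("Cho", 3.21))
  r_pk <- rbind(
    metabolite_peak("Lac/ML", 1.23), metabolite_peak("ML", 0.80),
    metabolite_peak("ML", 0.83),     metabolite_peak("mI/Gly", 3.54),
    metabolite_peak("PUFA", 2.80, linewidth = 0.20),
    metabolite_peak("ML/Lac", 1.34), metabolite_peak("NAA", 2.02),
    metabolite_peak("Cr", 3.04),     metabolite_peak("Cho", 3.21))
  list(
    N = class_signature("N", n_pk, c(1.00, 0.55, 1.05, 0.45, 0.25, 0.10)),
    T = class_signature("T", t_pk, c(1.30, 0.50, 0.45, 0.30, 0.15, 0.25,
                                     0.15, 0.35)),
    R = class_signature("R", r_pk, c(0.75, 0.50, 0.45, 0.80, 0.45, 0.35,
                                     0.20, 0.30, 0.30)))
}

#' Geometric layout of the tumour inside a phantom grid
#'
#' Voxels are addressed by 0-based `(row, col)` with row 0 at the grid top.
#' The tumour is a disc of Euclidean radius `radius` around `center`; with
#' `responding = TRUE` the whole disc is labelled R, otherwise voxels inside
#' the optional responding sub-disc are R and the rest of the disc is T.
#'
#' @param center numeric `(row, col)` of the disc centre (may be fractional).
#' @param radius disc radius in voxels.
#' @param responding logical: whole tumour responding (label R)?
#' @param responding_center,responding_radius optional sub-disc labelled R
#'   inside a T tumour (mixed response).
#' @return An object of class `tumour_layout`.
#' @export
tumour_layout <- function(center = c(4.5, 4.5), radius = 2.5,
                          responding = FALSE,
                          responding_center = NULL, responding_radius = NULL) {
  if (length(center) != 2 || !all(is.finite(center)) ||
      !is.finite(radius) || radius <= 0)
    stopf("tumour_layout: need a finite (row, col) centre and radius > 0",
          class = "mrsinet_config_error")
  if (!is.null(responding_radius) && is.null(responding_center))
    responding_center <- center
  structure(list(center = as.numeric(center), radius = radius,
                 responding = isTRUE(responding),
                 responding_center = responding_center,
                 responding_radius = responding_radius),
            class = "tumour_layout")
}

#' Phantom generator configuration
#'
#' @param axis a [ppm_axis()] (default: 692 points, 0-4.5 ppm).
#' @param signatures named list of the three class signatures.
#' @param noise_sd additive per-point Gaussian noise SD (>= 0).
#' @param baseline_amplitude scale of the smooth broad baseline hump.
#' @param grid_rows,grid_cols grid dimensions (default 10 x 10).
#' @param tumour_layout a [tumour_layout()].
#' @param unknown_rim_width border width (voxels) labelled `unknown`.
#' @param seed default seed used when generator calls omit one.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(axis = ppm_axis(),
                           signatures = default_signatures(),
                           noise_sd = 0.02, baseline_amplitude = 0.05,
                           grid_rows = 10L, grid_cols = 10L,
                           tumour_layout = mrsinet::tumour_layout(),
                           unknown_rim_width = 1L, seed = 1L) {
  stopifnot(inherits(axis, "ppm_axis"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stopf("phantom_config: noise_sd must be >= 0", class = "mrsinet_config_error")
  if (!setequal(names(signatures), c("N", "T", "R")))
    stopf("phantom_config: signatures must be a named list with N, T, R",
          class = "mrsinet_config_error")
  pv <- ppm_values(axis)
  for (sig in signatures)
    if (any(sig$peaks$center < axis$ppm_min | sig$peaks$center > axis$ppm_max))
      stopf("phantom_config: %s-signature peak outside the ppm axis",
            sig$class_label, class = "mrsinet_config_error")
  cfg <- structure(list(axis = axis, signatures = signatures,
                        noise_sd = noise_sd,
                        baseline_amplitude = baseline_amplitude,
                        grid_rows = as.integer(grid_rows),
                        grid_cols = as.integer(grid_cols),
                        tumour_layout = tumour_layout,
                        unknown_rim_width = as.integer(unknown_rim_width),
                        seed = as.integer(seed)),
                   class = "phantom_config")
  check_layout(cfg, tumour_layout)
  cfg
}

check_layout <- function(config, layout) {
  r <- layout$center[1]; c <- layout$center[2]; rad <- layout$radius
  if (r - rad < -0.5 || r + rad > config$grid_rows - 0.5 ||
      c - rad < -0.5 || c + rad > config$grid_cols - 0.5)
    stopf("tumour layout (centre %.1f,%.1f radius %.1f) exceeds the %dx%d grid",
          r, c, rad, config$grid_rows, config$grid_cols,
          class = "mrsinet_config_error")
  invisible(TRUE)
}

peak_profile <- function(ppm, center, linewidth, shape) {
  if (shape == "lorentzian") {
    hw <- linewidth / 2
    hw^2 / ((ppm - center)^2 + hw^2)
  } else {
    exp(-4 * log(2) * (ppm - center)^2 / linewidth^2)
  }
}

baseline_profile <- function(config) {
  ppm <- ppm_values(config$axis)
  mid <- (config$axis$ppm_min + config$axis$ppm_max) / 2
  config$baseline_amplitude * exp(-(ppm - mid)^2 / (2 * 1.5^2))
}

# Deterministic class profile for given amplitudes (defaults to the means).
signature_profile <- function(signature, config, amplitudes = signature$mean_amp) {
  ppm <- ppm_values(config$axis)
  prof <- baseline_profile(config)
  for (i in seq_len(nrow(signature$peaks)))
    prof <- prof + amplitudes[i] *
      peak_profile(ppm, signature$peaks$center[i],
                   signature$peaks$linewidth[i], signature$peaks$shape[i])
  prof
}

#' Zero-noise mean spectrum of a tissue class
#'
#' The closed-form expectation of [generate_spectrum()]: baseline plus the
#' sum of the class signature's peak profiles at their mean amplitudes.
#'
#' @param class_label `"N"`, `"T"` or `"R"`.
#' @param config a [phantom_config()].
#' @return Numeric vector of length `config$axis$n_points`.
#' @export
class_mean_spectrum <- function(class_label, config) {
  sig <- config$signatures[[class_label]]
  if (is.null(sig))
    stopf("unknown class label '%s' (expected N, T or R)", class_label,
          class = "mrsinet_class_error")
  signature_profile(sig, config)
}

#' Generate one synthetic voxel spectrum
#'
#' Draws per-peak amplitudes around the class-signature means (truncated at
#' zero), evaluates baseline + peak profiles on the ppm axis and adds
#' independent zero-mean Gaussian noise of SD `config$noise_sd`.
#'
#' @param class_label `"N"`, `"T"` or `"R"`.
#' @param config a [phantom_config()].
#' @param seed integer seed; the same seed reproduces the spectrum exactly.
#' @return Numeric vector of length `config$axis$n_points`.
#' @examples
#' cfg <- phantom_config(noise_sd = 0)
#' s <- generate_spectrum("N", cfg, seed = 1)
#' ppm_values(cfg$axis)[which.max(s)]   # creatine or NAA position
#' @export
generate_spectrum <- function(class_label, config, seed = config$seed) {
  sig <- config$signatures[[as.character(class_label)]]
  if (is.null(sig))
    stopf("unknown class label '%s' (expected N, T or R)", class_label,
          class = "mrsinet_class_error")
  with_seed(seed, {
    amps <- pmax(0, rnorm(length(sig$mean_amp), sig$mean_amp, sig$sd_amp))
    signature_profile(sig, config, amps) +
      rnorm(config$axis$n_points, 0, config$noise_sd)
  })
}

# Label grid (vector, row-major, 0-based (row, col) with row 0 on top).
# A NULL layout means a tumour-free (all-normal) grid.
layout_labels <- function(config, layout = config$tumour_layout) {
  nr <- config$grid_rows; nc <- config$grid_cols
  rr <- rep(0:(nr - 1), each = nc)   # row-major order
  cc <- rep(0:(nc - 1), times = nr)
  lab <- rep("N", nr * nc)
  if (!is.null(layout)) {
    check_layout(config, layout)
    d <- sqrt((rr - layout$center[1])^2 + (cc - layout$center[2])^2)
    inside <- d <= layout$radius
    lab[inside] <- if (layout$responding) "R" else "T"
    if (!layout$responding && !is.null(layout$responding_radius)) {
      d2 <- sqrt((rr - layout$responding_center[1])^2 +
                 (cc - layout$responding_center[2])^2)
      lab[inside & d2 <= layout$responding_radius] <- "R"
    }
  }
  w <- config$unknown_rim_width
  if (w > 0)
    lab[rr < w | rr >= nr - w | cc < w | cc >= nc - w] <- "unknown"
  lab
}

#' Generate one synthetic MRSI grid
#'
#' Assigns labels from the tumour layout (tumour disc T and/or responding R,
#' unknown border rim, N elsewhere), then draws one spectrum per voxel.
#' Unknown-rim voxels emulate peritumoural tissue: their mean profile is a
#' random blend of the class profiles found among their 8-neighbours (pure N
#' if none), plus noise.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param layout a [tumour_layout()] overriding `config$tumour_layout`;
#'   `NULL` generates a tumour-free (all-normal) grid.
#' @param subject_id,day metadata carried on the grid.
#' @return An object of class `mrsi_grid`: row-major spectra matrix
#'   (`rows*cols` x `n_points`), per-voxel ground-truth `labels`, dimensions,
#'   axis and metadata.
#' @export
generate_grid <- function(config, seed = config$seed,
                          layout = config$tumour_layout,
                          subject_id = "S1", day = NA_integer_) {
  labels <- layout_labels(config, layout)
  nv <- length(labels)
  seeds <- child_seeds(seed, nv + 1L)
  nr <- config$grid_rows; nc <- config$grid_cols
  spectra <- matrix(0, nv, config$axis$n_points)
  lab_mat <- matrix(labels, nr, nc, byrow = TRUE)
  for (v in seq_len(nv)) {
    lab <- labels[v]
    if (lab != "unknown") {
      spectra[v, ] <- generate_spectrum(lab, config, seeds[v])
    } else {
      r <- (v - 1) %/% nc; c <- (v - 1) %% nc
      nb_r <- pmax(0, pmin(nr - 1, r + c(-1, -1, -1, 0, 0, 1, 1, 1)))
      nb_c <- pmax(0, pmin(nc - 1, c + c(-1, 0, 1, -1, 1, -1, 0, 1)))
      nb <- unique(lab_mat[cbind(nb_r + 1, nb_c + 1)])
      nb <- setdiff(nb, "unknown")
      if (length(nb) == 0) nb <- "N"
      spectra[v, ] <- with_seed(seeds[v], {
        w <- runif(length(nb)); w <- w / sum(w)
        prof <- Reduce(`+`, Map(function(cl, wt)
          wt * signature_profile(config$signatures[[cl]], config), nb, w))
        prof + rnorm(config$axis$n_points, 0, config$noise_sd)
      })
    }
  }
  new_mrsi_grid(spectra, labels, nr, nc, config$axis, subject_id, day)
}

new_mrsi_grid <- function(spectra, labels, rows, cols, axis,
                          subject_id = "S1", day = NA_integer_) {
  if (nrow(spectra) != rows * cols || length(labels) != rows * cols)
    stopf("mrsi_grid: need rows*cols spectra and labels (%d x %d, got %d/%d)",
          rows, cols, nrow(spectra), length(labels))
  bad <- setdiff(unique(labels), c("N", "T", "R", "unknown"))
  if (length(bad))
    stopf("mrsi_grid: invalid label token(s) %s; allowed: N, T, R, unknown",
          paste(sQuote(bad), collapse = ", "), class = "mrsinet_format_error")
  structure(list(spectra = spectra, labels = labels,
                 rows = as.integer(rows), cols = as.integer(cols),
                 axis = axis, subject_id = subject_id,
                 day = if (is.na(day)) NA_integer_ else as.integer(day)),
            class = "mrsi_grid")
}

#' @export
print.mrsi_grid <- function(x, ...) {
  cat(sprintf("<mrsi_grid> %dx%d voxels, %d-point spectra, subject %s%s\n",
              x$rows, x$cols, ncol(x$spectra), x$subject_id,
              if (is.na(x$day)) "" else sprintf(" (day %d)", x$day)))
  print(table(labels = x$labels))
  invisible(x)
}

#' Ground-truth labels of a grid as a rows x cols matrix
#' @param grid an `mrsi_grid`.
#' @return Character matrix (row 0 of the grid = first matrix row).
#' @export
label_matrix <- function(grid) {
  matrix(grid$labels, grid$rows, grid$cols, byrow = TRUE)
}

#' Generate a synthetic cohort of subjects
#'
#' Mirrors a preclinical study design: control subjects carry an untreated
#' tumour (labels N/T/unknown), treated subjects a responding tumour (labels
#' N/R/unknown), and longitudinal subjects a series of grids whose tumour
#' transitions from unresponsive (T) through responding (R) to a mixed
#' relapse (R core inside a T ring).
#'
#' @param n_control,n_treated,n_longitudinal subject counts (>= 0).
#' @param timepoints_per_longitudinal grids per longitudinal subject.
#' @param config a [phantom_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `mrsi_cohort`: list of subjects, each with
#'   `id`, `condition` and a list of `mrsi_grid`s.
#' @examples
#' coh <- generate_cohort(2, 2, 1, 3, phantom_config(), seed = 7)
#' length(coh$subjects)
#' @export
generate_cohort <- function(n_control, n_treated, n_longitudinal,
                            timepoints_per_longitudinal,
                            config = phantom_config(), seed = config$seed) {
  counts <- c(n_control, n_treated, n_longitudinal)
  if (any(counts < 0)) stopf("generate_cohort: counts must be >= 0")
  n_sub <- sum(counts)
  seeds <- child_seeds(seed, max(n_sub, 1L))
  subjects <- vector("list", n_sub)
  conds <- rep(c("control", "treated", "longitudinal"), counts)
  base_layout <- config$tumour_layout
  for (i in seq_len(n_sub)) {
    id <- sprintf("S%03d", i)
    cond <- conds[i]
    if (cond == "longitudinal") {
      tp <- timepoints_per_longitudinal
      days <- 10L + 2L * (seq_len(tp) - 1L)
      gseeds <- child_seeds(seeds[i], tp)
      grids <- vector("list", tp)
      for (t in seq_len(tp)) {
        f <- if (tp == 1) 0 else (t - 1) / (tp - 1)
        lay <- if (f < 1 / 3) {
          tumour_layout(base_layout$center, base_layout$radius)
        } else if (f < 2 / 3) {
          tumour_layout(base_layout$center, base_layout$radius,
                        responding = TRUE)
        } else {
          tumour_layout(base_layout$center, base_layout$radius,
                        responding_radius = base_layout$radius / 2)
        }
        grids[[t]] <- generate_grid(config, gseeds[t], lay, id, days[t])
      }
    } else {
      lay <- tumour_layout(base_layout$center, base_layout$radius,
                           responding = (cond == "treated"))
      grids <- list(generate_grid(config, seeds[i], lay, id, NA_integer_))
    }
    subjects[[i]] <- list(id = id, condition = cond, grids = grids)
  }
  structure(list(subjects = subjects, axis = config$axis, config = config),
            class = "mrsi_cohort")
}

#' @export
print.mrsi_cohort <- function(x, ...) {
  conds <- vapply(x$subjects, `[[`, "", "condition")
  ng <- vapply(x$subjects, function(s) length(s$grids), 0L)
  cat(sprintf("<mrsi_cohort> %d subjects (%s), %d grids\n",
              length(x$subjects),
              paste(names(table(conds)), table(conds), sep = ":",
                    collapse = ", "), sum(ng)))
  invisible(x)
}

#' Subject identifiers of a cohort
#' @param cohort an `mrsi_cohort`.
#' @export
subject_ids <- function(cohort) vapply(cohort$subjects, `[[`, "", "id")
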