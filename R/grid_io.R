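# ASCII dialect for MRSI grids, label tables, cohort manifests and
# nosologic-map CSVs.  Everything is row-major (voxel (0,0) first), 0-based
# (row, col) with row 0 at the grid top, and written with 9 significant
# digits so files are diffable and round-trip UL2-scale values exactly
# enough for downstream use.

ALLOWED_LABELS <- c("N", "T", "R", "unknown")
CLASS_COLOURS <- c(N = "blue", T = "red", R = "green")

#' Write an MRSI grid as ASCII spectra plus a label table
#'
#' @param grid an `mrsi_grid`.
#' @param spectra_path output file: one line per voxel (row-major),
#'   whitespace-separated intensities, 9 significant digits.
#' @param labels_path output CSV with columns `row`, `col`, `label`.
#' @return Invisibly, the two paths.
#' @export
write_grid <- function(grid, spectra_path, labels_path) {
  stopifnot(inherits(grid, "mrsi_grid"))
  lines <- apply(grid$spectra, 1, function(s)
    paste(sprintf("%.9g", s), collapse = " "))
  writeLines(lines, spectra_path)
  idx <- expand.grid(col = 0:(grid$cols - 1), row = 0:(grid$rows - 1))
  df <- data.frame(row = idx$row, col = idx$col, label = grid$labels)
  write.csv(df, labels_path, row.names = FALSE, quote = FALSE)
  invisible(c(spectra = spectra_path, labels = labels_path))
}

#' Read an MRSI grid from the ASCII dialect
#'
#' @param spectra_path,labels_path files produced by [write_grid()] (or any
#'   files in the same dialect).
#' @param axis the [ppm_axis()] the spectra are declared on; every voxel
#'   line must have exactly `axis$n_points` values.
#' @param subject_id,day metadata to attach.
#' @return An `mrsi_grid`; round-trips with [write_grid()].
#' @export
read_grid <- function(spectra_path, labels_path, axis = ppm_axis(),
                      subject_id = "S1", day = NA_integer_) {
  if (!file.exists(spectra_path))
    stopf("read_grid: no such spectra file: %s", spectra_path,
          class = "mrsinet_format_error")
  if (!file.exists(labels_path))
    stopf("read_grid: no such label file: %s", labels_path,
          class = "mrsinet_format_error")
  lines <- readLines(spectra_path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  nlen <- lengths(vals)
  if (any(nlen != axis$n_points))
    stopf("read_grid: voxel %d has %d points but the axis declares %d",
          which(nlen != axis$n_points)[1], nlen[nlen != axis$n_points][1],
          axis$n_points, class = "mrsinet_format_error")
  lab <- read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "label") %in% names(lab)))
    stopf("read_grid: label table needs columns row, col, label",
          class = "mrsinet_format_error")
  bad <- setdiff(unique(lab$label), ALLOWED_LABELS)
  if (length(bad))
    stopf("read_grid: unknown label token(s) %s; allowed tokens: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(ALLOWED_LABELS, collapse = ", "),
          class = "mrsinet_format_error")
  rows <- max(lab$row) + 1L; cols <- max(lab$col) + 1L
  if (nrow(lab) != rows * cols || length(lines) != rows * cols)
    stopf("read_grid: expected %d voxels, got %d label rows / %d spectra",
          rows * cols, nrow(lab), length(lines),
          class = "mrsinet_format_error")
  lab <- lab[order(lab$row, lab$col), ]
  new_mrsi_grid(do.call(rbind, vals), lab$label, rows, cols, axis,
                subject_id, day)
}

#' Write a cohort to a directory with a JSON manifest
#'
#' One spectra file and one label table per grid plus `manifest.json`
#' recording subject id, condition, day and relative file paths.
#'
#' @param cohort an `mrsi_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in cohort$subjects) {
    for (g in s$grids) {
      stem <- if (is.na(g$day)) s$id else sprintf("%s_day%03d", s$id, g$day)
      sp <- file.path(dir, paste0(stem, "_spectra.txt"))
      lp <- file.path(dir, paste0(stem, "_labels.csv"))
      write_grid(g, sp, lp)
      e <- list(subject = s$id, condition = s$condition,
                spectra = basename(sp), labels = basename(lp))
      if (!is.na(g$day)) e$day <- g$day
      entries[[length(entries) + 1L]] <- e
    }
  }
  manifest <- list(axis = unclass(cohort$axis), grids = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `manifest.json`.
#' @return An `mrsi_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  axis <- ppm_axis(man$axis$n_points, man$axis$ppm_min, man$axis$ppm_max)
  subs <- list()
  for (e in man$grids) {
    day <- e$day
    if (is.null(day) || !length(day)) day <- NA_integer_
    g <- read_grid(file.path(dir, e$spectra), file.path(dir, e$labels),
                   axis, e$subject, day = day)
    if (is.null(subs[[e$subject]]))
      subs[[e$subject]] <- list(id = e$subject, condition = e$condition,
                                grids = list())
    subs[[e$subject]]$grids <- c(subs[[e$subject]]$grids, list(g))
  }
  structure(list(subjects = unname(subs), axis = axis, config = NULL),
            class = "mrsi_cohort")
}

#' Write a nosologic map as CSV
#'
#' @param map a `nosologic_map` (see [classify_grid()]).
#' @param path output CSV with columns `row`, `col`, `class`, `colour`
#'   (blue/red/green for N/T/R).
#' @return Invisibly, `path`.
#' @export
write_nosologic_map <- function(map, path) {
  stopifnot(inherits(map, "nosologic_map"))
  if (length(map$class) == 0)
    stopf("write_nosologic_map: empty map (0 voxels)",
          class = "mrsinet_format_error")
  idx <- expand.grid(col = 0:(map$cols - 1), row = 0:(map$rows - 1))
  df <- data.frame(row = idx$row, col = idx$col,
                   class = map$class, colour = unname(CLASS_COLOURS[map$class]))
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e)
             stopf("write_nosologic_map: cannot write %s: %s", path,
                   conditionMessage(e)))
  invisible(path)
}

#' Read a nosologic map CSV
#' @param path file written by [write_nosologic_map()].
#' @return A `nosologic_map` (without audit scores).
#' @export
read_nosologic_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$class), names(CLASS_COLOURS))
  if (length(bad))
    stopf("read_nosologic_map: invalid class token(s) %s",
          paste(sQuote(bad), collapse = ", "), class = "mrsinet_format_error")
  rows <- max(df$row) + 1L; cols <- max(df$col) + 1L
  df <- df[order(df$row, df$col), ]
  new_nosologic_map(df$class, rows, cols,
                    p1 = rep(NA_real_, nrow(df)), p2 = rep(NA_real_, nrow(df)))
}
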