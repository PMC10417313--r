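# Dice-score evaluation of nosologic maps against ground truth, and
# method-comparison summaries (per-class averages with normal-approximation
# confidence intervals).

#' Dice similarity of two binary masks
#'
#' `2 * |pred & truth| / (|pred| + |truth|)`, computed at the voxel level.
#' Returns `NA` (not available) when both masks are empty — agreement on an
#' absent class carries no evidence.
#'
#' @param pred_mask,truth_mask logical vectors/matrices of equal shape.
#' @return Dice score in `[0, 1]`, or `NA` for two empty masks.
#' @examples
#' dice(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 2/3
#' @export
dice <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask))
    stopf("dice: mask shapes differ (%d vs %d voxels)",
          length(pred_mask), length(truth_mask))
  p <- as.logical(pred_mask); t_ <- as.logical(truth_mask)
  denom <- sum(p) + sum(t_)
  if (denom == 0) return(NA_real_)
  2 * sum(p & t_) / denom
}

#' Dice evaluation of a nosologic map against grid ground truth
#'
#' Unknown-labelled voxels are excluded from both masks (maps colour them,
#' but they carry no ground truth).  One binary Dice score is computed per
#' class present in the ground truth — control grids typically contribute N
#' and T, treated grids N and R — and the multiclass score is the
#' unweighted mean of those per-class scores.  A class absent from both
#' truth and prediction is excluded rather than scored 1.
#'
#' @param map a `nosologic_map`.
#' @param grid the `mrsi_grid` holding the expert/ground-truth labels.
#' @return An object of class `dice_report`: `per_class` (named vector),
#'   `multiclass`, `n_evaluated`, `n_excluded`.
#' @export
evaluate_map <- function(map, grid) {
  stopifnot(inherits(map, "nosologic_map"), inherits(grid, "mrsi_grid"))
  if (map$rows != grid$rows || map$cols != grid$cols)
    stopf("evaluate_map: map is %dx%d but grid is %dx%d",
          map$rows, map$cols, grid$rows, grid$cols)
  keep <- grid$labels != "unknown"
  if (!any(keep)) stopf("evaluate_map: grid has no labelled voxels")
  truth <- grid$labels[keep]; pred <- map$class[keep]
  classes <- intersect(c("N", "T", "R"), unique(truth))
  per <- vapply(classes, function(cl) dice(pred == cl, truth == cl),
                numeric(1))
  structure(list(per_class = per, multiclass = mean(per, na.rm = TRUE),
                 n_evaluated = sum(keep), n_excluded = sum(!keep)),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report>\n  per class: ",
      paste(sprintf("%s %.3f", names(x$per_class), x$per_class),
            collapse = ", "),
      sprintf("\n  multiclass %.3f (%d voxels evaluated, %d excluded)\n",
              x$multiclass, x$n_evaluated, x$n_excluded))
  invisible(x)
}

#' Compare per-case Dice scores of two mapping methods
#'
#' Takes one table of per-case, per-class Dice scores per method (`NA`
#' where a class is absent from a case) and reports, per class and method,
#' the unweighted mean over the cases where the class is present together
#' with a 95% normal-approximation confidence half-width
#' (`1.96 * sd / sqrt(n)`), flagging the better method per class.
#'
#' @param reports_a,reports_b data frames with a `case` column and one
#'   numeric column per class (e.g. `N`, `T`, `R`), or lists of
#'   `dice_report`s (then `case` is taken from names or position).
#' @param names_ab labels for the two methods.
#' @return An object of class `dice_comparison`: a data frame with class,
#'   per-method mean and CI half-width, and the winner flag.
#' @export
compare_methods <- function(reports_a, reports_b,
                            names_ab = c("method_A", "method_B")) {
  tab <- function(r) {
    if (is.data.frame(r)) return(r)
    cls <- unique(unlist(lapply(r, function(d) names(d$per_class))))
    out <- data.frame(case = if (!is.null(names(r))) names(r) else
      sprintf("case%02d", seq_along(r)))
    for (cl in cls)
      out[[cl]] <- vapply(r, function(d)
        if (cl %in% names(d$per_class)) d$per_class[[cl]] else NA_real_,
        numeric(1))
    out
  }
  a <- tab(reports_a); b <- tab(reports_b)
  if (!identical(a$case, b$case))
    stopf("compare_methods: the two methods cover different case lists")
  classes <- intersect(setdiff(names(a), "case"), setdiff(names(b), "case"))
  rows <- lapply(classes, function(cl) {
    stat <- function(v) {
      v <- v[!is.na(v)]
      c(mean = mean(v), ci = 1.96 * sd(v) / sqrt(length(v)), n = length(v))
    }
    sa <- stat(a[[cl]]); sb <- stat(b[[cl]])
    data.frame(class = cl,
               mean_a = sa["mean"], ci_a = sa["ci"], n_a = sa["n"],
               mean_b = sb["mean"], ci_b = sb["ci"], n_b = sb["n"],
               best = if (isTRUE(all.equal(sa["mean"], sb["mean"]))) "tie"
               else if (sa["mean"] > sb["mean"]) names_ab[1] else names_ab[2],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "methods") <- names_ab
  class(out) <- c("dice_comparison", "data.frame")
  out
}

#' @export
print.dice_comparison <- function(x, ...) {
  m <- attr(x, "methods")
  cat(sprintf("<dice_comparison> %s vs %s (mean +/- 95%% CI half-width)\n",
              m[1], m[2]))
  df <- data.frame(
    class = x$class,
    a = sprintf("%.2f +/- %.2f (n=%d)", x$mean_a, x$ci_a, x$n_a),
    b = sprintf("%.2f +/- %.2f (n=%d)", x$mean_b, x$ci_b, x$n_b),
    best = x$best)
  names(df)[2:3] <- m
  print(df, row.names = FALSE)
  invisible(x)
}
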