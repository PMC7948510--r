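#' Positivity threshold from an isotype-control image
#'
#' The threshold for calling a cell marker-positive is the average of the
#' per-cell mean intensities measured on a single isotype-control image of
#' the same antibody/condition. One control image serves all experimental
#' images of that condition.
#'
#' @param control_records data frame with a `mean_raw` column, as returned
#'   by [per_cell_mean_intensity()] on the control image.
#' @return The control mean intensity (a single number).
#' @export
control_threshold <- function(control_records) {
  if (is.null(control_records$mean_raw) || nrow(control_records) == 0)
    stop("control image yielded no cells; choose a different control image")
  mean(control_records$mean_raw)
}

#' Background-subtract and call positivity for each cell
#'
#' Subtracts the control-image average from each cell's mean intensity; a
#' cell whose mean does not strictly exceed the control average has its
#' corrected expression set to zero. A cell is positive exactly when its
#' corrected expression is non-zero.
#'
#' @param records data frame with `nucleus_id` and `mean_raw` columns.
#' @param control_mean non-negative threshold from [control_threshold()].
#' @return The input data frame with added columns `mean_corrected` and
#'   `positive`.
#' @export
score_cells <- function(records, control_mean) {
  stopifnot(is.numeric(control_mean), length(control_mean) == 1,
            control_mean >= 0)
  records$mean_corrected <- ifelse(records$mean_raw > control_mean,
                                   records$mean_raw - control_mean, 0)
  records$positive <- records$mean_corrected > 0
  records
}

#' Fraction of marker-positive cells in one image
#'
#' @param scored data frame from [score_cells()].
#' @param image_id identifier recorded in the result.
#' @param control_mean the threshold used, recorded for auditability.
#' @return A one-row data frame with `image_id`, `n_cells`, `n_positive`,
#'   `frac_positive`, `control_mean`.
#' @export
fraction_positive <- function(scored, image_id = "image",
                              control_mean = NA_real_) {
  if (is.null(scored$positive) || nrow(scored) == 0)
    stop("no scored cells; cannot compute a fraction")
  data.frame(image_id = image_id,
             n_cells = nrow(scored),
             n_positive = sum(scored$positive),
             frac_positive = mean(scored$positive),
             control_mean = control_mean)
}

#' Quantify a set of experimental images against one control image
#'
#' Full imaging pipeline: segment nuclei in every image, measure per-cell
#' marker intensity over nucleus pixels, derive the positivity threshold
#' from the control image, and score each experimental image's fraction of
#' positive cells.
#'
#' @param fields named list of experimental fields; each element is a list
#'   with `dapi` and `marker` matrices (e.g. a `"nuclei_field"`).
#' @param control one control field of the same structure.
#' @param min_area,split_touching,bit_depth passed to [segment_nuclei()].
#' @return A list with `per_image` (one row per image:
#'   `image_id, n_cells, n_positive, frac_positive, control_mean`),
#'   `per_cell` (row-bound scored cell records with an `image_id` column)
#'   and `control_mean`.
#' @export
#' @examples
#' ctrl <- simulate_control_field(n_nuclei = 30, seed = 1)
#' fld <- simulate_nuclei_field(n_nuclei = 30, frac_positive = 0.5, seed = 2)
#' res <- quantify_images(list(img1 = fld), ctrl)
#' res$per_image
quantify_images <- function(fields, control, min_area = 30,
                            split_touching = FALSE, bit_depth = 16) {
  seg_ctrl <- segment_nuclei(control$dapi, min_area = min_area,
                             split_touching = split_touching,
                             bit_depth = bit_depth)
  if (seg_ctrl$n_nuclei == 0)
    stop("control image yielded no nuclei; choose a different control image")
  ctrl_rec <- per_cell_mean_intensity(control$marker, seg_ctrl)
  ctrl_mean <- control_threshold(ctrl_rec)

  if (is.null(names(fields)))
    names(fields) <- sprintf("image_%02d", seq_along(fields))
  per_cell <- vector("list", length(fields))
  per_image <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    id <- names(fields)[i]
    seg <- segment_nuclei(fields[[i]]$dapi, min_area = min_area,
                          split_touching = split_touching,
                          bit_depth = bit_depth)
    if (seg$n_nuclei == 0)
      stop("no nuclei segmented in image '", id, "'")
    rec <- score_cells(per_cell_mean_intensity(fields[[i]]$marker, seg),
                       ctrl_mean)
    per_cell[[i]] <- cbind(image_id = id, rec)
    per_image[[i]] <- fraction_positive(rec, id, ctrl_mean)
  }
  list(per_image = do.call(rbind, per_image),
       per_cell = do.call(rbind, per_cell),
       control_mean = ctrl_mean)
}

#' Compare fraction-positive between two treatment groups
#'
#' Two-sample two-tailed t test on per-image fractions of positive cells.
#' Welch's unequal-variance form is the default; set `pooled = TRUE` for the
#' classical pooled-variance test.
#'
#' @param group_a,group_b numeric vectors of per-image fractions (at least 2
#'   images each).
#' @param pooled use the pooled-variance t test instead of Welch.
#' @return A list of class `"group_comparison"` with `t_statistic`,
#'   `p_value`, `df`, `mean_a`, `mean_b` and `method`. If both groups are
#'   constant the test is degenerate: equal means give `t = 0, p = 1`,
#'   unequal means `t = +/-Inf, p = 0`, each with a warning.
#' @export
compare_groups <- function(group_a, group_b, pooled = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 images")
  method <- if (pooled) "pooled two-sample t-test" else "Welch two-sample t-test"
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("both groups constant with equal means; degenerate t = 0, p = 1")
      res <- list(t_statistic = 0, p_value = 1, df = NA_real_)
    } else {
      warning("both groups constant with unequal means; degenerate p = 0")
      res <- list(t_statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                  p_value = 0, df = NA_real_)
    }
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = pooled,
                        alternative = "two.sided")
    res <- list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter))
  }
  structure(c(res, list(mean_a = mean(group_a), mean_b = mean(group_b),
                        method = method)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.4g (df = %.3g), p = %.4g\n  group means: %.4g vs %.4g\n",
              x$method, x$t_statistic, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}
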