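#' Shape descriptors of a cell contour
#'
#' Computes the three morphodynamic descriptors used to quantify migrating
#' and rounding cells: perimeter (µm, polygonal arc length), area (µm²,
#' shoelace), sphericity (%, realized in 2D as circularity,
#' \code{100 * 4 * pi * area / perimeter^2}; 100 for a perfect circle) and
#' elongation ratio (first/second diameter of the second-central-moment
#' equivalent ellipse; minimum 1, attained for a round object).
#'
#' Sphericity and elongation are invariant to rigid motion and scale;
#' perimeter and area scale as s and s². By the isoperimetric inequality
#' \code{perimeter^2 >= 4 * pi * area} for every simple polygon, so
#' sphericity never exceeds 100.
#'
#' @param contour a \code{cell_contour} (or a 2-column vertex matrix, µm).
#' @return data frame with one row: frame, perimeter_um, area_um2,
#'   sphericity_pct, elongation_ratio.
#' @export
shape_descriptors <- function(contour) {
  v <- if (inherits(contour, "cell_contour")) contour$vertices else contour
  frame <- if (inherits(contour, "cell_contour")) contour$frame else NA_integer_
  if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 8)
    stop("contour must have >= 8 vertices")
  v <- ensure_ccw(v)
  a <- polygon_area(v)
  if (a <= 0) stop("degenerate polygon: non-positive area")
  p <- polygon_perimeter(v)
  m <- polygon_moments(v)
  ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps)
  elong <- sqrt(ev[1] / ev[2])
  data.frame(frame = frame,
             perimeter_um = p,
             area_um2 = a,
             sphericity_pct = min(100, 100 * 4 * pi * a / p^2),
             elongation_ratio = max(1, elong))
}

#' Shape time series with mitotic-rounding detection
#'
#' Per-frame descriptors for a contour series, plus detection of the
#' rounding event: during mitosis a migrating cell's minimal perimeter,
#' minimal elongation ratio and maximal sphericity are reached together.
#' The detected rounding frame is the frame of maximal sphericity,
#' reported only if (a) sphericity there reaches
#' \code{rounding_threshold} and (b) elongation is jointly minimal within
#' a window of \code{window} frames around it.
#'
#' @param series a \code{contour_series} from \code{\link{segment_series}},
#'   or a list of \code{cell_contour} objects (e.g. simulation truth).
#' @param rounding_threshold minimum sphericity (%) to call a rounding
#'   event (default 95).
#' @param window sliding-window width (frames) for the joint check.
#' @return list of class \code{shape_series}: \code{records} (per-frame
#'   data frame), \code{rounding_frame} (0-based index or NA),
#'   \code{summary} (min/max/mean of each descriptor).
#' @export
shape_series_stats <- function(series, rounding_threshold = 95, window = 5L) {
  contours <- if (inherits(series, "contour_series")) series$contours else series
  if (!length(contours)) stop("no usable contours: all frames flagged")
  rec <- do.call(rbind, lapply(contours, shape_descriptors))
  rec <- rec[order(rec$frame), , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rec) < 3L) stop("need >= 3 usable frames for series statistics")

  i_best <- which.max(rec$sphericity_pct)
  half <- floor(window / 2)
  win <- max(1L, i_best - half):min(nrow(rec), i_best + half)
  rounding <- NA_integer_
  if (rec$sphericity_pct[i_best] >= rounding_threshold &&
      which.min(rec$elongation_ratio[win]) == match(i_best, win))
    rounding <- rec$frame[i_best]

  summ <- do.call(rbind, lapply(
    c("perimeter_um", "area_um2", "sphericity_pct", "elongation_ratio"),
    function(col) data.frame(descriptor = col, min = min(rec[[col]]),
                             max = max(rec[[col]]), mean = mean(rec[[col]]))))
  structure(list(records = rec, rounding_frame = rounding, summary = summ),
            class = "shape_series")
}

#' @export
print.shape_series <- function(x, ...) {
  cat("shape_series:", nrow(x$records), "frames; rounding frame:",
      ifelse(is.na(x$rounding_frame), "none", x$rounding_frame), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
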