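#' Angle between a protrusion and the movement direction
#'
#' The unsigned angle between the unit vector of instantaneous cell
#' movement and the unit vector pointing from the cell centroid to the
#' protrusion tip: 0° for a protrusion pointing exactly toward the
#' direction of movement (cell front), 180° for one pointing exactly
#' opposite (cell back).
#'
#' @param direction unit 2-vector of instantaneous movement.
#' @param centroid cell centroid (x, y) in µm.
#' @param tip protrusion tip (x, y) in µm; must differ from the centroid.
#' @return angle in degrees, in [0, 180].
#' @export
protrusion_angle <- function(direction, centroid, tip) {
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-6) stop("direction must be a unit vector")
  v <- tip - centroid
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("undefined angle: tip coincides with centroid")
  deg(acos(clamp(sum(direction * v) / (nd * nv), -1, 1)))
}

empty_histogram <- function(edges, condition) {
  nb <- length(edges) - 1L
  structure(list(condition = condition, bin_lo = edges[-length(edges)],
                 bin_hi = edges[-1], frequency = rep(NA_real_, nb),
                 freq_per_frame = rep(NA_real_, nb),
                 count = rep(0L, nb), n_samples = 0L,
                 n_frames_condition = 0L, flag = "empty_condition"),
            class = "angle_histogram")
}

#' Speed-conditioned protrusion-angle histograms
#'
#' Builds one angle sample per (protrusion tip, frame) — the angle between
#' the instantaneous movement direction and the centroid-to-tip vector —
#' classes each sample by the cell's per-frame speed stratum, and
#' aggregates normalized angular histograms over [0°, 180°] for the
#' conditions \code{all}, \code{low} (speed < 25th percentile) and
#' \code{high} (speed > 75th percentile). Bins are half-open [a, b) with
#' the last bin closed at 180°. Samples at frames without a valid velocity
#' are dropped and counted.
#'
#' Two normalizations are emitted: \code{frequency} divides each bin count
#' by the number of samples in the condition (sums to 1), and
#' \code{freq_per_frame} divides by the number of frames observed in the
#' condition (the rose-plot convention when several protrusions coexist in
#' a frame). An empty condition yields an explicitly flagged empty
#' histogram, never a fabricated distribution.
#'
#' @param cell_track \code{point_tracks} of the cell centroid (one track).
#' @param tip_tracks \code{point_tracks} of protrusion tips.
#' @param vel \code{velocity_series} of the cell track.
#' @param thresholds \code{speed_thresholds} computed from \code{vel}.
#' @param bin_width_deg bin width in degrees (default 20, i.e. 9 bins).
#' @return list of class \code{angle_analysis}: \code{samples} (data frame
#'   frame, protrusion_id, angle_deg, speed_class), \code{histograms}
#'   (named list all/low/high of \code{angle_histogram}),
#'   \code{n_dropped_invalid}.
#' @export
angle_histograms <- function(cell_track, tip_tracks, vel, thresholds,
                             bin_width_deg = 20) {
  stopifnot(bin_width_deg > 0, bin_width_deg <= 180)
  edges <- unique(c(seq(0, 180, by = bin_width_deg), 180))
  cls <- thresholds$classes
  samples <- list(); dropped <- 0L
  for (i in seq_len(nrow(tip_tracks))) {
    f <- tip_tracks$frame[i]
    iv <- match(f, vel$frame)
    if (is.na(iv) || !vel$valid[iv]) { dropped <- dropped + 1L; next }
    ic <- match(f, cell_track$frame)
    if (is.na(ic)) { dropped <- dropped + 1L; next }
    ang <- protrusion_angle(c(vel$dir_x[iv], vel$dir_y[iv]),
                            c(cell_track$x_um[ic], cell_track$y_um[ic]),
                            c(tip_tracks$x_um[i], tip_tracks$y_um[i]))
    samples[[length(samples) + 1L]] <- data.frame(
      frame = f, protrusion_id = tip_tracks$track_id[i], angle_deg = ang,
      speed_class = cls$class[match(f, cls$frame)])
  }
  samples <- if (length(samples)) do.call(rbind, samples) else
    data.frame(frame = integer(0), protrusion_id = character(0),
               angle_deg = numeric(0), speed_class = character(0))

  hist_for <- function(cond) {
    sub <- if (cond == "all") samples else
      samples[samples$speed_class == cond, , drop = FALSE]
    nfr_cond <- if (cond == "all") length(unique(cls$frame)) else
      sum(cls$class == cond)
    if (!nrow(sub)) return(empty_histogram(edges, cond))
    bin <- findInterval(sub$angle_deg, edges, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nbins = length(edges) - 1L)
    structure(list(condition = cond, bin_lo = edges[-length(edges)],
                   bin_hi = edges[-1],
                   frequency = cnt / sum(cnt),
                   freq_per_frame = if (nfr_cond > 0) cnt / nfr_cond else
                     rep(NA_real_, length(cnt)),
                   count = cnt, n_samples = nrow(sub),
                   n_frames_condition = nfr_cond, flag = "ok"),
              class = "angle_histogram")
  }
  structure(list(samples = samples,
                 histograms = list(all = hist_for("all"),
                                   low = hist_for("low"),
                                   high = hist_for("high")),
                 n_dropped_invalid = dropped,
                 bin_width_deg = bin_width_deg),
            class = "angle_analysis")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("angle_histogram [%s]: %d samples over %d frames%s\n",
              x$condition, x$n_samples, x$n_frames_condition,
              if (x$flag != "ok") paste0(" (", x$flag, ")") else ""))
  if (x$n_samples > 0)
    print(data.frame(bin = sprintf("[%g,%g%s", x$bin_lo, x$bin_hi,
                                   ifelse(x$bin_hi >= 180, "]", ")")),
                     frequency = round(x$frequency, 4),
                     count = x$count), row.names = FALSE)
  invisible(x)
}

#' Convert an angle analysis to a long histogram data frame
#' @param analysis an \code{angle_analysis}.
#' @return data frame: condition, bin_lo, bin_hi, frequency,
#'   freq_per_frame, count, n_samples, n_frames_condition, flag.
#' @export
angle_histogram_df <- function(analysis) {
  do.call(rbind, lapply(analysis$histograms, function(h)
    data.frame(condition = h$condition, bin_lo = h$bin_lo, bin_hi = h$bin_hi,
               frequency = h$frequency, freq_per_frame = h$freq_per_frame,
               count = h$count, n_samples = h$n_samples,
               n_frames_condition = h$n_frames_condition, flag = h$flag)))
}

#' Polar (rose) plot of an angle histogram
#'
#' Mirrors the unsigned [0°, 180°] bins for display, radius = normalized
#' frequency, 0° to the right (direction of movement).
#'
#' @param hist an \code{angle_histogram}.
#' @param main plot title.
#' @export
plot_angle_histogram <- function(hist, main = hist$condition) {
  if (hist$n_samples == 0) {
    graphics::plot.new(); graphics::title(main = paste(main, "(empty)"))
    return(invisible(NULL))
  }
  rmax <- max(hist$frequency)
  graphics::plot(NA, xlim = c(-rmax, rmax) * 1.1, ylim = c(-rmax, rmax) * 1.1,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_along(hist$frequency)) {
    for (sgn in c(1, -1)) {
      th <- seq(rad(hist$bin_lo[i]), rad(hist$bin_hi[i]), length.out = 20) * sgn
      graphics::polygon(c(0, hist$frequency[i] * cos(th)),
                        c(0, hist$frequency[i] * sin(th)),
                        col = grDevices::adjustcolor("steelblue", 0.6))
    }
  }
  graphics::symbols(0, 0, circles = rmax, inches = FALSE, add = TRUE, fg = "grey")
  graphics::text(rmax * 1.08, 0, "0°"); graphics::text(-rmax * 1.08, 0, "180°")
  invisible(NULL)
}
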