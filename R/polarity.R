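# line/segment intersections of the ray centroid + t * d with polygon edges
axis_intersections <- function(vertices, centroid, direction) {
  w <- close_ring(vertices)
  a <- w[-nrow(w), , drop = FALSE]; b <- w[-1, , drop = FALSE]
  ts <- numeric(0)
  d <- direction
  for (i in seq_len(nrow(a))) {
    e <- b[i, ] - a[i, ]
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a[i, ] - centroid
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    u <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (u >= 0 && u <= 1) ts <- c(ts, t)
  }
  ts
}

#' Axial fluorescence profile of one frame (front to back line scan)
#'
#' Samples the image along the cell axis — the contour-clipped line
#' through the cell centroid along the instantaneous movement direction —
#' oriented front (s = 0) to back (s = 1), averaging over
#' \code{line_width_px} perpendicular offsets at each of
#' \code{n_positions} equally spaced axial positions (bilinear
#' interpolation). With \code{axis = "shape"} the equivalent-ellipse major
#' axis (oriented by the motion sign) replaces the movement direction, for
#' sensitivity analysis. For a z-stack the three central z planes are
#' max-projected first.
#'
#' @param img single-channel 2D frame (matrix), or an
#'   \code{\link{image_stack}} with \code{frame}/\code{channel} given.
#' @param contour a \code{cell_contour} (vertices in µm).
#' @param direction unit 2-vector of instantaneous movement at this frame.
#' @param pixel_size_um calibration; taken from the stack if one is given.
#' @param line_width_px perpendicular averaging width (default 3).
#' @param n_positions axial sample count (default 50).
#' @param frame,channel used when \code{img} is an \code{image_stack}.
#' @param axis \code{"movement"} (default) or \code{"shape"}.
#' @return numeric vector of length \code{n_positions} (intensities at
#'   s = 0..1), or \code{NULL} if the frame must be skipped (invalid
#'   direction or axis shorter than 4 px).
#' @export
axial_profile <- function(img, contour, direction, pixel_size_um = NULL,
                          line_width_px = 3, n_positions = 50,
                          frame = NULL, channel = "polarity",
                          axis = c("movement", "shape")) {
  axis <- match.arg(axis)
  if (inherits(img, "image_stack")) {
    pixel_size_um <- img$pixel_size_um
    img <- get_frame(img, frame, channel, project_z = TRUE)
  }
  if (is.null(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um required")
  if (any(!is.finite(direction)) || abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    return(NULL)
  v <- contour$vertices
  ctr <- polygon_centroid(v)
  d <- direction
  if (axis == "shape") {
    m <- polygon_moments(v)
    e <- eigen(m$cov, symmetric = TRUE)
    major <- e$vectors[, 1]
    if (sum(major * direction) < 0) major <- -major
    d <- major / sqrt(sum(major^2))
  }
  ts <- axis_intersections(v, ctr, d)
  tf <- suppressWarnings(max(ts[ts > 0])); tb <- suppressWarnings(min(ts[ts < 0]))
  if (!is.finite(tf) || !is.finite(tb)) return(NULL)
  front <- ctr + tf * d; back <- ctr + tb * d
  if (sqrt(sum((front - back)^2)) / pixel_size_um < 4) return(NULL)
  s <- seq(0, 1, length.out = n_positions)
  px <- cbind(front[1] + s * (back[1] - front[1]),
              front[2] + s * (back[2] - front[2])) / pixel_size_um
  perp <- c(-d[2], d[1])
  offs <- (seq_len(line_width_px) - (line_width_px + 1) / 2)  # px units
  prof <- numeric(n_positions)
  for (o in offs)
    prof <- prof + bilinear_sample(img, px[, 1] + o * perp[1],
                                   px[, 2] + o * perp[2])
  prof / length(offs)
}

#' Per-frame axial profiles over a segmented movie
#'
#' Runs \code{\link{axial_profile}} at every frame that has both a contour
#' and a valid velocity sample.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param contours a \code{contour_series} or list of \code{cell_contour}.
#' @param vel a \code{velocity_series} for the same cell.
#' @param channel channel to profile (default \code{"polarity"}).
#' @param line_width_px,n_positions,axis see \code{\link{axial_profile}}.
#' @return list: \code{profiles} (frames x positions matrix, rownames =
#'   frame), \code{n_skipped}.
#' @export
polarity_profiles <- function(stack, contours, vel, channel = "polarity",
                              line_width_px = 3, n_positions = 50,
                              axis = "movement") {
  cts <- if (inherits(contours, "contour_series")) contours$contours else contours
  rows <- list(); skipped <- 0L
  for (ct in cts) {
    f <- ct$frame
    iv <- match(f, vel$frame)
    if (is.na(iv) || !vel$valid[iv]) { skipped <- skipped + 1L; next }
    p <- axial_profile(stack, ct, c(vel$dir_x[iv], vel$dir_y[iv]),
                       line_width_px = line_width_px,
                       n_positions = n_positions, frame = f,
                       channel = channel, axis = axis)
    if (is.null(p)) { skipped <- skipped + 1L; next }
    rows[[as.character(f)]] <- p
  }
  if (!length(rows)) stop("no frame produced a valid axial profile")
  list(profiles = do.call(rbind, rows), n_skipped = skipped)
}

#' Average axial profile and rear-enrichment index
#'
#' Position-wise mean and SD of per-frame front-to-back profiles (each
#' already normalized to s in [0, 1]), plus the rear-enrichment index:
#' mean intensity over the back third (s in [2/3, 1]) divided by the mean
#' over the front third (s in [0, 1/3]). An index > 1 indicates rear
#' polarization of the marker. A mean-normalized variant (each per-frame
#' profile divided by its own mean before averaging) is also returned.
#'
#' @param profiles frames-by-positions matrix (>= 3 rows), e.g.
#'   \code{polarity_profiles(...)$profiles}.
#' @return list of class \code{rear_enrichment}: \code{profile} (data
#'   frame s, mean, sd, mean_norm, sd_norm, n), \code{index},
#'   \code{index_norm}, \code{n_frames}.
#' @export
rear_enrichment <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop("rear enrichment needs >= 3 per-frame profiles")
  npos <- ncol(profiles)
  s <- seq(0, 1, length.out = npos)
  pn <- profiles / pmax(rowMeans(profiles), 1e-12)
  prof <- data.frame(s = s,
                     mean = colMeans(profiles),
                     sd = apply(profiles, 2, stats::sd),
                     mean_norm = colMeans(pn),
                     sd_norm = apply(pn, 2, stats::sd),
                     n = nrow(profiles))
  front <- s <= 1 / 3; back <- s >= 2 / 3
  idx <- mean(prof$mean[back]) / mean(prof$mean[front])
  idxn <- mean(prof$mean_norm[back]) / mean(prof$mean_norm[front])
  structure(list(profile = prof, index = idx, index_norm = idxn,
                 n_frames = nrow(profiles)),
            class = "rear_enrichment")
}

#' @export
print.rear_enrichment <- function(x, ...) {
  cat(sprintf("rear enrichment index: %.3f (mean-normalized %.3f) over %d frames\n",
              x$index, x$index_norm, x$n_frames))
  invisible(x)
}

#' Plot the averaged axial profile
#' @param x a \code{rear_enrichment}.
#' @param ... passed to \code{plot}.
#' @export
plot.rear_enrichment <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$s, p$mean, type = "l", lwd = 2,
                 xlab = "normalized axial position (0 = front, 1 = back)",
                 ylab = "mean intensity (a.u.)", ...)
  graphics::polygon(c(p$s, rev(p$s)), c(p$mean - p$sd, rev(p$mean + p$sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(p$s, p$mean, lwd = 2)
  invisible(x)
}
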