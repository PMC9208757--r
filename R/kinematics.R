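#' Instantaneous velocities of a point track
#'
#' Finite differences over consecutive frames: for each pair (t, t+1),
#' speed = |displacement| / interval (µm/min) and direction = the unit
#' displacement vector, assigned to the interval-start frame. Samples with
#' displacement below \code{min_displacement_um} are kept but flagged
#' invalid (direction undefined at the tracking resolution). Frame gaps
#' split the track into subsequences; no velocity spans a gap. Raw
#' consecutive displacements are used, mirroring per-frame manual
#' tracking; an optional centred moving-average window smooths positions
#' first (off by default).
#'
#' @param track a \code{point_tracks} data frame holding one track (or the
#'   track to use selected via \code{track_id}).
#' @param interval_min frame interval in minutes.
#' @param min_displacement_um validity threshold (default 0.03 µm, ~0.1 px
#'   at 0.3 µm/px).
#' @param track_id which track to use when several are present.
#' @param smooth_window odd window length for optional position smoothing
#'   (1 = none).
#' @return data frame of class \code{velocity_series}: frame (interval
#'   start), dx_um, dy_um, dir_x, dir_y, speed_um_min, valid.
#' @export
velocities <- function(track, interval_min, min_displacement_um = 0.03,
                       track_id = NULL, smooth_window = 1L) {
  if (!is.null(track_id)) track <- track[track$track_id == track_id, ]
  if (length(unique(track$track_id)) > 1)
    stop("multiple tracks present; select one with track_id")
  if (nrow(track) < 2) stop("velocity needs >= 2 track samples")
  if (interval_min <= 0) stop("interval_min must be > 0")
  track <- track[order(track$frame), ]
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    pad <- floor(smooth_window / 2)
    sm <- function(x) {
      xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
      as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1):(pad + length(x))]
    }
    track$x_um <- sm(track$x_um); track$y_um <- sm(track$y_um)
  }
  df <- diff(track$frame)
  consec <- df == 1L
  i <- which(consec)
  if (!length(i)) stop("no consecutive-frame pairs in track")
  dx <- track$x_um[i + 1] - track$x_um[i]
  dy <- track$y_um[i + 1] - track$y_um[i]
  disp <- sqrt(dx^2 + dy^2)
  speed <- disp / interval_min
  valid <- disp >= min_displacement_um
  out <- data.frame(frame = track$frame[i], dx_um = dx, dy_um = dy,
                    dir_x = ifelse(valid, dx / disp, NA_real_),
                    dir_y = ifelse(valid, dy / disp, NA_real_),
                    speed_um_min = speed, valid = valid)
  structure(out, interval_min = interval_min,
            class = c("velocity_series", "data.frame"))
}

#' Per-cell speed percentile stratification
#'
#' Computes the 25th and 75th percentiles of the valid instantaneous
#' speeds (linear interpolation between order statistics) and classes
#' every valid sample: \code{low} if speed < p25, \code{high} if
#' speed > p75, \code{mid} otherwise. These per-cell thresholds define the
#' speed conditions of the protrusion-angle histograms.
#'
#' @param vel a \code{velocity_series}.
#' @param q_low,q_high percentile cutoffs (defaults 25 and 75).
#' @return list of class \code{speed_thresholds}: p25_um_min, p75_um_min,
#'   and \code{classes} (data frame frame, speed_um_min, class).
#' @export
speed_thresholds <- function(vel, q_low = 25, q_high = 75) {
  v <- vel$speed_um_min[vel$valid]
  if (length(v) < 4)
    stop("speed stratification needs >= 4 valid velocity samples")
  q <- stats::quantile(v, c(q_low, q_high) / 100, names = FALSE, type = 7)
  cls <- ifelse(v < q[1], "low", ifelse(v > q[2], "high", "mid"))
  structure(list(p25_um_min = q[1], p75_um_min = q[2],
                 q_low = q_low, q_high = q_high,
                 classes = data.frame(frame = vel$frame[vel$valid],
                                      speed_um_min = v, class = cls)),
            class = "speed_thresholds")
}

#' @export
print.speed_thresholds <- function(x, ...) {
  cat(sprintf("speed thresholds: p%g = %.3f, p%g = %.3f um/min (%d samples: %s)\n",
              x$q_low, x$p25_um_min, x$q_high, x$p75_um_min,
              nrow(x$classes),
              paste(names(table(x$classes$class)), table(x$classes$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# signed distance of a point to a layer: positive toward basal
layer_signed_distance <- function(x, y, layer_y = NULL, layer_poly = NULL,
                                  basal_sign = 1) {
  if (!is.null(layer_y)) return(basal_sign * (y - layer_y))
  # polyline: distance sign from interpolated y at the point's x
  yi <- stats::approx(layer_poly[, 1], layer_poly[, 2], xout = x, rule = 2)$y
  a <- layer_poly[-nrow(layer_poly), , drop = FALSE]
  b <- layer_poly[-1, , drop = FALSE]
  d <- Inf
  for (i in seq_len(nrow(a))) {
    ab <- b[i, ] - a[i, ]
    t <- clamp(sum((c(x, y) - a[i, ]) * ab) / max(sum(ab^2), 1e-12), 0, 1)
    d <- min(d, sqrt(sum((c(x, y) - a[i, ] - t * ab)^2)))
  }
  basal_sign * sign(y - yi) * d
}

#' Apico-basal depth of a track relative to a tissue layer
#'
#' Signed perpendicular distance (µm) of each track position from a named
#' layer (e.g. the OPL), positive toward basal by the geometry's sign
#' convention. Layers may be horizontal lines (a \code{tissue_geometry}
#' table) or per-frame polylines (data frame frame, x_um, y_um). Frames
#' where the layer is undefined are filled from the nearest frame up to
#' \code{max_gap} frames away, else dropped with a warning.
#'
#' @param track a \code{point_tracks} data frame (one track).
#' @param geometry a \code{tissue_geometry} or polyline data frame.
#' @param layer layer name (default \code{"OPL"}).
#' @param max_gap nearest-frame fill tolerance (frames).
#' @return data frame of class \code{depth_series} (frame, depth_um) with
#'   attributes \code{final_depth_um} and \code{max_basal_depth_um}.
#' @export
depth_relative_to_layer <- function(track, geometry, layer = "OPL",
                                    max_gap = 2L) {
  is_line <- inherits(geometry, "tissue_geometry") ||
    ("layer" %in% names(geometry) && "y_um" %in% names(geometry) &&
       !("x_um" %in% names(geometry)))
  basal_sign <- attr(geometry, "basal_sign")
  if (is.null(basal_sign)) basal_sign <- 1
  if (is_line) {
    g <- geometry[geometry$layer == layer, c("frame", "y_um")]
  } else {
    g <- geometry
  }
  if (!nrow(g)) stop("layer ", layer, " absent from geometry")
  gframes <- sort(unique(g$frame))
  depth <- numeric(0); frames <- integer(0); dropped <- 0L
  for (i in seq_len(nrow(track))) {
    f <- track$frame[i]
    j <- gframes[which.min(abs(gframes - f))]
    if (abs(j - f) > max_gap) { dropped <- dropped + 1L; next }
    if (is_line) {
      d <- layer_signed_distance(track$x_um[i], track$y_um[i],
                                 layer_y = g$y_um[g$frame == j][1],
                                 basal_sign = basal_sign)
    } else {
      poly <- as.matrix(g[g$frame == j, c("x_um", "y_um")])
      d <- layer_signed_distance(track$x_um[i], track$y_um[i],
                                 layer_poly = poly, basal_sign = basal_sign)
    }
    frames <- c(frames, f); depth <- c(depth, d)
  }
  if (dropped) warning(dropped, " track frame(s) dropped: layer undefined ",
                       "within max_gap")
  if (!length(frames)) stop("no track frame has a defined layer position")
  structure(data.frame(frame = frames, depth_um = depth),
            layer = layer,
            final_depth_um = depth[length(depth)],
            max_basal_depth_um = max(depth),
            class = c("depth_series", "data.frame"))
}

#' Centrosome offset from the cell centre
#'
#' Euclidean distance (µm) between the cell-centroid track and the
#' centrosome track at shared frames, plus a front/back label of the
#' centrosome relative to the instantaneous movement direction (sign of
#' the projection of the centre-to-centrosome vector on the direction).
#' The label is \code{"undefined"} where the two positions coincide or no
#' valid direction exists.
#'
#' @param cell_track,centrosome_track \code{point_tracks} data frames.
#' @param vel optional \code{velocity_series} of the cell track (for the
#'   front/back label).
#' @return data frame: frame, distance_um, side.
#' @export
centrosome_offset <- function(cell_track, centrosome_track, vel = NULL) {
  shared <- intersect(cell_track$frame, centrosome_track$frame)
  if (!length(shared)) stop("tracks share no frames")
  shared <- sort(shared)
  ic <- match(shared, cell_track$frame)
  io <- match(shared, centrosome_track$frame)
  dx <- centrosome_track$x_um[io] - cell_track$x_um[ic]
  dy <- centrosome_track$y_um[io] - cell_track$y_um[ic]
  dist <- sqrt(dx^2 + dy^2)
  side <- rep("undefined", length(shared))
  if (!is.null(vel)) {
    iv <- match(shared, vel$frame)
    ok <- !is.na(iv) & dist > 1e-9
    ok[ok] <- vel$valid[iv[ok]]
    proj <- dx * vel$dir_x[iv] + dy * vel$dir_y[iv]
    side[ok] <- ifelse(proj[ok] >= 0, "front", "back")
  }
  data.frame(frame = shared, distance_um = dist, side = side)
}

#' Trajectory summary of a track
#'
#' @param track a \code{point_tracks} data frame (one track).
#' @param interval_min frame interval (minutes).
#' @return one-row data frame: n_frames, total_path_um, net_displacement_um,
#'   mean_speed_um_min, duration_min.
#' @export
track_summary <- function(track, interval_min) {
  track <- track[order(track$frame), ]
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  dur <- (track$frame[nrow(track)] - track$frame[1]) * interval_min
  data.frame(n_frames = nrow(track),
             total_path_um = sum(d),
             net_displacement_um = sqrt(sum((track[nrow(track), c("x_um", "y_um")] -
                                               track[1, c("x_um", "y_um")])^2)),
             mean_speed_um_min = if (dur > 0) sum(d) / dur else 0,
             duration_min = dur)
}
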