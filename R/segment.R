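#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing SD in px (regularizes the
#'   boundary; the only smoothing knob — descriptors later measure the
#'   polygon as segmented).
#' @param min_contrast minimum relative foreground/background mean
#'   separation \code{(mu_fg - mu_bg) / mu_fg}; below it the seed is
#'   declared background (\code{low_contrast}).
#' @param max_iter threshold re-estimation iterations.
#' @param vertex_spacing_px target boundary vertex spacing (~1 vertex per
#'   2 px of perimeter stabilizes perimeter estimates across cell sizes).
#' @param merge_area_factor area-jump factor over the reference area above
#'   which a contour is flagged \code{merged_with_neighbor}.
#' @param max_gap number of consecutive failed frames tolerated during
#'   series propagation before the series is declared \code{lost}.
#' @param min_frames minimum usable frames for a series to be accepted.
#' @return list of class \code{segment_params}.
#' @export
segment_params <- function(smooth_sigma = 1, min_contrast = 0.25,
                           max_iter = 8L, vertex_spacing_px = 2,
                           merge_area_factor = 1.35, max_gap = 3L,
                           min_frames = 3L) {
  structure(list(smooth_sigma = smooth_sigma, min_contrast = min_contrast,
                 max_iter = max_iter, vertex_spacing_px = vertex_spacing_px,
                 merge_area_factor = merge_area_factor,
                 max_gap = as.integer(max_gap),
                 min_frames = as.integer(min_frames)),
            class = "segment_params")
}

# flood fill (4-connectivity) on a logical matrix from a seed pixel
flood_fill <- function(mask, seed_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  if (!mask[seed_rc[1], seed_rc[2]]) return(comp)
  idx <- (seed_rc[2] - 1L) * nr + seed_rc[1]
  comp[idx] <- TRUE
  frontier <- idx
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    cands <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
               frontier[frontier > nr] - nr,
               frontier[frontier <= (nc - 1L) * nr] + nr)
    cands <- unique(cands)
    cands <- cands[mask[cands] & !comp[cands]]
    comp[cands] <- TRUE
    frontier <- cands
  }
  comp
}

# Moore boundary tracing (8-connectivity) of a component; returns ordered
# boundary pixel (row, col) positions, clockwise in image coordinates.
trace_boundary <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && comp[r, c]
  start <- which(comp, arr.ind = TRUE)
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]  # leftmost, then top
  # neighbourhood in clockwise order starting west
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  path <- matrix(0L, 0, 2)
  cur <- start; back <- 1L  # came from west
  repeat {
    path <- rbind(path, cur)
    found <- FALSE
    for (k in 0:7) {
      j <- ((back - 1L + k) %% 8L) + 1L
      r <- cur[1] + dr[j]; c <- cur[2] + dc[j]
      if (inside(r, c)) {
        # resume the clockwise scan just past the backtrack direction
        back <- ((j + 5L) %% 8L) + 1L
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && nrow(path) > 2) break
    if (nrow(path) > 4L * (nr + nc)) break  # safety
  }
  unname(path)
}

# Sub-pixel boundary: move each traced boundary pixel along its local
# outward normal to the point where the smoothed image crosses `level`.
refine_boundary <- function(img_s, bpts_rc, level) {
  n <- nrow(bpts_rc)
  if (n < 3) return(cbind(bpts_rc[, 2] - 0.5, bpts_rc[, 1] - 0.5))
  x <- bpts_rc[, 2] - 0.5; y <- bpts_rc[, 1] - 0.5
  k <- max(1L, min(3L, floor((n - 1) / 2)))
  nxt <- c((k + 1):n, 1:k); prv <- c((n - k + 1):n, 1:(n - k))
  tx <- x[nxt] - x[prv]; ty <- y[nxt] - y[prv]
  tl <- pmax(sqrt(tx^2 + ty^2), 1e-9)
  nx_ <- -ty / tl; ny_ <- tx / tl
  # orient each normal outward (down the intensity gradient)
  f_plus <- bilinear_sample(img_s, x + nx_, y + ny_)
  f_minus <- bilinear_sample(img_s, x - nx_, y - ny_)
  flip <- f_plus > f_minus
  nx_[flip] <- -nx_[flip]; ny_[flip] <- -ny_[flip]
  steps <- seq(-1.5, 1.5, by = 0.25)
  prof <- sapply(steps, function(s)
    bilinear_sample(img_s, x + s * nx_, y + s * ny_))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  out_x <- x; out_y <- y
  for (i in seq_len(n)) {
    p <- prof[i, ]
    cross <- which(p[-length(p)] >= level & p[-1] < level)
    if (length(cross)) {
      j <- cross[which.min(abs(steps[cross] + 0.125))]  # nearest to centre
      f <- (p[j] - level) / max(p[j] - p[j + 1], 1e-12)
      s <- steps[j] + f * 0.25
      out_x[i] <- x[i] + s * nx_[i]
      out_y[i] <- y[i] + s * ny_[i]
    }
  }
  cbind(out_x, out_y)
}

segment_failure <- function(flag, frame = NA_integer_) {
  structure(list(frame = frame, flag = flag), class = "segment_failure")
}

#' Segment one cell in one frame from a seed point
#'
#' Region-based segmentation: the image is Gaussian-smoothed, a threshold
#' halfway between the foreground and background means is iterated to a
#' fixed point, the connected bright region containing the seed is
#' extracted, and its boundary is traced and refined to sub-pixel accuracy
#' at the threshold iso-level, then lightly smoothed and resampled to ~1
#' vertex per 2 px of perimeter. The result is intensity-scale invariant:
#' all decisions compare relative means.
#'
#' @param img single-channel 2D frame (matrix, rows = y).
#' @param seed_xy_um seed point (x, y) in µm, inside the target object.
#' @param pixel_size_um calibration (> 0).
#' @param params a \code{\link{segment_params}}.
#' @param frame 0-based frame index stored on the contour.
#' @param ref_area_um2 optional reference area; if the segmented area
#'   exceeds \code{merge_area_factor} times it, the contour is flagged
#'   \code{merged_with_neighbor}.
#' @param object_role \code{"cell_body"} or \code{"nucleus"}.
#' @return a \code{cell_contour} (fields frame, vertices [µm, CCW],
#'   object_role, area_px) or a \code{segment_failure} with flag
#'   \code{low_contrast} or \code{merged_with_neighbor}.
#' @export
segment_cell <- function(img, seed_xy_um, pixel_size_um,
                         params = segment_params(), frame = 0L,
                         ref_area_um2 = NULL, object_role = "cell_body") {
  stopifnot(pixel_size_um > 0)
  sc <- seed_xy_um / pixel_size_um
  sr <- floor(sc[2]) + 1L; scol <- floor(sc[1]) + 1L
  if (sr < 1 || sr > nrow(img) || scol < 1 || scol > ncol(img))
    stop("seed point outside the image")
  img_s <- gaussian_blur(img, params$smooth_sigma)

  # seed must sit on signal well above the background level (relative test,
  # so the decision is intensity-scale invariant)
  q25 <- stats::quantile(img_s, 0.25, names = FALSE)
  rng <- max(img_s) - q25
  if (rng <= 0 || (img_s[sr, scol] - q25) / rng < params$min_contrast)
    return(segment_failure("low_contrast", frame))

  mu_fg <- mean(img_s[clamp((sr - 1):(sr + 1), 1, nrow(img)),
                      clamp((scol - 1):(scol + 1), 1, ncol(img))])
  mu_bg <- stats::quantile(img_s, 0.25, names = FALSE)
  comp <- NULL; level <- NA
  for (it in seq_len(params$max_iter)) {
    level <- (mu_fg + mu_bg) / 2
    comp_new <- flood_fill(img_s >= level, c(sr, scol))
    n_in <- sum(comp_new)
    if (n_in < 9L) break
    mu_fg_new <- mean(img_s[comp_new])
    # background from the dilated bounding box, excluding the component
    w <- which(comp_new, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - 10L); r1 <- min(nrow(img), max(w[, 1]) + 10L)
    c0 <- max(1L, min(w[, 2]) - 10L); c1 <- min(ncol(img), max(w[, 2]) + 10L)
    box <- img_s[r0:r1, c0:c1]; inbox <- comp_new[r0:r1, c0:c1]
    mu_bg_new <- if (any(!inbox)) mean(box[!inbox]) else mu_bg
    conv <- !is.null(comp) && sum(xor(comp, comp_new)) == 0
    comp <- comp_new; mu_fg <- mu_fg_new; mu_bg <- mu_bg_new
    if (conv) break
  }
  if (is.null(comp) || sum(comp) < 9L)
    return(segment_failure("low_contrast", frame))
  if (mu_fg <= 0 || (mu_fg - mu_bg) / mu_fg < params$min_contrast)
    return(segment_failure("low_contrast", frame))

  b <- trace_boundary(comp)
  if (nrow(b) < 8L) return(segment_failure("low_contrast", frame))
  v_px <- refine_boundary(img_s, b, level)
  per <- polygon_perimeter(v_px)
  n_target <- max(8L, round(per / params$vertex_spacing_px))
  v_px <- resample_polygon(v_px, max(n_target, 16L))
  v_px <- smooth_polygon(v_px, 5L)
  v_px <- resample_polygon(v_px, n_target)
  v_um <- ensure_ccw(v_px * pixel_size_um)
  area <- polygon_area(v_um)
  if (area <= 0) return(segment_failure("low_contrast", frame))
  if (!is.null(ref_area_um2) && area > params$merge_area_factor * ref_area_um2)
    return(segment_failure("merged_with_neighbor", frame))
  structure(list(frame = as.integer(frame), vertices = v_um,
                 object_role = object_role, area_px = sum(comp)),
            class = "cell_contour")
}

#' Segment one cell through a time-lapse by centroid reseeding
#'
#' Frame t+1 is seeded by the frame-t contour centroid (independent
#' per-frame segmentation, tolerant of large shape change). Failed frames
#' carry a quality flag and no contour; after more than \code{max_gap}
#' consecutive failures the series stops with flag \code{lost}.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param seed_xy_um initial seed (x, y) in µm, valid at \code{frames[1]}.
#' @param channel channel to segment.
#' @param params a \code{\link{segment_params}}.
#' @param frames 0-based frames to process (default: all).
#' @param object_role stored on each contour.
#' @return list of class \code{contour_series}: \code{contours} (named by
#'   frame; only frames flagged \code{ok}), \code{flags} (data frame
#'   frame, flag), \code{params}.
#' @export
segment_series <- function(stack, seed_xy_um, channel = 1,
                           params = segment_params(), frames = NULL,
                           object_role = "cell_body") {
  if (is.null(frames)) frames <- 0:(n_frames(stack) - 1L)
  seed <- seed_xy_um
  ref_area <- NULL
  contours <- list(); flags <- character(length(frames))
  gap <- 0L
  for (i in seq_along(frames)) {
    f <- frames[i]
    img <- get_frame(stack, f, channel)
    res <- tryCatch(
      segment_cell(img, seed, stack$pixel_size_um, params, frame = f,
                   ref_area_um2 = ref_area, object_role = object_role),
      error = function(e) segment_failure("low_contrast", f))
    if (inherits(res, "cell_contour")) {
      flags[i] <- "ok"
      contours[[as.character(f)]] <- res
      seed <- polygon_centroid(res$vertices)
      a <- polygon_area(res$vertices)
      ref_area <- if (is.null(ref_area)) a else 0.7 * ref_area + 0.3 * a
      gap <- 0L
    } else {
      flags[i] <- res$flag
      gap <- gap + 1L
      if (gap > params$max_gap) {
        flags[i] <- "lost"
        flags <- flags[seq_len(i)]
        frames <- frames[seq_len(i)]
        break
      }
    }
  }
  n_ok <- sum(flags == "ok")
  if (n_ok < params$min_frames)
    stop("segmentation lost the object after ", n_ok,
         " usable frame(s) (< min_frames = ", params$min_frames, ")")
  structure(list(contours = contours,
                 flags = data.frame(frame = frames, flag = flags),
                 params = params),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  tb <- table(x$flags$flag)
  cat("contour_series:", nrow(x$flags), "frames (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Convert a contour series (or contour list) to a long data frame
#' @param series a \code{contour_series} or list of \code{cell_contour}.
#' @return data frame (frame, vertex_index, x_um, y_um, flag).
#' @export
contour_series_df <- function(series) {
  contours <- if (inherits(series, "contour_series")) series$contours else series
  df <- contours_to_df(contours)
  if (inherits(series, "contour_series")) {
    df$flag <- "ok"
    miss <- series$flags[series$flags$flag != "ok", ]
    if (nrow(miss))
      df <- rbind(df, data.frame(frame = miss$frame, vertex_index = NA,
                                 x_um = NA, y_um = NA, flag = miss$flag))
    df <- df[order(df$frame), ]
  }
  df
}
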