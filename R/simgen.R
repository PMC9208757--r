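#' Configuration for the synthetic time-lapse generator
#'
#' Parameterizes a deformable migrating cell imaged as a 2D (optionally
#' thin-z) multi-channel time-lapse, with ground truth for every downstream
#' analysis: a correlated-random-walk centroid path, per-frame star-convex
#' cell contours elongated along the movement axis, protrusion tips whose
#' orientation concentrates toward the movement direction more strongly at
#' high instantaneous speed, a cortical marker channel enriched at the cell
#' rear, static crowded neighbour nuclei, and optional global XY drift.
#'
#' Defaults emulate the imaging conditions of light-sheet time lapses of
#' migrating retinal horizontal cells: 1 min frame interval, 0.3 µm/px,
#' a ~5 µm cell-body radius, and instantaneous speeds spanning roughly
#' 0.06–4.4 µm/min with lower/upper quartiles near 0.38 and 0.93 µm/min.
#'
#' @param field_size_px integer pair (width, height) in pixels.
#' @param pixel_size_um µm per pixel (> 0).
#' @param frame_interval_min minutes per frame (> 0).
#' @param n_frames number of frames (>= 2).
#' @param path_persistence direction correlation between consecutive steps,
#'   in [0, 1).
#' @param mean_speed_um_min mean instantaneous speed (µm/min, >= 0).
#' @param speed_shape gamma shape of per-frame speeds (controls how broad
#'   the realized speed distribution is around the mean).
#' @param protrusion_rate expected protrusion tips per frame (Poisson).
#' @param kappa_low,kappa_high von Mises concentration of the protrusion
#'   angular offset from the movement direction at low (< 25th pct) and
#'   high (> 75th pct) instantaneous speed; \code{kappa_low <= kappa_high}
#'   (protrusions are more front-biased at high speed).
#' @param protrusion_len_um length range (µm) of protrusion tips from the
#'   centroid.
#' @param rear_polarity_strength rear-to-front cortical intensity ratio
#'   (>= 1) of the polarity-marker channel.
#' @param rounding_frame optional 0-based frame at which the cell becomes a
#'   perfect circle (mitotic rounding); \code{NULL} for none.
#' @param drift_per_frame_px global XY drift added per frame (px, length-2).
#' @param neighbor_density neighbour nuclei per 100 x 100 px.
#' @param noise_sd additive Gaussian noise SD (intensity units, images are
#'   scaled to [0, 1]).
#' @param psf_sigma_px Gaussian optical-blur SD (px) applied to every
#'   rendered channel, emulating the microscope's in-plane point-spread
#'   function; 0 for crisp edges.
#' @param n_z 1 (single plane) or 3 (thin z-stack for the max-projection
#'   contract of the polarity line scan).
#' @param cell_radius_um equivalent cell-body radius (µm).
#' @param elongation typical major/minor axis ratio of the migrating cell.
#' @param shape_wobble amplitude of the per-frame radial Fourier deformation.
#' @param centrosome_offset_um distance of the centrosome from the centroid.
#' @param centrosome_pattern \code{"front"} (always ahead of the centroid
#'   along the movement direction) or \code{"alternate"} (fore/aft on
#'   alternating frames).
#' @param seed integer RNG seed; identical (config, seed) gives
#'   bit-identical outputs.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(field_size_px = c(200L, 200L),
                       pixel_size_um = 0.3,
                       frame_interval_min = 1,
                       n_frames = 60L,
                       path_persistence = 0.6,
                       mean_speed_um_min = 0.7,
                       speed_shape = 1.2,
                       protrusion_rate = 2,
                       kappa_low = 0.5,
                       kappa_high = 4,
                       protrusion_len_um = c(6, 9),
                       rear_polarity_strength = 3,
                       rounding_frame = NULL,
                       drift_per_frame_px = c(0, 0),
                       neighbor_density = 2,
                       noise_sd = 0.02,
                       psf_sigma_px = 0.7,
                       n_z = 1L,
                       cell_radius_um = 5,
                       elongation = 2,
                       shape_wobble = 0.1,
                       centrosome_offset_um = 2,
                       centrosome_pattern = c("front", "alternate"),
                       seed = 1L) {
  centrosome_pattern <- match.arg(centrosome_pattern)
  cfg <- list(field_size_px = as.integer(field_size_px),
              pixel_size_um = pixel_size_um,
              frame_interval_min = frame_interval_min,
              n_frames = as.integer(n_frames),
              path_persistence = path_persistence,
              mean_speed_um_min = mean_speed_um_min,
              speed_shape = speed_shape,
              protrusion_rate = protrusion_rate,
              kappa_low = kappa_low, kappa_high = kappa_high,
              protrusion_len_um = protrusion_len_um,
              rear_polarity_strength = rear_polarity_strength,
              rounding_frame = if (is.null(rounding_frame)) NULL else
                as.integer(rounding_frame),
              drift_per_frame_px = as.numeric(drift_per_frame_px),
              neighbor_density = neighbor_density,
              noise_sd = noise_sd,
              psf_sigma_px = psf_sigma_px,
              n_z = as.integer(n_z),
              cell_radius_um = cell_radius_um,
              elongation = elongation,
              shape_wobble = shape_wobble,
              centrosome_offset_um = centrosome_offset_um,
              centrosome_pattern = centrosome_pattern,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_frames < 2L) stop("invalid config: n_frames must be >= 2")
  if (length(cfg$field_size_px) != 2L || any(cfg$field_size_px < 16L))
    stop("invalid config: field_size_px must be two integers >= 16")
  if (cfg$pixel_size_um <= 0 || cfg$frame_interval_min <= 0 ||
      cfg$cell_radius_um <= 0)
    stop("invalid config: physical scales must be strictly positive")
  if (cfg$path_persistence < 0 || cfg$path_persistence >= 1)
    stop("invalid config: path_persistence must be in [0, 1)")
  if (cfg$mean_speed_um_min < 0 || cfg$protrusion_rate < 0)
    stop("invalid config: rates/speeds must be >= 0")
  if (cfg$kappa_low < 0 || cfg$kappa_high < 0)
    stop("invalid config: kappa parameters must be >= 0")
  if (cfg$kappa_low > cfg$kappa_high)
    stop("invalid config: kappa_low must be <= kappa_high")
  if (cfg$rear_polarity_strength < 1)
    stop("invalid config: rear_polarity_strength must be >= 1")
  if (!is.null(cfg$rounding_frame) &&
      (cfg$rounding_frame < 0L || cfg$rounding_frame >= cfg$n_frames))
    stop("invalid config: rounding_frame outside 0..n_frames-1")
  if (!cfg$n_z %in% c(1L, 3L)) stop("invalid config: n_z must be 1 or 3")
  if (cfg$noise_sd < 0 || cfg$neighbor_density < 0 || cfg$psf_sigma_px < 0)
    stop("invalid config: noise_sd, neighbor_density and psf_sigma_px must be >= 0")
  invisible(cfg)
}

# linear kappa interpolation between the low/high speed regimes
kappa_at_speed <- function(v, p25, p75, kappa_low, kappa_high) {
  if (v < p25) return(kappa_low)
  if (v > p75) return(kappa_high)
  if (p75 <= p25) return((kappa_low + kappa_high) / 2)
  kappa_low + (kappa_high - kappa_low) * (v - p25) / (p75 - p25)
}

# star-convex cell outline: area-preserving ellipse along `theta`, with a
# low-order radial Fourier wobble; exact circle when round = TRUE
star_contour <- function(center, radius_um, elong, theta, wobble_amp,
                         round = FALSE, n_vert = 64L) {
  phi <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
  if (round) {
    r <- rep(radius_um, n_vert)
    theta <- 0
  } else {
    a <- radius_um * sqrt(elong); b <- radius_um / sqrt(elong)
    r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    if (wobble_amp > 0) {
      for (k in 2:4) {
        amp <- wobble_amp * stats::runif(1, 0.2, 1) / (k - 1)
        r <- r * (1 + amp * cos(k * phi + stats::runif(1, 0, 2 * pi)))
      }
    }
  }
  v <- cbind(center[1] + r * cos(phi + theta),
             center[2] + r * sin(phi + theta))
  # pin the polygon's area centroid exactly on the requested centre
  v <- v + matrix(rep(center - polygon_centroid(v), each = n_vert), n_vert)
  ensure_ccw(v)
}

#' Simulate the ground-truth kinematics of one migrating cell
#'
#' Draws a correlated random-walk centroid path, per-frame cell contours
#' (elongated along the instantaneous movement axis; a perfect circle at
#' \code{rounding_frame}), protrusion tips with von Mises angular offsets
#' whose concentration follows the realized speed quartiles, a centrosome
#' track, and a fixed tissue-layer geometry. All positions in µm.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_kinematics} with elements \code{track},
#'   \code{protrusions} (with column \code{angle_true_deg}),
#'   \code{contours}, \code{centrosome} (with column \code{side_true}),
#'   \code{geometry}, \code{speeds_um_min}, \code{directions} (unit vectors
#'   per frame), \code{speed_thresholds} and \code{config}.
#' @export
simulate_kinematics <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_frames
    dt <- config$frame_interval_min
    psz <- config$pixel_size_um
    field_um <- config$field_size_px * psz
    margin <- config$cell_radius_um * sqrt(config$elongation) * 1.3 + 2

    # headings: wrapped-normal turning so that E[cos(turn)] = persistence
    p <- config$path_persistence
    head0 <- stats::runif(1, -pi, pi)
    turns <- if (p <= 0) stats::runif(n - 1, -pi, pi) else
      stats::rnorm(n - 1, 0, sqrt(-2 * log(p)))
    headings <- cumsum(c(head0, turns))

    step_len <- if (config$mean_speed_um_min <= 0) rep(0, n - 1) else
      stats::rgamma(n - 1, shape = config$speed_shape,
                    scale = config$mean_speed_um_min /
                      config$speed_shape) * dt

    pos <- matrix(0, n, 2)
    pos[1, ] <- field_um / 2
    for (t in seq_len(n - 1)) {
      nxt <- pos[t, ] + step_len[t] * c(cos(headings[t]), sin(headings[t]))
      # reflect at the field margins so the cell stays imageable
      for (k in 1:2) {
        if (nxt[k] < margin) nxt[k] <- 2 * margin - nxt[k]
        if (nxt[k] > field_um[k] - margin) nxt[k] <- 2 * (field_um[k] - margin) - nxt[k]
      }
      pos[t + 1, ] <- nxt
    }

    disp <- diff(pos)
    speeds <- sqrt(rowSums(disp^2)) / dt          # µm/min, steps 0..n-2
    dirs <- matrix(NA_real_, n, 2)                # direction at interval start
    valid <- speeds > 1e-12
    dirs[which(valid), ] <- disp[valid, , drop = FALSE] / (speeds[valid] * dt)
    # last frame inherits the last defined direction; undefined -> +x
    last_dir <- c(1, 0)
    for (t in seq_len(n)) {
      if (t <= n - 1 && valid[t]) last_dir <- dirs[t, ]
      dirs[t, ] <- last_dir
    }

    vs <- speeds[valid]
    thr <- if (length(vs) >= 4)
      stats::quantile(vs, c(0.25, 0.75), names = FALSE, type = 7) else c(NA, NA)

    contours <- vector("list", n)
    for (t in seq_len(n)) {
      is_round <- !is.null(config$rounding_frame) &&
        (t - 1L) == config$rounding_frame
      theta <- atan2(dirs[t, 2], dirs[t, 1])
      contours[[t]] <- structure(
        list(frame = t - 1L,
             vertices = star_contour(pos[t, ], config$cell_radius_um,
                                     config$elongation, theta,
                                     config$shape_wobble, round = is_round),
             object_role = "cell_body"),
        class = "cell_contour")
    }

    # protrusion tips: one single-sample track per tip, truth angle recorded
    tip_rows <- list()
    if (config$protrusion_rate > 0) {
      for (t in seq_len(n - 1)) {
        if (!valid[t] || any(is.na(thr))) next
        np <- stats::rpois(1, config$protrusion_rate)
        if (np == 0) next
        kap <- kappa_at_speed(speeds[t], thr[1], thr[2],
                              config$kappa_low, config$kappa_high)
        off <- rvonmises0(np, kap)
        len <- stats::runif(np, config$protrusion_len_um[1],
                            config$protrusion_len_um[2])
        ang <- atan2(dirs[t, 2], dirs[t, 1]) + off
        tip_rows[[length(tip_rows) + 1L]] <- data.frame(
          track_id = sprintf("tip_f%03d_%02d", t - 1L, seq_len(np)),
          frame = t - 1L,
          x_um = pos[t, 1] + len * cos(ang),
          y_um = pos[t, 2] + len * sin(ang),
          angle_true_deg = deg(abs(off)))
      }
    }
    tips <- if (length(tip_rows)) do.call(rbind, tip_rows) else
      data.frame(track_id = character(0), frame = integer(0),
                 x_um = numeric(0), y_um = numeric(0),
                 angle_true_deg = numeric(0))
    prot <- point_tracks(tips$track_id, tips$frame, tips$x_um, tips$y_um,
                         role = "protrusion_tip")
    prot$angle_true_deg <- tips$angle_true_deg[match(
      paste(prot$track_id, prot$frame), paste(tips$track_id, tips$frame))]

    side <- if (config$centrosome_pattern == "front") rep(1, n) else
      rep_len(c(1, -1), n)
    centro <- point_tracks(
      rep("centrosome", n), 0:(n - 1),
      pos[, 1] + side * config$centrosome_offset_um * dirs[, 1],
      pos[, 2] + side * config$centrosome_offset_um * dirs[, 2],
      role = "centrosome")
    centro$side_true <- ifelse(side > 0, "front", "back")

    geom <- tissue_geometry(
      frame = rep(0:(n - 1), each = 3),
      layer = rep(c("apical_surface", "OPL", "IPL"), n),
      y_um = rep(c(0.15, 0.5, 0.85) * field_um[2], n),
      basal_sign = 1)

    structure(list(
      track = point_tracks(rep("cell", n), 0:(n - 1), pos[, 1], pos[, 2],
                           role = "cell_centroid"),
      protrusions = prot,
      contours = contours,
      centrosome = centro,
      geometry = geom,
      speeds_um_min = speeds,
      directions = dirs,
      speed_thresholds = c(p25_um_min = thr[1], p75_um_min = thr[2]),
      config = config), class = "sim_kinematics")
  })
}

# quantize to the 16-bit grid used on disk, so memory and file agree exactly
quantize16 <- function(x) round(clamp(x, 0, 1) * 65535) / 65535

#' Render a simulated cell into a multi-channel image stack
#'
#' Channel 1 (\code{cell}): the filled cell contour. Channel 2
#' (\code{polarity}): a 3 px cortical band whose intensity rises linearly
#' from the cell front to the cell back by \code{rear_polarity_strength}.
#' Channel 3 (\code{nuclei}): static neighbour nuclei (non-overlapping
#' ellipses avoiding the cell's path). Global drift accumulates at
#' \code{drift_per_frame_px} per frame (frame 0 undrifted) and shifts all
#' channels; additive Gaussian noise of SD \code{noise_sd} is applied last
#' and intensities are clipped to [0, 1] and quantized to the 16-bit grid.
#'
#' @param kin a \code{sim_kinematics} result.
#' @param config the same \code{\link{sim_config}} (defaults to
#'   \code{kin$config}).
#' @return list with \code{stack} (an \code{\link{image_stack}}),
#'   \code{truth_drift} (data frame frame, dx_px, dy_px, cumulative),
#'   and \code{flagged_frames} (frames whose contour exceeds the field
#'   after drift; rendered clipped but flagged, never silently dropped).
#' @export
render_frames <- function(kin, config = kin$config) {
  stopifnot(inherits(kin, "sim_kinematics"))
  if (length(kin$contours) != config$n_frames)
    stop("kinematics truth must cover every frame")
  with_seed(config$seed + 1L, {
    nx <- config$field_size_px[1]; ny <- config$field_size_px[2]
    psz <- config$pixel_size_um
    n <- config$n_frames
    cum_drift <- cbind(dx_px = (0:(n - 1)) * config$drift_per_frame_px[1],
                       dy_px = (0:(n - 1)) * config$drift_per_frame_px[2])

    # static neighbour nuclei, sampled away from the cell's whole path
    n_nuc <- round(config$neighbor_density * nx * ny / 1e4)
    path <- cbind(kin$track$x_um, kin$track$y_um)
    reach <- config$cell_radius_um * sqrt(config$elongation) * 1.25
    nuclei <- list()
    tries <- 0L
    while (length(nuclei) < n_nuc && tries < 300L * max(n_nuc, 1L)) {
      tries <- tries + 1L
      a <- stats::runif(1, 2.5, 3.5); ratio <- stats::runif(1, 1.2, 1.8)
      b <- a / ratio
      ctr <- c(stats::runif(1, a, nx * psz - a),
               stats::runif(1, a, ny * psz - a))
      d_path <- min(sqrt((path[, 1] - ctr[1])^2 + (path[, 2] - ctr[2])^2))
      if (d_path < reach + a + 1) next
      clash <- FALSE
      for (nu in nuclei)
        if (sqrt(sum((nu$ctr - ctr)^2)) < (nu$a + a) * 0.95) { clash <- TRUE; break }
      if (clash) next
      nuclei[[length(nuclei) + 1L]] <-
        list(ctr = ctr, a = a, b = b, th = stats::runif(1, 0, pi))
    }
    nuc_polys <- lapply(nuclei, function(nu) {
      phi <- seq(0, 2 * pi, length.out = 33)[-33]
      xy <- cbind(nu$a * cos(phi), nu$b * sin(phi)) %*% t(rot2(nu$th))
      cbind(xy[, 1] + nu$ctr[1], xy[, 2] + nu$ctr[2])
    })

    nz <- config$n_z
    z_w <- if (nz == 3L) c(0.6, 1, 0.6) else 1
    arr <- if (nz == 1L) array(0, c(ny, nx, 3L, n)) else
      array(0, c(ny, nx, nz, 3L, n))
    flagged <- integer(0)

    for (t in seq_len(n)) {
      sh_um <- cum_drift[t, ] * psz
      cell <- matrix(0, ny, nx); pol <- matrix(0, ny, nx)
      nucs <- matrix(0, ny, nx)

      v_um <- kin$contours[[t]]$vertices +
        matrix(rep(sh_um, each = nrow(kin$contours[[t]]$vertices)), ncol = 2)
      v_px <- v_um / psz
      if (min(v_px[, 1]) < 0 || min(v_px[, 2]) < 0 ||
          max(v_px[, 1]) > nx || max(v_px[, 2]) > ny)
        flagged <- c(flagged, t - 1L)

      px <- rasterize_polygon(v_px, ny, nx)
      if (nrow(px)) {
        cell[px] <- 0.8
        # cortical band: inside pixels within 3 px of the boundary
        pts <- cbind(px[, "col"] - 0.5, px[, "row"] - 0.5)
        dists <- dist_to_polygon(pts, v_px)
        band <- dists <= 3
        if (any(band)) {
          d <- kin$directions[t, ]
          ctr <- (polygon_centroid(v_um)) / psz
          proj <- (pts[band, 1] - ctr[1]) * d[1] + (pts[band, 2] - ctr[2]) * d[2]
          # normalized axial position: 0 at the front tip, 1 at the back
          pr_f <- max(proj); pr_b <- min(proj)
          s <- if (pr_f - pr_b < 1e-9) rep(0.5, sum(band)) else
            (pr_f - proj) / (pr_f - pr_b)
          pol[px[band, , drop = FALSE]] <-
            0.25 * (1 + (config$rear_polarity_strength - 1) * s)
        }
      }
      for (np in nuc_polys) {
        vpx <- (np + matrix(rep(sh_um, each = nrow(np)), ncol = 2)) / psz
        ix <- rasterize_polygon(vpx, ny, nx)
        if (nrow(ix)) nucs[ix] <- 0.7
      }
      for (ch in 1:3) {
        base <- switch(ch, cell, pol, nucs)
        if (config$psf_sigma_px > 0)
          base <- gaussian_blur(base, config$psf_sigma_px)
        for (z in seq_len(nz)) {
          img <- base * z_w[z]
          if (config$noise_sd > 0)
            img <- img + stats::rnorm(length(img), 0, config$noise_sd)
          img <- quantize16(img)
          if (nz == 1L) arr[, , ch, t] <- img else arr[, , z, ch, t] <- img
        }
      }
    }
    list(stack = image_stack(arr, psz, config$frame_interval_min,
                             channel_names = c("cell", "polarity", "nuclei")),
         truth_drift = data.frame(frame = 0:(n - 1),
                                  dx_px = cum_drift[, 1],
                                  dy_px = cum_drift[, 2]),
         flagged_frames = unique(flagged))
  })
}

contours_to_df <- function(contours) {
  do.call(rbind, lapply(contours, function(ct)
    data.frame(frame = ct$frame,
               vertex_index = seq_len(nrow(ct$vertices)) - 1L,
               x_um = ct$vertices[, 1], y_um = ct$vertices[, 2])))
}

df_to_contours <- function(df, object_role = "cell_body") {
  lapply(split(df, df$frame), function(sub) {
    sub <- sub[order(sub$vertex_index), ]
    structure(list(frame = sub$frame[1],
                   vertices = cbind(sub$x_um, sub$y_um),
                   object_role = object_role),
              class = "cell_contour")
  })
}

#' Generate and persist a complete synthetic dataset
#'
#' Runs \code{\link{simulate_kinematics}} and \code{\link{render_frames}}
#' and writes the TIFF stack, all ground-truth CSV tables and a YAML echo
#' of the configuration to \code{dir}. The same (config, seed) written
#' twice produces byte-identical files; \code{\link{read_dataset}}
#' round-trips the result exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory \code{kin}, \code{render}
#'   and the output \code{dir}.
#' @export
generate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create dataset directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("dataset directory not writable: ", dir)
  kin <- simulate_kinematics(config)
  ren <- render_frames(kin, config)
  write_stack(ren$stack, file.path(dir, "stack.tif"))
  write_atomic_csv(as.data.frame(kin$track),
                   file.path(dir, "truth_cell_track.csv"))
  write_atomic_csv(as.data.frame(kin$protrusions),
                   file.path(dir, "truth_protrusions.csv"))
  write_atomic_csv(as.data.frame(kin$centrosome),
                   file.path(dir, "truth_centrosome.csv"))
  write_atomic_csv(contours_to_df(kin$contours),
                   file.path(dir, "truth_contours.csv"))
  write_atomic_csv(ren$truth_drift, file.path(dir, "truth_drift.csv"))
  write_atomic_csv(as.data.frame(kin$geometry),
                   file.path(dir, "truth_geometry.csv"))
  cfg <- config
  cfg$rounding_frame <- if (is.null(cfg$rounding_frame)) -1L else cfg$rounding_frame
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(list(kin = kin, render = ren, dir = dir))
}

#' Reload a persisted synthetic dataset
#' @param dir directory written by \code{\link{generate_dataset}}.
#' @return list with \code{stack}, \code{config}, and all truth tables.
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  if (!is.null(cfg$rounding_frame) && cfg$rounding_frame < 0)
    cfg$rounding_frame <- NULL
  cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  # pages are frame-major: channels consecutive within a frame, z planes
  # consecutive within a channel
  stack <- read_stack(file.path(dir, "stack.tif"), cfg$pixel_size_um,
                      cfg$frame_interval_min, n_channels = 3L * cfg$n_z)
  if (cfg$n_z == 3L) {
    d <- dim(stack$pixels)
    arr5 <- array(0, c(d[1], d[2], 3L, 3L, d[4]))
    for (f in seq_len(d[4])) for (ch in 1:3) for (z in 1:3)
      arr5[, , z, ch, f] <- stack$pixels[, , (ch - 1L) * 3L + z, f]
    stack <- image_stack(arr5, cfg$pixel_size_um, cfg$frame_interval_min,
                         channel_names = c("cell", "polarity", "nuclei"))
  } else {
    stack$channel_names <- c("cell", "polarity", "nuclei")
  }
  tr <- utils::read.csv(file.path(dir, "truth_cell_track.csv"))
  pr <- utils::read.csv(file.path(dir, "truth_protrusions.csv"))
  ce <- utils::read.csv(file.path(dir, "truth_centrosome.csv"))
  prot <- point_tracks(pr$track_id, pr$frame, pr$x_um, pr$y_um,
                       role = "protrusion_tip")
  prot$angle_true_deg <- pr$angle_true_deg[match(
    paste(prot$track_id, prot$frame), paste(pr$track_id, pr$frame))]
  centro <- point_tracks(ce$track_id, ce$frame, ce$x_um, ce$y_um,
                         role = "centrosome")
  centro$side_true <- ce$side_true[match(
    paste(centro$track_id, centro$frame), paste(ce$track_id, ce$frame))]
  list(stack = stack, config = cfg,
       track = point_tracks(tr$track_id, tr$frame, tr$x_um, tr$y_um,
                            role = "cell_centroid"),
       protrusions = prot,
       centrosome = centro,
       contours = df_to_contours(
         utils::read.csv(file.path(dir, "truth_contours.csv"))),
       drift = utils::read.csv(file.path(dir, "truth_drift.csv")),
       geometry = read_geometry(file.path(dir, "truth_geometry.csv")))
}
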