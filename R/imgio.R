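#' Calibrated image stack
#'
#' Container for a multi-channel time-lapse image stack. Pixels are stored as
#' a 4D array \code{[y, x, channel, frame]} (or 5D \code{[y, x, z, channel,
#' frame]} for a small z extent). The physical calibration (micrometres per
#' pixel, minutes per frame) travels with the pixels; every downstream
#' quantity is reported in micrometres and minutes.
#'
#' Image coordinate convention: origin at the top-left corner, x rightward,
#' y downward; the centre of pixel (row r, column c) is at
#' ((c - 0.5), (r - 0.5)) pixels. The apico-basal tissue axis maps to image
#' y unless a geometry table says otherwise.
#'
#' @param pixels numeric array, dims (y, x, channel, frame) or
#'   (y, x, z, channel, frame); finite, non-negative.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_interval_min frame interval in minutes (> 0).
#' @param channel_names optional character vector of channel labels.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(pixels, pixel_size_um, frame_interval_min,
                        channel_names = NULL) {
  if (!is.array(pixels) || !(length(dim(pixels)) %in% c(4L, 5L)))
    stop("`pixels` must be a 4D (y,x,channel,frame) or 5D (y,x,z,channel,frame) array")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1 ||
      frame_interval_min <= 0)
    stop("`frame_interval_min` must be a single positive number")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0")
  d <- dim(pixels)
  has_z <- length(d) == 5L
  n_channels <- d[length(d) - 1L]
  n_frames <- d[length(d)]
  if (n_frames < 1L) stop("stack must have at least one frame")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_channels))
  if (length(channel_names) != n_channels)
    stop("length(channel_names) must equal the number of channels")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 channel_names = channel_names, has_z = has_z),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("image_stack:", d[2], "x", d[1], "px,",
      if (x$has_z) paste(d[3], "z-planes,") else "",
      n_frames(x), "frames,", length(x$channel_names), "channel(s) [",
      paste(x$channel_names, collapse = ", "), "]\n")
  cat("  calibration:", x$pixel_size_um, "um/px,",
      x$frame_interval_min, "min/frame\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[length(dim(stack$pixels))]

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("unknown channel: ", channel)
    ci
  } else as.integer(channel)
}

#' Extract one frame of one channel as a y-by-x matrix
#'
#' @param stack an \code{image_stack}.
#' @param frame 0-based frame index.
#' @param channel channel index or name.
#' @param project_z for a z-stack, max-project the 3 central z planes
#'   (the projection the line-scan profiling contract assumes).
#' @return numeric matrix (rows = y, cols = x).
#' @export
get_frame <- function(stack, frame, channel = 1, project_z = FALSE) {
  ci <- channel_index(stack, channel)
  fi <- frame + 1L
  if (fi < 1L || fi > n_frames(stack)) stop("frame out of range: ", frame)
  if (!stack$has_z) return(stack$pixels[, , ci, fi])
  nz <- dim(stack$pixels)[3]
  if (project_z) {
    mid <- ceiling(nz / 2)
    zz <- clamp((mid - 1L):(mid + 1L), 1L, nz)
    sub <- stack$pixels[, , unique(zz), ci, fi, drop = FALSE]
    apply(sub, c(1, 2), max)
  } else {
    stack$pixels[, , ceiling(nz / 2), ci, fi]
  }
}

#' Read a calibrated TIFF stack
#'
#' Reads a frame-major multi-page grayscale TIFF (pages ordered frame by
#' frame, channels consecutive within each frame) into an
#' \code{image_stack}. Calibration is always an explicit argument: pixel
#' size is acquisition-specific and is never defaulted.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_min physical calibration (> 0).
#' @param n_channels number of interleaved channels per frame.
#' @param channel_names optional channel labels.
#' @return an \code{image_stack}.
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_min,
                       n_channels = 1L, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("TIFF has no pages: ", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("format error: expected single-sample grayscale pages (axis ",
         "problem: page has a sample/colour axis); split channels upstream")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: pages differ in size (inconsistent y/x axes)")
  if (length(pages) %% n_channels != 0L)
    stop("format error: page count ", length(pages),
         " is not a multiple of n_channels = ", n_channels,
         " (ambiguous frame/channel axes)")
  nf <- length(pages) %/% n_channels
  arr <- array(0, c(dims[1, 1], dims[2, 1], n_channels, nf))
  for (f in seq_len(nf)) for (ch in seq_len(n_channels))
    arr[, , ch, f] <- pages[[(f - 1L) * n_channels + ch]]
  image_stack(arr, pixel_size_um, frame_interval_min, channel_names)
}

#' Write an image stack as a frame-major multi-page TIFF
#'
#' Intensities must lie in [0, 1]; they are stored as 16-bit samples.
#' A z-stack is written plane-major within each (frame, channel) page group.
#'
#' @param stack an \code{image_stack}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  if (max(stack$pixels) > 1 + 1e-12)
    stop("intensities must be <= 1 for 16-bit TIFF export")
  pages <- list()
  if (stack$has_z) {
    for (f in seq_len(d[5])) for (ch in seq_len(d[4])) for (z in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- stack$pixels[, , z, ch, f]
  } else {
    for (f in seq_len(d[4])) for (ch in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- stack$pixels[, , ch, f]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# --- point tracks -------------------------------------------------------

#' Build a point-track table
#'
#' A point track is a time-indexed position series for one labelled object:
#' a cell centroid, a protrusion tip, or a centrosome. Tracks live in a
#' plain data frame (columns \code{track_id}, \code{frame}, \code{x_um},
#' \code{y_um}) with a role attribute; frames are 0-based and strictly
#' increasing within a track, and gaps are permitted and preserved.
#'
#' @param track_id vector of track labels.
#' @param frame 0-based integer frame indices.
#' @param x_um,y_um positions in micrometres.
#' @param role one of \code{"cell_centroid"}, \code{"protrusion_tip"},
#'   \code{"centrosome"}.
#' @return data frame of class \code{point_tracks}.
#' @export
point_tracks <- function(track_id, frame, x_um, y_um,
                         role = c("cell_centroid", "protrusion_tip", "centrosome")) {
  role <- match.arg(role)
  df <- data.frame(track_id = track_id, frame = as.integer(frame),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um))
  validate_tracks(df)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, role = role, class = c("point_tracks", "data.frame"))
}

validate_tracks <- function(df) {
  if (nrow(df)) {
    key <- paste(df$track_id, df$frame)
    if (anyDuplicated(key))
      stop("duplicate (track, frame) rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(df)
}

#' Read point tracks from CSV (MTrackJ-style)
#'
#' Accepts any CSV whose header contains a track id, frame, x and y column
#' (case-insensitive; \code{track_id}/\code{tid}/\code{track},
#' \code{frame}/\code{t}, \code{x}/\code{x_um}/\code{x_px}, same for y).
#' Coordinates may be in pixels or micrometres; pixels require
#' \code{pixel_size_um}. MTrackJ exports number frames from 1; pass
#' \code{frames_one_based = TRUE} so frame 1 maps to internal frame 0 —
#' a silent off-by-one here is the classic tracking bug.
#'
#' @param path CSV path.
#' @param role track role (see \code{\link{point_tracks}}).
#' @param units \code{"um"} or \code{"px"}.
#' @param pixel_size_um required when \code{units = "px"}.
#' @param frames_one_based logical; subtract 1 from the frame column.
#' @return a \code{point_tracks} data frame (possibly empty).
#' @export
read_tracks <- function(path, role = "cell_centroid", units = c("um", "px"),
                        pixel_size_um = NULL, frames_one_based = FALSE) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("cannot read tracks: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(df))
  find_col <- function(cands) {
    i <- which(nm %in% cands)
    if (!length(i)) stop("track CSV missing a (", paste(cands, collapse = "/"),
                         ") column: ", path)
    i[1]
  }
  it <- find_col(c("track_id", "tid", "track"))
  if (nrow(df) == 0L) {
    warning("empty track file: ", path)
    return(point_tracks(character(0), integer(0), numeric(0), numeric(0),
                        role = role))
  }
  ifr <- find_col(c("frame", "t", "time_point"))
  ix <- find_col(c("x_um", "x", "x_px"))
  iy <- find_col(c("y_um", "y", "y_px"))
  fr <- as.integer(df[[ifr]]) - if (frames_one_based) 1L else 0L
  if (any(fr < 0L)) stop("negative frame index after 0-basing; check frames_one_based")
  x <- as.numeric(df[[ix]]); y <- as.numeric(df[[iy]])
  if (units == "px") {
    if (is.null(pixel_size_um) || pixel_size_um <= 0)
      stop("units = 'px' requires a positive pixel_size_um")
    x <- x * pixel_size_um; y <- y * pixel_size_um
  }
  ord <- order(df[[it]], fr)
  sp <- split(fr[ord], df[[it]][ord])
  bad <- names(sp)[vapply(sp, function(f) any(diff(f) <= 0L), logical(1))]
  if (length(bad))
    stop("non-monotone or duplicated frames in track(s): ",
         paste(bad, collapse = ", "))
  point_tracks(df[[it]], fr, x, y, role = role)
}

#' Write point tracks to CSV
#' @param tracks a \code{point_tracks} data frame.
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  write_atomic_csv(as.data.frame(tracks), path)
}

# --- tissue geometry ----------------------------------------------------

#' Per-frame tissue-layer landmarks
#'
#' Positions of the apical surface and of the outer/inner plexiform layers
#' (OPL/IPL) along the apico-basal axis, per frame, in micrometre image
#' coordinates. Layers are horizontal lines (constant y) in the primary
#' form; curved layers may be supplied as per-frame polylines to
#' \code{\link{depth_relative_to_layer}}. By convention image +y is basal
#' unless \code{basal_sign = -1}.
#'
#' @param frame 0-based frame indices.
#' @param layer layer name per row: \code{"apical_surface"}, \code{"OPL"},
#'   \code{"IPL"}.
#' @param y_um layer position (µm).
#' @param basal_sign +1 if larger y is more basal, -1 otherwise.
#' @return data frame of class \code{tissue_geometry}.
#' @export
tissue_geometry <- function(frame, layer, y_um, basal_sign = 1) {
  stopifnot(basal_sign %in% c(-1, 1))
  df <- data.frame(frame = as.integer(frame), layer = as.character(layer),
                   y_um = as.numeric(y_um))
  ok <- df$layer %in% c("apical_surface", "OPL", "IPL")
  if (any(!ok)) stop("unknown layer name(s): ",
                     paste(unique(df$layer[!ok]), collapse = ", "))
  # the OPL must lie between the apical surface and the IPL where all exist
  for (f in unique(df$frame)) {
    sub <- df[df$frame == f, ]
    a <- sub$y_um[sub$layer == "apical_surface"]
    o <- sub$y_um[sub$layer == "OPL"]
    i <- sub$y_um[sub$layer == "IPL"]
    if (length(a) && length(o) && length(i) &&
        !(min(a, i) <= o && o <= max(a, i)))
      stop("frame ", f, ": OPL must lie between the apical surface and the IPL")
  }
  structure(df, basal_sign = basal_sign,
            class = c("tissue_geometry", "data.frame"))
}

#' Read tissue geometry from CSV (frame, layer, y_um)
#' @param path CSV path.
#' @param basal_sign +1 if larger y is more basal.
#' @export
read_geometry <- function(path, basal_sign = 1) {
  df <- utils::read.csv(path)
  tissue_geometry(df$frame, df$layer, df$y_um, basal_sign = basal_sign)
}

# --- result writing -----------------------------------------------------

# Atomic CSV write: write to a temp file in the same directory, then rename,
# so a failed write never leaves a truncated file behind.
write_atomic_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))  # declared µm precision
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  ok <- tryCatch({
    utils::write.csv(df, tmp, row.names = FALSE)
    file.rename(tmp, path)
  }, error = function(e) {
    unlink(tmp)
    stop("failed writing ", path, ": ", conditionMessage(e))
  })
  if (!isTRUE(ok)) { unlink(tmp); stop("failed writing ", path) }
  invisible(path)
}

# Small stable content hash (polynomial rolling hash over the serialized
# object), for the run manifest; not cryptographic.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write result tables plus a run manifest
#'
#' Writes each table as \code{<name>.csv} (atomically: write-then-rename)
#' and a \code{manifest.yaml} recording the inputs, parameters, their hash,
#' the seed and the package version, so any run can be reproduced.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param inputs named list describing input files/parameters (recorded).
#' @param seed the RNG seed used (recorded).
#' @return path of the manifest file, invisibly.
#' @export
write_results <- function(tables, dir, inputs = list(), seed = NA) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  for (nm in names(tables))
    write_atomic_csv(as.data.frame(tables[[nm]]), file.path(dir, paste0(nm, ".csv")))
  manifest <- list(
    package = "hcmigrate",
    version = as.character(utils::packageVersion("hcmigrate")),
    inputs = inputs,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = content_hash(inputs),
    tables = paste0(names(tables), ".csv"))
  mpath <- file.path(dir, "manifest.yaml")
  tmp <- tempfile(tmpdir = dir, fileext = ".yaml.tmp")
  yaml::write_yaml(manifest, tmp)
  file.rename(tmp, mpath)
  invisible(mpath)
}
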