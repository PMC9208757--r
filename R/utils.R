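# Internal helpers: RNG scoping, image sampling, polygon geometry.

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# --- image sampling -----------------------------------------------------

# Pixel (row r, col c) has centre (x, y) = (c - 0.5, r - 0.5) in px units.
# Bilinear sampling at continuous pixel coordinates; outside -> 0.
bilinear_sample <- function(img, x_px, y_px) {
  nr <- nrow(img); nc <- ncol(img)
  cc <- x_px + 0.5; rr <- y_px + 0.5
  c0 <- floor(cc); r0 <- floor(rr)
  fc <- cc - c0; fr <- rr - r0
  pick <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- pick(r0, c0); v01 <- pick(r0, c0 + 1)
  v10 <- pick(r0 + 1, c0); v11 <- pick(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Separable Gaussian blur with replicated edges, via banded matrix products.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  kr <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-kr):kr)^2 / (2 * sigma^2)); k <- k / sum(k)
  smooth_dim <- function(n) {
    idx <- outer(seq_len(n), (-kr):kr, `+`)
    idx <- clamp(idx, 1L, n)           # replicate edges
    M <- matrix(0, n, n)
    for (j in seq_len(2 * kr + 1)) {
      M[cbind(seq_len(n), idx[, j])] <- M[cbind(seq_len(n), idx[, j])] + k[j]
    }
    M
  }
  Mr <- smooth_dim(nrow(img)); Mc <- smooth_dim(ncol(img))
  Mr %*% img %*% t(Mc)
}

# Shift an image by (dx, dy) px: out(r, c) = in(r - dy, c - dx), bilinear,
# zero padding outside.
translate_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc) - dx
  ys <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc) - dy
  matrix(bilinear_sample(img, as.vector(xs), as.vector(ys)), nr, nc)
}

# --- polygon geometry ---------------------------------------------------

close_ring <- function(v) rbind(v, v[1, , drop = FALSE])

polygon_area <- function(v) {
  w <- close_ring(v)
  x <- w[, 1]; y <- w[, 2]; n <- nrow(w)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

polygon_perimeter <- function(v) {
  w <- close_ring(v)
  sum(sqrt(rowSums(diff(w)^2)))
}

polygon_centroid <- function(v) {
  w <- close_ring(v)
  x <- w[, 1]; y <- w[, 2]; n <- nrow(w)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(v))
  c(sum((x[-n] + x[-1]) * cr), sum((y[-n] + y[-1]) * cr)) / (6 * a)
}

# Normalized central second moments of the polygon region (Green's theorem).
# For an ellipse with semi-axes a >= b these are (a^2/4, b^2/4) along the axes.
polygon_moments <- function(v) {
  w <- close_ring(v)
  x <- w[, 1]; y <- w[, 2]; n <- nrow(w)
  x0 <- x[-n]; x1 <- x[-1]; y0 <- y[-n]; y1 <- y[-1]
  cr <- x0 * y1 - x1 * y0
  a <- sum(cr) / 2
  cx <- sum((x0 + x1) * cr) / (6 * a)
  cy <- sum((y0 + y1) * cr) / (6 * a)
  ixx <- sum((x0^2 + x0 * x1 + x1^2) * cr) / 12
  iyy <- sum((y0^2 + y0 * y1 + y1^2) * cr) / 12
  ixy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cr) / 24
  list(area = a, centroid = c(cx, cy),
       cov = matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                      ixy / a - cx * cy, iyy / a - cy^2), 2, 2))
}

# Ensure positive (counter-clockwise by shoelace) orientation.
ensure_ccw <- function(v) {
  if (polygon_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

# Resample a closed polygon to n vertices equally spaced in arc length.
resample_polygon <- function(v, n) {
  w <- close_ring(v)
  seg <- sqrt(rowSums(diff(w)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  ix <- findInterval(s, cum, rightmost.closed = TRUE)
  ix <- clamp(ix, 1L, nrow(w) - 1L)
  t <- (s - cum[ix]) / pmax(seg[ix], .Machine$double.eps)
  w[ix, , drop = FALSE] + t * (w[ix + 1, , drop = FALSE] - w[ix, , drop = FALSE])
}

# Circular moving-average smoothing of a closed polygon's vertices.
smooth_polygon <- function(v, window) {
  if (window < 2) return(v)
  n <- nrow(v)
  half <- floor(window / 2)
  idx <- outer(seq_len(n), (-half):half, function(i, k) ((i + k - 1) %% n) + 1)
  out <- v
  out[, 1] <- rowMeans(matrix(v[idx, 1], n))
  out[, 2] <- rowMeans(matrix(v[idx, 2], n))
  out
}

# Point-in-polygon on a grid of pixel centres covering the polygon's
# bounding box (in px units). Returns row/col indices of inside pixels.
rasterize_polygon <- function(v_px, nr, nc) {
  r0 <- max(1L, floor(min(v_px[, 2]) + 0.5)); r1 <- min(nr, ceiling(max(v_px[, 2]) + 0.5))
  c0 <- max(1L, floor(min(v_px[, 1]) + 0.5)); c1 <- min(nc, ceiling(max(v_px[, 1]) + 0.5))
  if (r1 < r0 || c1 < c0) return(cbind(row = integer(0), col = integer(0)))
  rows <- r0:r1; cols <- c0:c1
  grid <- cbind(x = rep(cols - 0.5, each = length(rows)),
                y = rep(rows - 0.5, length(cols)))
  inside <- mgcv::in.out(close_ring(v_px), grid)
  cbind(row = rep(rows, length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

# Minimum distance from points to a closed polygon's boundary.
dist_to_polygon <- function(pts, v) {
  w <- close_ring(v)
  a <- w[-nrow(w), , drop = FALSE]
  b <- w[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), .Machine$double.eps)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(a))) {
    ap_x <- pts[, 1] - a[i, 1]; ap_y <- pts[, 2] - a[i, 2]
    t <- clamp((ap_x * ab[i, 1] + ap_y * ab[i, 2]) / len2[i], 0, 1)
    dx <- ap_x - t * ab[i, 1]; dy <- ap_y - t * ab[i, 2]
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

# von Mises sampler (Best & Fisher 1979 rejection method), mean 0,
# concentration kappa >= 0; kappa = 0 degenerates to uniform on (-pi, pi].
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-9) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    val <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(val), m)
    if (take > 0) out[(got + 1):(got + take)] <- val[seq_len(take)]
    got <- got + take
  }
  out
}
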