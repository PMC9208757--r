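# shared fixtures, built in code

small_config <- function(...) {
  defaults <- list(field_size_px = c(160L, 160L), n_frames = 16L, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# analytic binary disk image (intensity `amp` inside radius r_um)
disk_image <- function(nx = 120, ny = 120, ctr_um = c(18, 18), r_um = 10,
                       pixel_size_um = 0.3, amp = 1) {
  outer(((1:ny) - 0.5) * pixel_size_um, ((1:nx) - 0.5) * pixel_size_um,
        function(y, x) ifelse((x - ctr_um[1])^2 + (y - ctr_um[2])^2 <= r_um^2,
                              amp, 0))
}

circle_polygon <- function(r_um = 10, n = 360, ctr = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(ctr[1] + r_um * cos(phi), ctr[2] + r_um * sin(phi))
}

ellipse_polygon <- function(a, b, n = 3600, ctr = c(0, 0), theta = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(a * cos(phi), b * sin(phi))
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(xy %*% t(R), 2, ctr, `+`)
}

# random convex polygon: convex hull of points on a random ellipse arc set
random_convex_polygon <- function(n_pts = 40) {
  a <- stats::runif(1, 5, 20); b <- stats::runif(1, 3, a)
  th <- stats::runif(1, 0, pi)
  phi <- sort(stats::runif(n_pts, 0, 2 * pi))
  xy <- cbind(a * cos(phi), b * sin(phi))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- xy %*% t(R)
  xy[grDevices::chull(xy)[length(grDevices::chull(xy)):1], , drop = FALSE]
}

# pixel-cloud moments oracle for elongation: rasterize the interior on a
# fine grid and take the eigenvalue ratio of the point-cloud covariance
elongation_pixel_oracle <- function(v, step = 0.05) {
  xr <- range(v[, 1]); yr <- range(v[, 2])
  gx <- seq(xr[1], xr[2], by = step); gy <- seq(yr[1], yr[2], by = step)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- mgcv::in.out(rbind(v, v[1, ]), pts)
  p <- pts[inside, , drop = FALSE]
  ev <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
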