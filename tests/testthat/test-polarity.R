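make_contour <- function(v, frame = 0L)
  structure(list(frame = frame, vertices = v, object_role = "cell_body"),
            class = "cell_contour")

test_that("a uniform disk yields a flat axial profile", {
  psz <- 0.3
  img <- disk_image(r_um = 10, ctr_um = c(18, 18), pixel_size_um = psz)
  ct <- make_contour(circle_polygon(9.2, 90, ctr = c(18, 18)))
  p <- axial_profile(img, ct, c(1, 0), pixel_size_um = psz)
  expect_lte((max(p) - min(p)) / mean(p), 0.02)
})

test_that("an intensity ramp along the motion axis maps linearly onto s", {
  psz <- 0.5; nx <- 100; ny <- 100
  xs <- ((1:nx) - 0.5) * psz
  img <- matrix(rep(xs, each = ny), ny, nx)  # I(x) = x, moving +x
  ct <- make_contour(circle_polygon(15, 90, ctr = c(25, 25)))
  p <- axial_profile(img, ct, c(1, 0), pixel_size_um = psz)
  s <- seq(0, 1, length.out = length(p))
  # front (s = 0) is at large x: profile decreases linearly front -> back
  expect_true(all(diff(p) < 0))
  line <- p[1] + (p[length(p)] - p[1]) * s
  expect_lt(max(abs(p - line)) / mean(p), 1e-6)
})

test_that("frames with invalid direction or tiny axes are skipped", {
  img <- disk_image()
  ct <- make_contour(circle_polygon(9, 90, ctr = c(18, 18)))
  expect_null(axial_profile(img, ct, c(NA, NA), pixel_size_um = 0.3))
  tiny <- make_contour(circle_polygon(0.4, 16, ctr = c(18, 18)))
  expect_null(axial_profile(img, tiny, c(1, 0), pixel_size_um = 0.3))
})

test_that("rear-polarized rendering yields a back-enriched profile and index", {
  cfg <- small_config(rear_polarity_strength = 3, noise_sd = 0,
                      neighbor_density = 0)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  v <- velocities(kin$track, 1)
  pr <- polarity_profiles(ren$stack, kin$contours, v)
  en <- rear_enrichment(pr$profiles)
  back <- rowMeans(pr$profiles[, 38:50])   # s in [0.75, 1]
  front <- rowMeans(pr$profiles[, 1:13])   # s in [0, 0.25]
  expect_gte(mean(back) / mean(front), 2)
  expect_gt(en$index, 1)
  # bootstrap over frames: the index is > 1 at 95% confidence
  set.seed(99)
  boot <- replicate(200, {
    i <- sample(nrow(pr$profiles), replace = TRUE)
    rear_enrichment(pr$profiles[i, , drop = FALSE])$index
  })
  expect_gt(stats::quantile(boot, 0.025), 1)
})

test_that("an unpolarized cell gives a rear-enrichment index of 1", {
  cfg <- small_config(rear_polarity_strength = 1, noise_sd = 0,
                      neighbor_density = 0, n_frames = 48L)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  v <- velocities(kin$track, 1)
  pr <- polarity_profiles(ren$stack, kin$contours, v)
  en <- rear_enrichment(pr$profiles)
  expect_equal(en$index, 1, tolerance = 0.02)
})

test_that("reversing the direction maps the index to its reciprocal", {
  cfg <- small_config(rear_polarity_strength = 3, noise_sd = 0,
                      neighbor_density = 0)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  v <- velocities(kin$track, 1)
  en <- rear_enrichment(polarity_profiles(ren$stack, kin$contours, v)$profiles)
  v_rev <- v
  v_rev$dir_x <- -v$dir_x; v_rev$dir_y <- -v$dir_y
  en_rev <- rear_enrichment(
    polarity_profiles(ren$stack, kin$contours, v_rev)$profiles)
  expect_equal(en_rev$index, 1 / en$index, tolerance = 0.02)
})

test_that("the profile is invariant under joint 90-degree rotation", {
  psz <- 0.4; n <- 120
  set.seed(7)
  img <- matrix(stats::runif(n * n), n, n)
  img <- hcmigrate:::gaussian_blur(img, 2)
  ctr <- c(24, 24)
  ct <- make_contour(circle_polygon(12, 90, ctr = ctr))
  p1 <- axial_profile(img, ct, c(1, 0), pixel_size_um = psz)
  # rotate the image by 90 deg: (x, y) -> (W - y, x); directions rotate too
  img_r <- t(img)[, n:1]
  ctr_r <- c(n * psz - ctr[2], ctr[1])
  ct_r <- make_contour(circle_polygon(12, 90, ctr = ctr_r))
  p2 <- axial_profile(img_r, ct_r, c(0, 1), pixel_size_um = psz)
  expect_equal(p2, p1, tolerance = 0.01)
})

test_that("averaging is linear and identical profiles have zero sd", {
  p <- sin(seq(0, pi, length.out = 50)) + 2
  m <- rbind(p, p, p, p)
  en <- rear_enrichment(m)
  expect_equal(en$profile$mean, unname(p))
  expect_true(all(en$profile$sd == 0))
  expect_error(rear_enrichment(m[1:2, ]), ">= 3")
})

test_that("thin z-stacks are max-projected over the central planes", {
  cfg <- small_config(n_z = 3L, noise_sd = 0, neighbor_density = 0)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  expect_true(ren$stack$has_z)
  proj <- get_frame(ren$stack, 2, "polarity", project_z = TRUE)
  central <- ren$stack$pixels[, , 2, 2, 3]
  expect_equal(proj, central)  # outer planes are dimmer copies
  v <- velocities(kin$track, 1)
  pr <- polarity_profiles(ren$stack, kin$contours, v)
  expect_gte(nrow(pr$profiles), 3)
})
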