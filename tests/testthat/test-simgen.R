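test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_frames = 1), "invalid config")
  expect_error(sim_config(kappa_low = 3, kappa_high = 1), "kappa_low")
  expect_error(sim_config(pixel_size_um = 0), "positive")
  expect_error(sim_config(rounding_frame = 99, n_frames = 10), "rounding_frame")
  expect_error(sim_config(rear_polarity_strength = 0.5), "rear_polarity")
})

test_that("identical (config, seed) gives bit-identical outputs", {
  cfg <- small_config(noise_sd = 0.02)
  k1 <- simulate_kinematics(cfg); k2 <- simulate_kinematics(cfg)
  expect_identical(k1, k2)
  r1 <- render_frames(k1, cfg); r2 <- render_frames(k2, cfg)
  expect_identical(r1$stack$pixels, r2$stack$pixels)
})

test_that("truth tables cover all frames and contour centroids sit on the track", {
  cfg <- small_config()
  kin <- simulate_kinematics(cfg)
  expect_identical(sort(kin$track$frame), 0:(cfg$n_frames - 1))
  expect_identical(sort(unique(kin$centrosome$frame)), 0:(cfg$n_frames - 1))
  expect_length(kin$contours, cfg$n_frames)
  errs <- vapply(seq_along(kin$contours), function(i) {
    ctr <- hcmigrate:::polygon_centroid(kin$contours[[i]]$vertices)
    sqrt(sum((ctr - c(kin$track$x_um[i], kin$track$y_um[i]))^2))
  }, numeric(1))
  expect_lt(max(errs), 0.5 * cfg$pixel_size_um)  # 0.5 px
})

test_that("zero mean speed with no persistence gives exactly zero displacement", {
  kin <- simulate_kinematics(small_config(mean_speed_um_min = 0,
                                          path_persistence = 0))
  expect_equal(max(abs(diff(kin$track$x_um))), 0)
  expect_equal(max(abs(diff(kin$track$y_um))), 0)
})

test_that("kappa = 0 yields protrusion angles uniform on [0, 180]", {
  cfg <- sim_config(n_frames = 400L, protrusion_rate = 6,
                    kappa_low = 0, kappa_high = 0, seed = 21L)
  kin <- simulate_kinematics(cfg)
  ang <- kin$protrusions$angle_true_deg
  expect_gt(length(ang), 2000)
  ang <- ang[seq_len(2000)]
  counts <- table(cut(ang, breaks = seq(0, 180, by = 20),
                      include.lowest = TRUE))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)  # uniformity not rejected at alpha = 0.01
})

test_that("the rounding frame contour is an exact circle", {
  cfg <- small_config(rounding_frame = 7L)
  kin <- simulate_kinematics(cfg)
  sh <- shape_descriptors(kin$contours[[8]])
  expect_equal(sh$elongation_ratio, 1, tolerance = 1e-6)
  expect_equal(sh$sphericity_pct, 100, tolerance = 0.1)
})

test_that("angular bias: high-speed tips concentrate frontward, low-speed flatter", {
  cfg <- sim_config(n_frames = 300L, protrusion_rate = 5,
                    kappa_low = 0.3, kappa_high = 8, seed = 31L)
  kin <- simulate_kinematics(cfg)
  expect_gt(nrow(kin$protrusions), 1000)
  v <- kin$speeds_um_min
  thr <- kin$speed_thresholds
  cls <- ifelse(v < thr[1], "low", ifelse(v > thr[2], "high", "mid"))
  tipcls <- cls[kin$protrusions$frame + 1L]
  edges <- seq(0, 180, by = 20)
  freq <- function(k) {
    h <- hist(kin$protrusions$angle_true_deg[tipcls == k], breaks = edges,
              plot = FALSE)$counts
    h / sum(h)
  }
  f_high <- freq("high"); f_low <- freq("low")
  expect_equal(which.max(f_high), 1L)               # mode in [0, 20)
  expect_gt(shannon_entropy(f_low), shannon_entropy(f_high))
})

test_that("rasterized contour area matches polygon area within 2%", {
  cfg <- sim_config(cell_radius_um = 9, pixel_size_um = 0.3,
                    field_size_px = c(220L, 220L), n_frames = 4L, seed = 2L)
  kin <- simulate_kinematics(cfg)
  v_px <- kin$contours[[1]]$vertices / cfg$pixel_size_um
  expect_gt(diff(range(v_px[, 1])), 50)  # >= 50 px diameter
  px <- hcmigrate:::rasterize_polygon(v_px, 220L, 220L)
  a_poly <- hcmigrate:::polygon_area(v_px)
  expect_equal(nrow(px), a_poly, tolerance = 0.02)
})

test_that("rendering honours polarity, drift and background contracts", {
  # rear_polarity_strength = 1: cortical band uniform along the axis
  # (measured mid-band on a round frame, where curvature is constant)
  cfg <- small_config(rear_polarity_strength = 1, noise_sd = 0,
                      neighbor_density = 0, rounding_frame = 3L)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  pol <- get_frame(ren$stack, 3, "polarity")
  v_px <- kin$contours[[4]]$vertices / cfg$pixel_size_um
  px <- hcmigrate:::rasterize_polygon(v_px, nrow(pol), ncol(pol))
  dd <- hcmigrate:::dist_to_polygon(cbind(px[, "col"] - 0.5,
                                          px[, "row"] - 0.5), v_px)
  band <- pol[px[dd >= 1.4 & dd <= 1.6, , drop = FALSE]]
  expect_lte(max(band) / min(band), 1.05)
  # background exactly zero with no noise and no neighbours
  cell <- get_frame(ren$stack, 3, "cell")
  nuc <- get_frame(ren$stack, 3, "nuclei")
  expect_identical(max(nuc), 0)
  expect_identical(min(cell), 0)
  # cumulative drift accumulates linearly from the reference frame
  cfg2 <- small_config(drift_per_frame_px = c(2, 0), n_frames = 10L)
  ren2 <- render_frames(simulate_kinematics(cfg2), cfg2)
  expect_equal(ren2$truth_drift$dx_px, 2 * (0:9))
  expect_equal(ren2$truth_drift$dy_px, rep(0, 10))
})

test_that("generate_dataset persists deterministically and round-trips", {
  cfg <- small_config(n_frames = 6L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ds <- read_dataset(d1)
  kin <- simulate_kinematics(cfg)
  ren <- render_frames(kin, cfg)
  expect_equal(ds$stack$pixels, ren$stack$pixels)
  expect_equal(ds$track$x_um, round(kin$track$x_um, 6))
  expect_equal(sort(unique(ds$geometry$frame)), 0:(cfg$n_frames - 1))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a minimal two-frame dataset passes the type invariants", {
  cfg <- small_config(n_frames = 2L)
  dir <- file.path(tempdir(), "ds_min")
  unlink(dir, recursive = TRUE)
  generate_dataset(cfg, dir)
  ds <- read_dataset(dir)
  expect_s3_class(ds$stack, "image_stack")
  expect_identical(hcmigrate:::n_frames(ds$stack), 2L)
  expect_identical(sort(ds$track$frame), 0:1)
  unlink(dir, recursive = TRUE)
})
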