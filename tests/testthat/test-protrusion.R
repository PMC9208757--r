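test_that("protrusion angle endpoints and orthogonal case are exact", {
  expect_equal(protrusion_angle(c(1, 0), c(0, 0), c(5, 0)), 0)
  expect_equal(protrusion_angle(c(1, 0), c(0, 0), c(-2, 0)), 180)
  expect_equal(protrusion_angle(c(1, 0), c(0, 0), c(0, 3)), 90)
  expect_error(protrusion_angle(c(1, 0), c(1, 1), c(1, 1)), "undefined angle")
  expect_error(protrusion_angle(c(2, 0), c(0, 0), c(1, 0)), "unit vector")
})

# a deterministic toy scene: cell moving +x at varied speed, tips placed by hand
toy_scene <- function(speeds = c(1, 2, 3, 4, 5, 6, 7, 8),
                      tip_offsets = NULL) {
  n <- length(speeds) + 1
  x <- cumsum(c(0, speeds))
  cell <- point_tracks(rep("c", n), 0:(n - 1), x, rep(0, n))
  if (is.null(tip_offsets))
    tip_offsets <- lapply(seq_len(n - 1), function(i) c(10, 0))
  rows <- do.call(rbind, lapply(seq_along(tip_offsets), function(i)
    data.frame(id = paste0("p", i), frame = i - 1L,
               x = x[i] + tip_offsets[[i]][1], y = tip_offsets[[i]][2])))
  tips <- point_tracks(rows$id, rows$frame, rows$x, rows$y,
                       role = "protrusion_tip")
  v <- velocities(cell, 1)
  list(cell = cell, tips = tips, vel = v, thr = speed_thresholds(v))
}

test_that("tips parallel to motion land entirely in the first bin", {
  sc <- toy_scene()
  an <- angle_histograms(sc$cell, sc$tips, sc$vel, sc$thr)
  h <- an$histograms$all
  expect_equal(h$frequency[1], 1)
  expect_true(all(h$frequency[-1] == 0))
  expect_identical(h$bin_lo[1], 0); expect_identical(h$bin_hi[1], 20)
})

test_that("every non-empty histogram sums to 1 and strata partition the samples", {
  cfg <- small_config(n_frames = 40L, protrusion_rate = 3)
  kin <- simulate_kinematics(cfg)
  v <- velocities(kin$track, 1)
  thr <- speed_thresholds(v)
  an <- angle_histograms(kin$track, kin$protrusions, v, thr)
  for (h in an$histograms)
    if (h$n_samples > 0) expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
  cls <- an$samples$speed_class
  expect_true(all(cls %in% c("low", "mid", "high")))  # exhaustive
  n_all <- an$histograms$all$n_samples
  expect_identical(sum(cls == "low") + sum(cls == "mid") + sum(cls == "high"),
                   n_all)                              # disjoint
  # low + mid + high counts reproduce the all-condition histogram exactly
  edges <- seq(0, 180, 20)
  recount <- tabulate(findInterval(an$samples$angle_deg, edges,
                                   rightmost.closed = TRUE), 9L)
  expect_identical(recount, an$histograms$all$count)
})

test_that("rotating the whole scene leaves every angle sample unchanged", {
  sc <- toy_scene(tip_offsets = list(c(3, 1), c(-2, 2), c(0, 4), c(1, -5),
                                     c(6, 0), c(2, 2), c(-1, -1), c(4, 3)))
  base <- angle_histograms(sc$cell, sc$tips, sc$vel, sc$thr)$samples
  th <- 1.1
  R <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                           y = sin(th) * x + cos(th) * y)
  rc <- R(sc$cell$x_um, sc$cell$y_um)
  rt <- R(sc$tips$x_um, sc$tips$y_um)
  cell_r <- point_tracks(sc$cell$track_id, sc$cell$frame, rc$x, rc$y)
  tips_r <- point_tracks(sc$tips$track_id, sc$tips$frame, rt$x, rt$y,
                         role = "protrusion_tip")
  v_r <- velocities(cell_r, 1)
  rot <- angle_histograms(cell_r, tips_r, v_r, speed_thresholds(v_r))$samples
  expect_equal(rot$angle_deg[order(rot$protrusion_id)],
               base$angle_deg[order(base$protrusion_id)], tolerance = 1e-9)
})

test_that("samples at invalid-velocity frames are dropped and counted", {
  cell <- point_tracks(rep("c", 4), 0:3, c(0, 1, 1, 2), c(0, 0, 0, 0))
  tips <- point_tracks(c("p1", "p2", "p3"), c(0L, 1L, 2L),
                       c(5, 5, 5), c(0, 0, 0), role = "protrusion_tip")
  v <- velocities(cell, 1)   # frame 1 has zero displacement -> invalid
  cellv <- point_tracks(rep("c", 9), 0:8, cumsum(c(0, 1:8)), rep(0, 9))
  vv <- velocities(cellv, 1)
  thr <- speed_thresholds(vv)
  an <- angle_histograms(cell, tips, v, thr)
  expect_identical(an$n_dropped_invalid, 1L)
  expect_identical(nrow(an$samples), 2L)
})

test_that("an empty speed condition is flagged, not fabricated", {
  sc <- toy_scene(speeds = rep(2, 8))  # constant speed: all samples mid
  an <- angle_histograms(sc$cell, sc$tips, sc$vel, sc$thr)
  expect_identical(an$histograms$low$n_samples, 0L)
  expect_identical(an$histograms$low$flag, "empty_condition")
  expect_true(all(is.na(an$histograms$low$frequency)))
  expect_identical(an$histograms$all$n_samples, 8L)
})

test_that("a flat generator produces a uniform low-speed histogram", {
  cfg <- sim_config(n_frames = 700L, protrusion_rate = 6, kappa_low = 0,
                    kappa_high = 0, seed = 23L, field_size_px = c(300L, 300L))
  kin <- simulate_kinematics(cfg)
  v <- velocities(kin$track, 1)
  thr <- speed_thresholds(v)
  an <- angle_histograms(kin$track, kin$protrusions, v, thr)
  h <- an$histograms$low
  expect_gte(h$n_samples, 500)
  p0 <- 1 / 9
  sigma <- sqrt(p0 * (1 - p0) / h$n_samples)
  expect_lte(max(abs(h$frequency - p0)), 3.3 * sigma)
})

test_that("generator bias is recovered: front bin dominates at high speed", {
  cfg <- sim_config(n_frames = 300L, protrusion_rate = 5, kappa_low = 0.3,
                    kappa_high = 8, seed = 31L)
  kin <- simulate_kinematics(cfg)
  v <- velocities(kin$track, 1)
  thr <- speed_thresholds(v)
  an <- angle_histograms(kin$track, kin$protrusions, v, thr)
  hi <- an$histograms$high; lo <- an$histograms$low
  expect_gt(an$histograms$all$n_samples, 1000)
  expect_identical(which.max(hi$frequency), 1L)
  expect_gt(hi$frequency[1], lo$frequency[1])
})
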