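test_that("velocities are exact finite differences with unit directions", {
  tr <- point_tracks(c("a", "a"), 0:1, c(0, 3), c(0, 4))
  v <- velocities(tr, interval_min = 5)
  expect_equal(v$speed_um_min, 1)
  expect_equal(c(v$dir_x, v$dir_y), c(0.6, 0.8))
  expect_true(v$valid)
})

test_that("stationary tracks are flagged invalid; gaps split the sequence", {
  tr <- point_tracks(rep("a", 5), 0:4, rep(1, 5), rep(2, 5))
  v <- velocities(tr, 1)
  expect_false(any(v$valid))
  trg <- point_tracks(rep("a", 4), c(0, 1, 5, 6), c(0, 1, 9, 10), rep(0, 4))
  vg <- velocities(trg, 1)
  expect_identical(vg$frame, c(0L, 5L))  # nothing spans the 1 -> 5 gap
})

test_that("speed percentiles follow linear order-statistic interpolation", {
  tr <- point_tracks(rep("a", 9), 0:8, cumsum(c(0, 1:8)), rep(0, 9))
  v <- velocities(tr, 1)
  expect_equal(v$speed_um_min, 1:8)
  thr <- speed_thresholds(v)
  expect_equal(thr$p25_um_min, 2.75)
  expect_equal(thr$p75_um_min, 6.25)
  expect_identical(thr$classes$class[thr$classes$speed_um_min %in% c(1, 2)],
                   rep("low", 2))
  expect_identical(thr$classes$class[thr$classes$speed_um_min %in% c(7, 8)],
                   rep("high", 2))
  # all-equal speeds: p25 = p75 and everything is mid
  tre <- point_tracks(rep("a", 6), 0:5, (0:5) * 2, rep(0, 6))
  thr2 <- speed_thresholds(velocities(tre, 1))
  expect_equal(thr2$p25_um_min, thr2$p75_um_min)
  expect_true(all(thr2$classes$class == "mid"))
  expect_error(speed_thresholds(velocities(tr[1:3, ], 1)), ">= 4 valid")
})

test_that("stratification is invariant to track reversal and rigid motion", {
  cfg <- small_config()
  kin <- simulate_kinematics(cfg)
  v <- velocities(kin$track, 1)
  thr <- speed_thresholds(v)
  rev_tr <- kin$track
  rev_tr$frame <- max(rev_tr$frame) - rev_tr$frame
  rev_tr <- point_tracks(rev_tr$track_id, rev_tr$frame, rev_tr$x_um,
                         rev_tr$y_um)
  thr_rev <- speed_thresholds(velocities(rev_tr, 1))
  expect_equal(thr_rev$p25_um_min, thr$p25_um_min)
  expect_equal(thr_rev$p75_um_min, thr$p75_um_min)
  th <- 0.83
  rot <- point_tracks(kin$track$track_id, kin$track$frame,
                      cos(th) * kin$track$x_um - sin(th) * kin$track$y_um + 40,
                      sin(th) * kin$track$x_um + cos(th) * kin$track$y_um - 9)
  thr_rot <- speed_thresholds(velocities(rot, 1))
  expect_equal(thr_rot$p25_um_min, thr$p25_um_min)
  expect_equal(thr_rot$p75_um_min, thr$p75_um_min)
})

test_that("about 25% of samples fall in the low stratum for continuous speeds", {
  cfg <- sim_config(n_frames = 1001L, seed = 17L,
                    field_size_px = c(400L, 400L))
  kin <- simulate_kinematics(cfg)
  thr <- speed_thresholds(velocities(kin$track, 1))
  expect_equal(mean(thr$classes$class == "low"), 0.25, tolerance = 0.02 / 0.25)
})

test_that("depth relative to a layer honours the sign convention", {
  g <- tissue_geometry(frame = rep(0:4, each = 3),
                       layer = rep(c("apical_surface", "OPL", "IPL"), 5),
                       y_um = rep(c(10, 40, 70), 5))
  tr <- point_tracks(rep("a", 5), 0:4, rep(5, 5), c(50, 45, 40, 35, 30))
  d <- depth_relative_to_layer(tr, g, "OPL")
  expect_equal(d$depth_um, c(10, 5, 0, -5, -10))  # positive = basal (+y)
  expect_equal(attr(d, "final_depth_um"), -10)
  expect_equal(attr(d, "max_basal_depth_um"), 10)
  # sign change exactly at the crossing frame
  expect_identical(d$frame[d$depth_um == 0], 2L)
  # inverted basal convention flips the series
  g2 <- tissue_geometry(frame = rep(0:4, each = 3),
                        layer = rep(c("apical_surface", "OPL", "IPL"), 5),
                        y_um = rep(c(70, 40, 10), 5), basal_sign = -1)
  d2 <- depth_relative_to_layer(tr, g2, "OPL")
  expect_equal(d2$depth_um, -d$depth_um)
})

test_that("depth series is invariant under joint translation of track and geometry", {
  cfg <- small_config()
  kin <- simulate_kinematics(cfg)
  d <- depth_relative_to_layer(kin$track, kin$geometry, "OPL")
  tr2 <- point_tracks(kin$track$track_id, kin$track$frame,
                      kin$track$x_um + 11, kin$track$y_um + 3.5)
  g2 <- kin$geometry
  g2$y_um <- g2$y_um + 3.5
  d2 <- depth_relative_to_layer(tr2, g2, "OPL")
  expect_equal(d2$depth_um, d$depth_um)
})

test_that("polyline layers give the same depth as their constant-y equivalent", {
  poly <- data.frame(frame = rep(0L, 2), x_um = c(0, 100), y_um = c(40, 40))
  tr <- point_tracks("a", 0L, 30, 55)
  d <- depth_relative_to_layer(tr, poly)
  expect_equal(d$depth_um, 15)
})

test_that("centrosome offset distances and front/back labels are correct", {
  cell <- point_tracks("c", 0L, 0, 0)
  cen <- point_tracks("k", 0L, 3, 4, role = "centrosome")
  off <- centrosome_offset(cell, cen)
  expect_equal(off$distance_um, 5)
  expect_identical(off$side, "undefined")  # no velocity supplied
  # coincident tracks: zero distance, undefined side
  off0 <- centrosome_offset(cell, point_tracks("k", 0L, 0, 0,
                                               role = "centrosome"))
  expect_equal(off0$distance_um, 0)
  expect_identical(off0$side, "undefined")
  expect_error(centrosome_offset(cell, point_tracks("k", 5L, 1, 1,
                                                    role = "centrosome")),
               "share no frames")
  # simulated alternating fore/aft placement is recovered from the labels
  cfg <- sim_config(n_frames = 200L, seed = 19L,
                    centrosome_pattern = "alternate")
  kin <- simulate_kinematics(cfg)
  v <- velocities(kin$track, 1)
  off2 <- centrosome_offset(kin$track, kin$centrosome, v)
  truth <- kin$centrosome$side_true[match(off2$frame, kin$centrosome$frame)]
  defined <- off2$side != "undefined"
  expect_gte(mean(off2$side[defined] == truth[defined]), 0.99)
  expect_equal(off2$distance_um[defined],
               rep(cfg$centrosome_offset_um, sum(defined)))
})

test_that("path length dominates net displacement for every simulated track", {
  for (s in 1:5) {
    kin <- simulate_kinematics(small_config(seed = s))
    ts <- track_summary(kin$track, 1)
    expect_gte(ts$total_path_um, ts$net_displacement_um - 1e-12)
  }
  # equality for collinear monotone motion
  tr <- point_tracks(rep("a", 4), 0:3, c(0, 1, 2, 3), rep(0, 4))
  ts <- track_summary(tr, 1)
  expect_equal(ts$total_path_um, ts$net_displacement_um)
})
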