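test_that("trajectory simulation is seed-deterministic with the stated shape", {
  cfg <- scene_config(n_fish = 3, n_frames = 15, seed = 4)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1$pos, t2$pos)
  expect_equal(dim(t1$pos), c(3, 15, 3))
  expect_true(all(is.finite(t1$pos)))
  # positions stay in the volume
  expect_true(all(t1$pos[, , 3] >= cfg$volume$zlim[1] &
                  t1$pos[, , 3] <= cfg$volume$zlim[2]))
  # per-frame displacement bounded by 3 * speed_mean / fps
  step <- sqrt(apply((t1$pos[, -1, , drop = FALSE] -
                      t1$pos[, -15, , drop = FALSE])^2, c(1, 2), sum))
  expect_true(all(step <= 3 * cfg$speed_mean / cfg$fps + 1e-12))
})

test_that("zero speed freezes the fish", {
  cfg <- scene_config(n_fish = 2, n_frames = 10, speed_mean = 0, speed_sd = 0,
                      seed = 9)
  tr <- simulate_trajectories(cfg)
  expect_equal(tr$pos[, 1, ], tr$pos[, 10, ])
})

test_that("rendered disparities follow the stereo geometry", {
  cfg <- noiseless_config(n_fish = 3, n_frames = 20, seed = 31)
  sc <- render_observations(simulate_trajectories(cfg))
  m <- sc$matches
  # every noiseless match pair triangulates back to a true fish depth
  tr <- triangulate(cfg$calib, m$xl, m$yl, m$xr)
  zerr <- vapply(seq_len(nrow(m)), function(k) {
    min(abs(sc$truth$pos[, m$frame[k] + 1, 3] - tr$Z[k]))
  }, numeric(1))
  expect_lt(max(zerr), 1e-9)
  # empirical disparity equals b * fx / (1000 * Z)
  d <- m$xl - m$xr
  znear <- vapply(seq_len(nrow(m)), function(k) {
    zs <- sc$truth$pos[, m$frame[k] + 1, 3]
    zs[which.min(abs(zs - tr$Z[k]))]
  }, numeric(1))
  expect_equal(d, cfg$calib$baseline_mm * cfg$calib$fx / (1000 * znear),
               tolerance = 1e-9)
})

test_that("projected box size scales inversely with depth", {
  pin <- function(z) {
    eps <- 1e-4
    cfg <- noiseless_config(
      n_fish = 1, n_frames = 1, seed = 2, speed_mean = 0, speed_sd = 0,
      volume = list(xlim = c(-eps, eps), ylim = c(-eps, eps),
                    zlim = c(z - eps, z + eps)))
    render_observations(simulate_trajectories(cfg))
  }
  sc1 <- pin(1.5); sc2 <- pin(3.0)
  w1 <- sc1$detections$w[sc1$detections$side == "left"]
  w2 <- sc2$detections$w[sc2$detections$side == "left"]
  expect_equal(w1 / w2, 2, tolerance = 1e-3)
})

test_that("detection rate approximates 1 - dropout_p", {
  cfg <- scene_config(n_fish = 1, n_frames = 400, dropout_p = 0.3,
                      pixel_noise_sd = 0, speed_mean = 0, speed_sd = 0,
                      volume = list(xlim = c(-0.1, 0.1), ylim = c(-0.1, 0.1),
                                    zlim = c(1.9, 2.1)),
                      seed = 17)
  sc <- render_observations(simulate_trajectories(cfg))
  n_vis <- sum(sc$truth$vis_left)
  expect_equal(n_vis, 400)  # central fish is always fully in view
  k <- sum(sc$detections$side == "left")
  ci <- stats::binom.test(k, n_vis)$conf.int
  expect_true(ci[1] <= 1 - cfg$dropout_p && 1 - cfg$dropout_p <= ci[2])
})

test_that("dropout of one side starves stereo but not mono", {
  cfg <- noiseless_config(n_fish = 2, n_frames = 10, seed = 23)
  cfg$dropout_p <- 0  # left side untouched below
  sc <- render_observations(simulate_trajectories(cfg))
  sc$detections <- sc$detections[sc$detections$side == "left", ]
  expect_equal(nrow(run_segmentdepth(sc)), 0)
  expect_equal(nrow(run_bboxdepth(sc)), 0)
  expect_gt(nrow(run_mono(sc)), 0)
})

test_that("oracle depth raster is a z-buffer over the background", {
  eps <- 1e-4
  cfg <- noiseless_config(
    n_fish = 1, n_frames = 1, seed = 3, speed_mean = 0, speed_sd = 0,
    volume = list(xlim = c(-eps, eps), ylim = c(-eps, eps),
                  zlim = c(2 - eps, 2 + eps)))
  sc <- render_observations(simulate_trajectories(cfg))
  Zmap <- sc$depth_map(0)
  expect_equal(dim(Zmap), c(cfg$calib$height, cfg$calib$width))
  z <- sc$truth$pos[1, 1, 3]
  ctr <- project_stereo(cfg$calib, sc$truth$pos[1, 1, 1],
                        sc$truth$pos[1, 1, 2], z)$left
  expect_equal(Zmap[round(ctr$v) + 1, round(ctr$u) + 1], z)
  expect_equal(Zmap[1, 1], cfg$background_depth_m)
})
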