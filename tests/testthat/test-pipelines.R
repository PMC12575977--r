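test_that("noiseless scenes: stereo pipelines agree with truth and each other", {
  cfg <- noiseless_config(n_fish = 2, n_frames = 30, seed = 7)
  tru <- simulate_trajectories(cfg)
  sc <- render_observations(tru)
  rs <- run_segmentdepth(sc)
  rb <- run_bboxdepth(sc)
  rg <- run_superglue(sc)
  for (r in list(rs, rb, rg)) {
    expect_gt(nrow(r), 0)
    expect_lt(max(nearest_truth_error(r, tru)), 1e-6)
    # one record schema for all pipelines
    expect_named(as.data.frame(r), c("frame", "track_id", "X", "Y", "Z",
                                     "distance_m", "pipeline"))
    expect_equal(r$distance_m, sqrt(r$X^2 + r$Y^2 + r$Z^2))
  }
  # mask- and box-based variants coincide on a noiseless, uncrowded scene
  vb <- run_segmentdepth(sc, match_on = "bbox")
  expect_equal(as.data.frame(rs), as.data.frame(vb), tolerance = 1e-9)
})

test_that("mono pipeline reads the raster verbatim", {
  cfg <- noiseless_config(n_fish = 2, n_frames = 10, seed = 19)
  sc <- render_observations(simulate_trajectories(cfg))
  # constant raster: every record carries exactly that depth
  const_map <- function(frame) matrix(2.5, cfg$calib$height, cfg$calib$width)
  rm_ <- run_mono(sc, depth_map = const_map)
  expect_true(all(rm_$Z == 2.5))
  # oracle z-buffer: depth exact at fin pixels
  rz <- run_mono(sc)
  expect_gt(nrow(rz), 0)
  expect_lt(max(nearest_truth_z_error(rz, sc$truth)), 1e-12)
})

test_that("confidence threshold and record-count orderings hold", {
  cfg <- noiseless_config(n_fish = 2, n_frames = 15, seed = 29)
  sc <- render_observations(simulate_trajectories(cfg))
  # all match confidences below the threshold: zero records
  sc2 <- sc
  sc2$matches$conf <- 0.05
  r0 <- run_superglue(sc2)
  expect_equal(nrow(r0), 0)
  expect_gt(run_summary(r0)$rejections[["no_match"]], 0)
  # mono needs one view only: at least as many records as any stereo pipeline
  counts <- c(seg = nrow(run_segmentdepth(sc)), box = nrow(run_bboxdepth(sc)),
              sg = nrow(run_superglue(sc)), mono = nrow(run_mono(sc)))
  expect_true(all(counts["mono"] >= counts[c("seg", "box", "sg")]))
  # record count never exceeds tracked-box count
  left <- sc$detections[sc$detections$side == "left", ]
  expect_true(all(counts <= nrow(left)))
})

test_that("box-center invariance: inflating right boxes changes nothing", {
  cfg <- noiseless_config(n_fish = 2, n_frames = 10, seed = 37)
  sc <- render_observations(simulate_trajectories(cfg))
  r1 <- run_bboxdepth(sc)
  sc2 <- sc
  idx <- sc2$detections$side == "right"
  d <- sc2$detections[idx, ]
  sc2$detections[idx, c("x", "y", "w", "h")] <-
    cbind(d$x - 0.1 * d$w, d$y - 0.1 * d$h, 1.2 * d$w, 1.2 * d$h)
  r2 <- run_bboxdepth(sc2)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-9)
})

test_that("stereo depth error grows with pixel noise (scaled-down check)", {
  # scaled-down version of the acceptance property (fewer seeds and frames)
  sigmas <- c(0, 1, 2)
  med <- sapply(sigmas, function(s) {
    errs <- list(seg = c(), box = c(), sg = c())
    for (seed in 1:4) {
      cfg <- scene_config(n_fish = 2, n_frames = 40, pixel_noise_sd = s,
                          match_jitter_sd = s, dropout_p = 0,
                          n_clutter_matches = 0, conf_beta = c(60, 2),
                          seed = 100 + seed)
      tru <- simulate_trajectories(cfg)
      sc <- render_observations(tru)
      errs$seg <- c(errs$seg, nearest_truth_z_error(run_segmentdepth(sc), tru))
      errs$box <- c(errs$box, nearest_truth_z_error(run_bboxdepth(sc), tru))
      errs$sg <- c(errs$sg, nearest_truth_z_error(run_superglue(sc), tru))
    }
    vapply(errs, stats::median, numeric(1))
  })
  for (p in 1:3) expect_false(is.unsorted(med[p, ]))
})

test_that("rejection accounting separates disparity failures", {
  # hand-built scene: identical boxes in both views -> zero disparity
  det <- rbind(
    data.frame(frame = 0:4, side = "left", x = 100, y = 100, w = 40, h = 30,
               conf = 0.9, truth_id = 1L, det = 1L),
    data.frame(frame = 0:4, side = "right", x = 100, y = 100, w = 40, h = 30,
               conf = 0.9, truth_id = 1L, det = 1L))
  sc <- structure(list(cfg = noiseless_config(), detections = det,
                       masks = list(), matches = NULL, depth_map = NULL),
                  class = "fin_scene")
  r <- run_bboxdepth(sc)
  expect_equal(nrow(r), 0)
  expect_equal(unname(run_summary(r)$rejections[["disparity"]]), 5)
})
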