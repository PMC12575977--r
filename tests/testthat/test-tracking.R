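test_that("box IOU matches hand-evaluated cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  # inter 1, union 4 + 4 - 1 = 7
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)),
               iou(c(1, 1, 2, 2), c(0, 0, 2, 2)))
  expect_error(iou(c(0, 0, 0, 2), c(1, 1, 2, 2)), "degenerate")
})

test_that("a stable box yields one track; disjoint boxes keep distinct IDs", {
  d <- det_stream(0:9, x = 100)
  tr <- track_sequence(d)
  expect_length(tr$tracks, 1)
  expect_equal(nrow(tr$tracks[[1]]$history), 10)

  d2 <- rbind(det_stream(0:9, x = 100), det_stream(0:9, x = 900))
  tr2 <- track_sequence(d2)
  expect_length(tr2$tracks, 2)
  # IDs frame-stable: each input x position maps to exactly one track id
  a <- merge(tr2$assignments, cbind(row = seq_len(nrow(d2)), d2), by = "row")
  expect_equal(length(unique(a$track_id[a$x == 100])), 1)
  expect_equal(length(unique(a$track_id[a$x == 900])), 1)
})

test_that("a gap longer than the track buffer splits the track", {
  buf <- 5
  d <- det_stream(c(0:4, (5 + buf + 1):(5 + buf + 5)), x = 100)
  tr <- track_sequence(d, tracker_params(track_buffer = buf))
  expect_length(tr$tracks, 2)
  expect_equal(sort(unique(tr$assignments$track_id)), c(1L, 2L))
  # within the buffer the track survives the gap
  d2 <- det_stream(c(0:4, (5 + buf - 1):(5 + buf + 3)), x = 100)
  tr2 <- track_sequence(d2, tracker_params(track_buffer = buf))
  expect_length(tr2$tracks, 1)
})

test_that("low-confidence detections rescue active tracks but never spawn", {
  d <- det_stream(0:5, x = 100)
  d$conf[3] <- 0.3  # below conf_high, above conf_low, same position
  tr <- track_sequence(d)
  expect_length(tr$tracks, 1)
  expect_equal(nrow(tr$tracks[[1]]$history), 6)
  # a lone low-confidence detection creates nothing
  tr2 <- track_sequence(det_stream(0, x = 100, conf = 0.3))
  expect_length(tr2$tracks, 0)
})

test_that("per-frame assignment is one-to-one and order-invariant", {
  set.seed(5)
  # two jittering fish plus occasional clutter
  frames <- 0:19
  d <- rbind(
    det_stream(frames, x = 100 + cumsum(rnorm(20, 0, 2))),
    det_stream(frames, x = 400 + cumsum(rnorm(20, 0, 2))),
    det_stream(sample(frames, 6), x = runif(6, 700, 1500), conf = 0.6))
  tr <- track_sequence(d)
  # no detection in two tracks, no track with two detections per frame
  expect_false(any(duplicated(tr$assignments$row)))
  key <- paste(tr$assignments$frame, tr$assignments$track_id)
  expect_false(any(duplicated(key)))
  # permuting within-frame detection order leaves the output invariant
  perm <- order(d$frame, runif(nrow(d)))
  tr_p <- track_sequence(d[perm, , drop = FALSE])
  a1 <- tr$assignments[order(tr$assignments$frame, tr$assignments$track_id), ]
  a2 <- tr_p$assignments[order(tr_p$assignments$frame, tr_p$assignments$track_id), ]
  # compare by (frame, track_id, box) since row indices refer to the input
  b1 <- cbind(a1$frame, a1$track_id, d$x[a1$row])
  b2 <- cbind(a2$frame, a2$track_id, d[perm, ]$x[a2$row])
  expect_equal(b1, b2)
})

test_that("tracker recovers simulated tracks exactly without dropout", {
  cfg <- noiseless_config(n_fish = 3, n_frames = 40, seed = 21)
  sc <- render_observations(simulate_trajectories(cfg))
  left <- sc$detections[sc$detections$side == "left", ]
  tr <- track_sequence(left)
  # visible fish counts per frame equal assigned detections per frame
  expect_equal(nrow(tr$assignments), nrow(left))
  # each truth fish maps to exactly one recovered track and the recovered
  # frame set equals the ground-truth visibility set
  a <- tr$assignments
  a$truth_id <- left$truth_id[a$row]
  for (i in unique(a$truth_id)) {
    ids <- unique(a$track_id[a$truth_id == i])
    expect_length(ids, 1)
    got <- sort(a$frame[a$truth_id == i])
    want <- which(sc$truth$vis_left[i, ]) - 1L
    expect_equal(got, want)
  }
})

test_that("empty input gives empty output", {
  tr <- track_sequence(det_stream(integer(0), x = numeric(0)))
  expect_length(tr$tracks, 0)
  expect_equal(nrow(tr$assignments), 0)
})
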