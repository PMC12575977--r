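test_that("mask centroids average member pixel coordinates", {
  expect_equal(mask_centroid(mask_region(5, 7)), c(u = 5, v = 7))
  m <- mask_region(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 2x2 block at origin
  expect_equal(mask_centroid(m), c(u = 0.5, v = 0.5))
  L <- mask_region(c(0, 0, 1), c(0, 1, 0))
  expect_equal(mask_centroid(L), c(u = 1 / 3, v = 1 / 3))
  expect_error(mask_region(numeric(0), numeric(0)), "non-empty")
})

test_that("IOU cost matrices cover mask and bbox modes", {
  a <- mask_region(c(0, 1), c(0, 0), frame = 3)
  b <- mask_region(c(0, 1), c(0, 0), frame = 3)
  expect_equal(iou_cost_matrix(list(a), list(b), mode = "mask"),
               matrix(0))
  dis <- mask_region(c(10, 11), c(9, 9), frame = 3)
  expect_equal(iou_cost_matrix(list(a), list(dis), mode = "mask"),
               matrix(1))
  expect_equal(
    iou_cost_matrix(matrix(c(0, 0, 2, 2), 1), matrix(c(1, 1, 2, 2), 1),
                    mode = "bbox"),
    matrix(6 / 7))
  other <- mask_region(0, 0, frame = 4)
  expect_error(iou_cost_matrix(list(a), list(other), mode = "mask"), "mixed")
  # transpose symmetry
  set.seed(3)
  A <- matrix(runif(12, 0, 50), 3); A[, 3:4] <- A[, 3:4] + 1
  B <- matrix(runif(8, 0, 50), 2); B[, 3:4] <- B[, 3:4] + 1
  expect_equal(iou_cost_matrix(A, B, mode = "bbox"),
               t(iou_cost_matrix(B, A, mode = "bbox")))
})

test_that("gated assignment follows the Hungarian optimum", {
  p <- assign_stereo(matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE))
  expect_equal(p$left, c(1L, 2L))
  expect_equal(p$right, c(1L, 2L))
  expect_equal(sum(1 - p$iou), 0.2)
  # identity-like cost picks the diagonal
  cm <- matrix(1, 3, 3); diag(cm) <- 0
  expect_equal(assign_stereo(cm)$right, 1:3)
  # below-gate pairs are dropped after assignment
  expect_equal(nrow(assign_stereo(matrix(0.95), min_iou = 0.1)), 0)
  expect_equal(nrow(assign_stereo(matrix(numeric(0), 0, 0))), 0)
})

test_that("Hungarian solution equals the exhaustive permutation minimum", {
  set.seed(99)
  for (rep in 1:120) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    m <- matrix(runif(nr * nc), nr, nc)
    a <- solve_assignment(m)
    expect_equal(assignment_cost(m, a), brute_min_cost(m), tolerance = 1e-12)
    expect_equal(sum(!is.na(a)), min(nr, nc))
    expect_false(any(duplicated(a[!is.na(a)])))
  }
  expect_error(solve_assignment(matrix(c(1, Inf), 1)), "finite")
})

test_that("match filtering applies the confidence and inside-box rules", {
  boxes <- data.frame(x = c(0, 100), y = c(0, 100), w = c(50, 50), h = c(50, 50))
  m <- data.frame(
    xl = c(10, 10, 300, 0, 120), yl = c(10, 10, 300, 0, 120),
    xr = 1:5, yr = 1:5,
    conf = c(0.05, 0.8, 0.8, 0.8, 0.2))
  f <- filter_matches(m, boxes)
  # row 1 fails confidence, row 3 is outside every box,
  # row 4 sits exactly on a corner (boundary counts as inside)
  expect_equal(f$xr, c(2, 4, 5))
  expect_equal(f$box, c(1L, 1L, 2L))
  # threshold is strict: conf == conf_min is discarded
  expect_equal(nrow(filter_matches(
    data.frame(xl = 1, yl = 1, xr = 0, yr = 1, conf = 0.1), boxes)), 0)
})

test_that("right-point estimation follows the offset-vector construction", {
  g <- data.frame(xl = 90, yl = 45, xr = 60, yr = 45)
  expect_equal(estimate_right_point(c(100, 50), g), c(u = 70, v = 50))
  # zero offset: result is the mean right position
  g2 <- data.frame(xl = c(95, 105), yl = c(45, 55), xr = c(65, 75),
                   yr = c(45, 55))
  expect_equal(estimate_right_point(c(100, 50), g2), c(u = 70, v = 50))
  # single match at the centre passes its right point through
  g3 <- data.frame(xl = 100, yl = 50, xr = 80, yr = 50)
  expect_equal(estimate_right_point(c(100, 50), g3), c(u = 80, v = 50))
  expect_error(estimate_right_point(c(0, 0), g3[0, ]), "no matches")
})

test_that("right-point estimation is translation-equivariant", {
  set.seed(8)
  for (rep in 1:20) {
    g <- data.frame(xl = runif(5, 0, 100), yl = runif(5, 0, 100),
                    xr = runif(5, 0, 100), yr = runif(5, 0, 100))
    ctr <- runif(2, 0, 100)
    ab <- runif(2, -50, 50)
    base <- estimate_right_point(ctr, g)
    shifted <- estimate_right_point(
      ctr + ab,
      data.frame(xl = g$xl + ab[1], yl = g$yl + ab[2],
                 xr = g$xr + ab[1], yr = g$yr + ab[2]))
    expect_equal(shifted, base + ab)
  }
})

test_that("noiseless stereo pairs match ground-truth identities", {
  cfg <- noiseless_config(n_fish = 3, n_frames = 30, seed = 13)
  sc <- render_observations(simulate_trajectories(cfg))
  calib <- cfg$calib
  det <- sc$detections
  for (f in unique(det$frame)) {
    lb <- det[det$frame == f & det$side == "left", ]
    rb <- det[det$frame == f & det$side == "right", ]
    if (!nrow(lb) || !nrow(rb)) next
    ml <- sc$masks[[paste0(f, ":left")]][lb$det]
    mr <- sc$masks[[paste0(f, ":right")]][rb$det]
    # disparity < fin width for every co-visible fish => masks overlap
    pairs <- assign_stereo(iou_cost_matrix(ml, mr, mode = "mask"))
    got <- cbind(lb$truth_id[pairs$left], rb$truth_id[pairs$right])
    co_visible <- intersect(lb$truth_id, rb$truth_id)
    expect_equal(nrow(got), length(co_visible))
    expect_true(all(got[, 1] == got[, 2]))
  }
})
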