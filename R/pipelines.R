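# The four distance-estimation pipelines. All share the same front end (left
# stream tracked with the two-stage IOU tracker) and emit one record schema,
# so downstream evaluation is pipeline-agnostic. Streams are hardware-
# synchronised: identical frame indices are paired. Track IDs always come from
# the LEFT tracker; right-side detections stay anonymous.
#
# Every dropped candidate is accounted for with a reason code
# (no_match, disparity, range, bounds, empty_mask, nonfinite_depth) in the run
# summary.

# Track the left stream and return left detections with a track_id column.
tracked_left_detections <- function(scene, params) {
  left <- scene$detections[scene$detections$side == "left", , drop = FALSE]
  trk <- track_sequence(left, params)
  left$track_id <- NA_integer_
  if (nrow(trk$assignments)) {
    # assignments$row indexes rows of `left` as passed to track_sequence
    left$track_id[trk$assignments$row] <- trk$assignments$track_id
  }
  left
}

new_record_collector <- function(pipeline) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$rejections <- c(no_match = 0L, disparity = 0L, range = 0L,
                      bounds = 0L, empty_mask = 0L, nonfinite_depth = 0L)
  env$epipolar_warn <- 0L
  env$pipeline <- pipeline
  env
}

collect_point <- function(col, frame, track_id, tri) {
  if (tri$status == "ok") {
    col$rows[[length(col$rows) + 1L]] <-
      c(frame, track_id, tri$X, tri$Y, tri$Z)
  } else if (tri$status == "degenerate_disparity") {
    col$rejections[["disparity"]] <- col$rejections[["disparity"]] + 1L
  } else if (tri$status == "out_of_range") {
    col$rejections[["range"]] <- col$rejections[["range"]] + 1L
  } else {
    col$rejections[["nonfinite_depth"]] <- col$rejections[["nonfinite_depth"]] + 1L
  }
}

finish_records <- function(col) {
  rec <- if (length(col$rows)) {
    m <- do.call(rbind, col$rows)
    data.frame(frame = as.integer(m[, 1]), track_id = as.integer(m[, 2]),
               X = m[, 3], Y = m[, 4], Z = m[, 5],
               distance_m = sqrt(m[, 3]^2 + m[, 4]^2 + m[, 5]^2))
  } else
    data.frame(frame = integer(0), track_id = integer(0), X = numeric(0),
               Y = numeric(0), Z = numeric(0), distance_m = numeric(0))
  rec$pipeline <- rep(col$pipeline, nrow(rec))
  structure(rec, class = c("fin_trajectories", "data.frame"),
            summary = list(pipeline = col$pipeline,
                           n_records = nrow(rec),
                           rejections = col$rejections,
                           epipolar_warnings = col$epipolar_warn))
}

#' Run summary of a pipeline result
#'
#' @param records A `fin_trajectories` result from one of the `run_*`
#'   pipelines.
#' @return List with the pipeline label, record count, per-reason rejection
#'   counts and the number of epipolar-consistency warnings.
#' @export
run_summary <- function(records) attr(records, "summary")

# Shared core of the mask- and box-based stereo pipelines.
run_region_stereo <- function(scene, pipeline, match_on, centroids_from,
                              min_iou, params, d_min, z_max,
                              disparity_shift, epipolar_warn_px = 5) {
  calib <- scene$cfg$calib
  col <- new_record_collector(pipeline)
  left <- tracked_left_detections(scene, params)
  right <- scene$detections[scene$detections$side == "right", , drop = FALSE]
  frames <- sort(unique(left$frame[!is.na(left$track_id)]))
  for (f in frames) {
    lb <- left[left$frame == f & !is.na(left$track_id), , drop = FALSE]
    rb <- right[right$frame == f, , drop = FALSE]
    if (nrow(rb) == 0) {
      col$rejections[["no_match"]] <- col$rejections[["no_match"]] + nrow(lb)
      next
    }
    ml <- mr <- NULL
    if (match_on == "mask" || centroids_from == "mask") {
      ml <- scene$masks[[paste0(f, ":left")]][lb$det]
      mr <- scene$masks[[paste0(f, ":right")]][rb$det]
      bad <- vapply(c(ml, mr), is.null, logical(1))
      if (any(bad)) {
        col$rejections[["empty_mask"]] <- col$rejections[["empty_mask"]] +
          sum(bad)
        next
      }
    }
    cost <- if (match_on == "mask") {
      iou_cost_matrix(ml, mr, mode = "mask", disparity_shift = disparity_shift)
    } else {
      iou_cost_matrix(lb[, c("x", "y", "w", "h")], rb[, c("x", "y", "w", "h")],
                      mode = "bbox", disparity_shift = disparity_shift)
    }
    pairs <- assign_stereo(cost, min_iou = min_iou)
    col$rejections[["no_match"]] <- col$rejections[["no_match"]] +
      (nrow(lb) - nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$left[k]; j <- pairs$right[k]
      if (centroids_from == "mask") {
        cl <- mask_centroid(ml[[i]])
        cr <- mask_centroid(mr[[j]])
      } else {
        cl <- c(lb$x[i] + lb$w[i] / 2, lb$y[i] + lb$h[i] / 2)
        cr <- c(rb$x[j] + rb$w[j] / 2, rb$y[j] + rb$h[j] / 2)
      }
      if (abs(cl[2] - cr[2]) > epipolar_warn_px) {
        col$epipolar_warn <- col$epipolar_warn + 1L
      }
      tri <- triangulate(calib, cl[1], cl[2], cr[1], d_min = d_min,
                         z_max = z_max)
      collect_point(col, f, lb$track_id[i], tri)
    }
  }
  finish_records(col)
}

#' SegmentDepth pipeline: stereo association of segmentation masks
#'
#' Both camera streams are run through the detector; the left stream is
#' tracked. Masks segmented within the boxes on both sides are associated
#' across views by mask IOU and minimum-cost assignment (`match_on = "mask"`),
#' or — the computationally cheaper variant — boxes are matched and the masks
#' only supply centroids (`match_on = "bbox"`). The mask centroids of each
#' matched pair are triangulated: the left centroid is the 2D key, the right
#' centroid supplies `xr`.
#'
#' @param scene A `fin_scene` (from [render_observations()] or [read_scene()]).
#' @param match_on `"mask"` or `"bbox"` (the matcher-on-boxes variant).
#' @param min_iou IOU gate for accepting a stereo pair.
#' @param params Tracker parameters, see [tracker_params()].
#' @param d_min,z_max Triangulation gates, see [triangulate()].
#' @param disparity_shift Optional horizontal pre-shift of right items before
#'   IOU (px); 0 mirrors the published procedure.
#' @return A `fin_trajectories` data frame (`frame`, `track_id`, `X`, `Y`,
#'   `Z`, `distance_m`, `pipeline`) with a [run_summary()] attribute.
#' @export
run_segmentdepth <- function(scene, match_on = c("mask", "bbox"),
                             min_iou = 0.1, params = tracker_params(),
                             d_min = 0.5, z_max = 10, disparity_shift = 0) {
  match_on <- match.arg(match_on)
  run_region_stereo(scene, "segmentdepth", match_on, centroids_from = "mask",
                    min_iou, params, d_min, z_max, disparity_shift)
}

#' BBoxDepth pipeline: stereo association of bounding boxes
#'
#' Boxes from the two views are associated by box IOU and minimum-cost
#' assignment, and the centres of each matched pair are triangulated.
#'
#' @inheritParams run_segmentdepth
#' @return A `fin_trajectories` data frame, see [run_segmentdepth()].
#' @export
run_bboxdepth <- function(scene, min_iou = 0.1, params = tracker_params(),
                          d_min = 0.5, z_max = 10, disparity_shift = 0) {
  run_region_stereo(scene, "bboxdepth", match_on = "bbox",
                    centroids_from = "bbox", min_iou, params, d_min, z_max,
                    disparity_shift)
}

#' SuperGlue-style pipeline: sparse feature-match triangulation
#'
#' Only the left stream is tracked. Per tracked box, the feature matches are
#' filtered (confidence > `conf_min` and left point inside the box), the
#' right-image position of the box centre is estimated by the offset-vector
#' construction ([estimate_right_point()]), and the box centre is triangulated
#' against it. Boxes with no surviving matches yield no record.
#'
#' @inheritParams run_segmentdepth
#' @param conf_min Match confidence threshold (strict, default 0.1).
#' @param epipolar_warn_px Vertical-residual diagnostic threshold, px.
#' @return A `fin_trajectories` data frame, see [run_segmentdepth()].
#' @export
run_superglue <- function(scene, conf_min = 0.1, params = tracker_params(),
                          d_min = 0.5, z_max = 10, epipolar_warn_px = 5) {
  calib <- scene$cfg$calib
  col <- new_record_collector("superglue")
  left <- tracked_left_detections(scene, params)
  frames <- sort(unique(left$frame[!is.na(left$track_id)]))
  for (f in frames) {
    lb <- left[left$frame == f & !is.na(left$track_id), , drop = FALSE]
    m <- scene$matches[scene$matches$frame == f, , drop = FALSE]
    fm <- filter_matches(m, lb[, c("x", "y", "w", "h")], conf_min = conf_min)
    for (i in seq_len(nrow(lb))) {
      grp <- fm[fm$box == i, , drop = FALSE]
      if (nrow(grp) == 0) {
        col$rejections[["no_match"]] <- col$rejections[["no_match"]] + 1L
        next
      }
      ctr <- c(lb$x[i] + lb$w[i] / 2, lb$y[i] + lb$h[i] / 2)
      rp <- estimate_right_point(ctr, grp)
      if (abs(rp[["v"]] - ctr[2]) > epipolar_warn_px) {
        col$epipolar_warn <- col$epipolar_warn + 1L
      }
      tri <- triangulate(calib, ctr[1], ctr[2], rp[["u"]], d_min = d_min,
                         z_max = z_max)
      collect_point(col, f, lb$track_id[i], tri)
    }
  }
  finish_records(col)
}

#' Monocular depth-map pipeline
#'
#' Only the left stream is used. For each tracked box the depth raster value
#' at the central pixel (floor of the continuous box centre) is read and the
#' pixel back-projected to 3D. The record carries whatever the raster says —
#' there is no stereo consistency check. A 3x3 patch-median option exists for
#' robustness experiments.
#'
#' @inheritParams run_segmentdepth
#' @param depth_map Backend `function(frame) -> height x width` matrix of
#'   metric depths (meters); defaults to the scene's own raster backend.
#' @param patch `"center"` (single-pixel read, the default) or `"median3"`
#'   (median over the 3x3 neighbourhood).
#' @return A `fin_trajectories` data frame, see [run_segmentdepth()].
#' @export
run_mono <- function(scene, depth_map = scene$depth_map,
                     params = tracker_params(), patch = c("center", "median3")) {
  patch <- match.arg(patch)
  calib <- scene$cfg$calib
  col <- new_record_collector("mono")
  left <- tracked_left_detections(scene, params)
  frames <- sort(unique(left$frame[!is.na(left$track_id)]))
  for (f in frames) {
    lb <- left[left$frame == f & !is.na(left$track_id), , drop = FALSE]
    Zmap <- depth_map(f)
    for (i in seq_len(nrow(lb))) {
      cu <- floor(lb$x[i] + lb$w[i] / 2)
      cv <- floor(lb$y[i] + lb$h[i] / 2)
      if (cu < 0 || cv < 0 || cu > calib$width - 1 || cv > calib$height - 1) {
        col$rejections[["bounds"]] <- col$rejections[["bounds"]] + 1L
        next
      }
      Z <- if (patch == "center") {
        Zmap[cv + 1, cu + 1]
      } else {
        us <- pmin(pmax((cu - 1):(cu + 1), 0), calib$width - 1)
        vs <- pmin(pmax((cv - 1):(cv + 1), 0), calib$height - 1)
        stats::median(Zmap[vs + 1, us + 1])
      }
      if (!is.finite(Z) || Z <= 0) {
        col$rejections[["nonfinite_depth"]] <-
          col$rejections[["nonfinite_depth"]] + 1L
        next
      }
      bp <- backproject(calib, cu, cv, Z)
      collect_point(col, f, lb$track_id[i],
                    list(status = bp$status, X = bp$X, Y = bp$Y, Z = bp$Z))
    }
  }
  finish_records(col)
}

#' @export
print.fin_trajectories <- function(x, ...) {
  s <- run_summary(x)
  cat(sprintf("fin_trajectories [%s]: %d records, rejections: %s\n",
              s$pipeline, s$n_records,
              paste(names(s$rejections), s$rejections, sep = "=",
                    collapse = " ")))
  NextMethod()
}
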