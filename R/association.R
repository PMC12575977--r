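# Stereo correspondence logic: mask/box IOU cost matrices for Hungarian
# assignment, feature-match filtering, the offset-vector right-point estimator,
# and mask centroids. Cross-view IOU is computed in the shared rectified pixel
# frame with no disparity compensation (the short 42 mm baseline keeps
# same-fish regions overlapping across views at the working ranges); an
# optional median-disparity shift is available for wide-baseline use.

#' Construct a segmentation mask region
#'
#' A mask is a set of pixel coordinates. Real rasters yield integer
#' coordinates; the simulator's oracle segmenter emits sub-pixel coordinates
#' (a symmetric lattice about the true fin centre) so that centroids are exact.
#' Overlap computations always quantise coordinates to the pixel grid.
#'
#' @param u,v Pixel coordinates of member pixels (equal-length, non-empty).
#' @param frame Frame index (0-based).
#' @param side `"left"` or `"right"`.
#' @param parent_box Optional `(x, y, w, h)` detection box the mask was
#'   segmented within.
#' @return An object of class `mask_region`.
#' @export
mask_region <- function(u, v, frame = 0L, side = "left", parent_box = NULL) {
  if (length(u) == 0 || length(u) != length(v)) {
    stop("mask must be a non-empty set of (u, v) pixels")
  }
  structure(list(u = as.numeric(u), v = as.numeric(v),
                 frame = as.integer(frame), side = side,
                 parent_box = parent_box),
            class = "mask_region")
}

#' Centroid of a segmentation mask
#'
#' The arithmetic mean of all member pixel coordinates (continuous result).
#'
#' @param mask A [mask_region()].
#' @return Numeric vector `c(u, v)`.
#' @examples
#' mask_centroid(mask_region(u = c(0, 0, 1), v = c(0, 1, 0)))  # (1/3, 1/3)
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "mask_region"))
  c(u = mean(mask$u), v = mean(mask$v))
}

# Quantised pixel keys of a mask (u shifted by `shift` pixels first).
mask_keys <- function(m, shift = 0) {
  unique(round(m$u + shift) * 2^20 + round(m$v))
}

key_iou <- function(ka, kb) {
  ninter <- sum(ka %in% kb)
  ninter / (length(ka) + length(kb) - ninter)
}

# IOU between two masks on the quantised pixel grid.
mask_iou <- function(a, b) key_iou(mask_keys(a), mask_keys(b))

#' IOU assignment cost matrix between left and right items
#'
#' Entry `(i, j)` is `1 - IOU(left_i, right_j)`. In `"mask"` mode the IOU is
#' computed on (quantised) pixel sets; in `"bbox"` mode on `(x, y, w, h)`
#' boxes. Items must all come from the same frame. No disparity compensation
#' is applied unless `disparity_shift` is nonzero, in which case right items
#' are shifted by that many pixels toward the left view before the overlap is
#' computed.
#'
#' @param left_items,right_items In mask mode, lists of [mask_region()]; in
#'   bbox mode, matrices/data frames with 4 columns `(x, y, w, h)`.
#' @param mode `"mask"` or `"bbox"`.
#' @param disparity_shift Horizontal pre-shift of right items in pixels
#'   (default 0, mirroring the published procedure).
#' @return Numeric cost matrix, `length(left) x length(right)`.
#' @export
iou_cost_matrix <- function(left_items, right_items, mode = c("mask", "bbox"),
                            disparity_shift = 0) {
  mode <- match.arg(mode)
  if (mode == "mask") {
    nl <- length(left_items); nr <- length(right_items)
    if (nl && nr) {
      fr <- vapply(c(left_items, right_items), function(m) m$frame, integer(1))
      if (length(unique(fr)) > 1) stop("items from mixed frames")
    }
    kl <- lapply(left_items, mask_keys)
    kr <- lapply(right_items, mask_keys, shift = disparity_shift)
    out <- matrix(1, nl, nr)
    for (i in seq_len(nl)) {
      for (j in seq_len(nr)) {
        out[i, j] <- 1 - key_iou(kl[[i]], kr[[j]])
      }
    }
    out
  } else {
    A <- matrix(as.numeric(as.matrix(left_items)), ncol = 4)
    B <- matrix(as.numeric(as.matrix(right_items)), ncol = 4)
    if (disparity_shift != 0) B[, 1] <- B[, 1] + disparity_shift
    1 - iou_matrix(A, B)
  }
}

#' Filter feature matches by confidence and containing box
#'
#' Keeps matches whose confidence strictly exceeds `conf_min` and whose
#' left-image point falls inside at least one detection box (a point on the box
#' edge counts as inside). Each retained match is associated with one box; if a
#' point lies inside several boxes, the box whose centre is nearest is chosen
#' (ties to the lower box index).
#'
#' @param matches Data frame with columns `xl`, `yl`, `xr`, `yr`, `conf`.
#' @param boxes Data frame / matrix of left-side boxes, columns `(x, y, w, h)`.
#' @param conf_min Confidence threshold (default 0.1, strict inequality).
#' @return `matches` restricted to retained rows, with an added `box` column
#'   (index into `boxes`).
#' @export
filter_matches <- function(matches, boxes, conf_min = 0.1) {
  boxes <- matrix(as.numeric(as.matrix(boxes)), ncol = 4)
  keep <- matches$conf > conf_min
  out <- matches[keep, , drop = FALSE]
  if (nrow(out) == 0 || nrow(boxes) == 0) {
    out$box <- integer(0)
    return(out[integer(0), , drop = FALSE])
  }
  bx1 <- boxes[, 1]; by1 <- boxes[, 2]
  bx2 <- boxes[, 1] + boxes[, 3]; by2 <- boxes[, 2] + boxes[, 4]
  cxs <- bx1 + boxes[, 3] / 2; cys <- by1 + boxes[, 4] / 2
  box_id <- vapply(seq_len(nrow(out)), function(i) {
    inside <- which(out$xl[i] >= bx1 & out$xl[i] <= bx2 &
                    out$yl[i] >= by1 & out$yl[i] <= by2)
    if (!length(inside)) return(NA_integer_)
    if (length(inside) == 1) return(inside)
    d2 <- (out$xl[i] - cxs[inside])^2 + (out$yl[i] - cys[inside])^2
    inside[which.min(d2)]
  }, integer(1))
  out$box <- box_id
  out[!is.na(box_id), , drop = FALSE]
}

#' Estimate the right-image point for a tracked box
#'
#' Offset-vector construction: the 2D vector from the mean left-image position
#' of the box's matched points to the box centre is added to the mean
#' right-image position of those points, estimating where the box centre lies
#' in the right image. The box centre itself remains the left-image
#' triangulation key.
#'
#' @param box_center_left Numeric `c(u, v)`, the left box centre.
#' @param group Data frame of matches associated with this box (columns `xl`,
#'   `yl`, `xr`, `yr`); must be non-empty.
#' @return Numeric `c(u, v)` estimated right-image position. The vertical
#'   component is returned for epipolar diagnostics; only the horizontal
#'   component enters triangulation.
#' @examples
#' estimate_right_point(c(100, 50),
#'                      data.frame(xl = 90, yl = 45, xr = 60, yr = 45))
#' @export
estimate_right_point <- function(box_center_left, group) {
  if (is.null(group) || nrow(group) == 0) stop("no matches for box")
  d <- box_center_left - c(mean(group$xl), mean(group$yl))
  r <- c(mean(group$xr), mean(group$yr)) + d
  c(u = r[[1]], v = r[[2]])
}
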