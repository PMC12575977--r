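# Pinhole rectified-stereo camera model: triangulation, back-projection and
# forward projection. All pixel coordinates are continuous, 0-based, origin at
# the image top-left, y pointing down. Camera frame: x right, y down, z forward
# along the optical axis of the left camera. The baseline is given in mm (as on
# the physical rig); all 3D output is in meters, with the mm->m conversion
# applied in exactly one place (triangulation / projection).

#' Stereo calibration object
#'
#' Bundles the intrinsics of a rectified stereo pair: focal lengths and
#' principal point of the (shared) pinhole model, the stereo baseline, and the
#' image size. The right camera is modelled as the left camera displaced by
#' `baseline_mm` along +x, so disparity `xl - xr` is non-negative for points in
#' front of the rig.
#'
#' @param fx Horizontal focal length in pixels (> 0).
#' @param fy Vertical focal length in pixels (> 0); defaults to `fx`.
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param baseline_mm Stereo baseline in millimeters (> 0).
#' @param width,height Image size in pixels.
#'
#' @return An object of class `stereo_calibration`.
#' @examples
#' calib <- stereo_calibration(fx = 1400, cx = 960, cy = 600,
#'                             baseline_mm = 42, width = 1920, height = 1200)
#' calib
#' @export
stereo_calibration <- function(fx, fy = fx, cx, cy, baseline_mm, width, height) {
  stopifnot(is.numeric(fx), is.numeric(fy), is.numeric(cx), is.numeric(cy),
            is.numeric(baseline_mm), is.numeric(width), is.numeric(height))
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (baseline_mm <= 0) stop("baseline_mm must be positive")
  if (width <= 0 || height <= 0) stop("image size must be positive")
  if (cx < 0 || cx >= width) stop("cx must satisfy 0 <= cx < width")
  if (cy < 0 || cy >= height) stop("cy must satisfy 0 <= cy < height")
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         cx = as.numeric(cx), cy = as.numeric(cy),
         baseline_mm = as.numeric(baseline_mm),
         width = as.numeric(width), height = as.numeric(height)),
    class = "stereo_calibration"
  )
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat(sprintf(
    "stereo_calibration: %gx%g px, fx=%g fy=%g, c=(%g, %g), baseline=%g mm\n",
    x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$baseline_mm))
  invisible(x)
}

#' Default calibration of the simulated rig
#'
#' The field rig this package emulates used a 42 mm baseline and 1920x1200 px
#' frames; its calibrated focal length was never published, so the default
#' focal length here (1400 px) is a simulator convention chosen to give
#' realistic disparities (15--60 px) over the 0.7--4 m fish ranges, not a field
#' value.
#'
#' @return A [stereo_calibration()] object.
#' @export
default_calibration <- function() {
  stereo_calibration(fx = 1400, fy = 1400, cx = 960, cy = 600,
                     baseline_mm = 42, width = 1920, height = 1200)
}

#' Triangulate rectified stereo observations
#'
#' Converts a left-image point and the horizontal coordinate of its right-image
#' correspondence into a 3D point in the left-camera frame:
#' `Z = b * fx / (xl - xr)` (converted mm -> m), `X = Z (u - cx) / fx`,
#' `Y = Z (v - cy) / fy`, with `(u, v)` the left point. The horizontal focal
#' length is used in the depth formula because disparity is horizontal.
#'
#' Vectorised over observations. Degenerate disparities (`<= d_min`) and points
#' beyond `z_max` are rejected: their coordinates are `NA` and `status` records
#' the reason.
#'
#' @param calib A [stereo_calibration()].
#' @param u,v Left-image pixel coordinates (numeric vectors).
#' @param xr Right-image horizontal pixel coordinate(s).
#' @param d_min Minimum admissible disparity in pixels (default 0.5).
#' @param z_max Maximum admissible depth in meters (default 10).
#'
#' @return A data frame with columns `X`, `Y`, `Z` (meters) and `status`
#'   (`"ok"`, `"degenerate_disparity"` or `"out_of_range"`).
#' @examples
#' calib <- stereo_calibration(fx = 1000, cx = 960, cy = 600,
#'                             baseline_mm = 42, width = 1920, height = 1200)
#' triangulate(calib, u = 960, v = 600, xr = 960 - 21)  # Z = 2 m on-axis
#' @export
triangulate <- function(calib, u, v, xr, d_min = 0.5, z_max = 10) {
  stopifnot(inherits(calib, "stereo_calibration"))
  n <- max(length(u), length(v), length(xr))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  xr <- rep_len(as.numeric(xr), n)
  d <- u - xr
  Z <- (calib$baseline_mm * calib$fx / d) / 1000
  X <- Z * (u - calib$cx) / calib$fx
  Y <- Z * (v - calib$cy) / calib$fy
  status <- rep("ok", n)
  bad_d <- !is.finite(d) | d <= d_min
  status[bad_d] <- "degenerate_disparity"
  far <- !bad_d & Z > z_max
  status[far] <- "out_of_range"
  drop <- bad_d | far
  X[drop] <- NA_real_; Y[drop] <- NA_real_; Z[drop] <- NA_real_
  data.frame(X = X, Y = Y, Z = Z, status = status, stringsAsFactors = FALSE)
}

#' Back-project a pixel at known depth
#'
#' Inverse pinhole mapping used by the monocular depth-map pipeline: given a
#' pixel `(u, v)` and a metric depth `Z`, returns
#' `X = Z (u - cx) / fx`, `Y = Z (v - cy) / fy`, `Z` unchanged.
#'
#' @inheritParams triangulate
#' @param Z Depth in meters; entries `<= 0` (or non-finite) are rejected.
#' @return A data frame with `X`, `Y`, `Z`, `status` (`"ok"`/`"invalid_depth"`).
#' @export
backproject <- function(calib, u, v, Z) {
  stopifnot(inherits(calib, "stereo_calibration"))
  n <- max(length(u), length(v), length(Z))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  Z <- rep_len(as.numeric(Z), n)
  bad <- !is.finite(Z) | Z <= 0
  X <- Z * (u - calib$cx) / calib$fx
  Y <- Z * (v - calib$cy) / calib$fy
  X[bad] <- NA_real_; Y[bad] <- NA_real_; Z[bad] <- NA_real_
  status <- ifelse(bad, "invalid_depth", "ok")
  data.frame(X = X, Y = Y, Z = Z, status = status, stringsAsFactors = FALSE)
}

#' Project a 3D point into both rectified images
#'
#' Forward pinhole projection, the inverse of [triangulate()]; used by the
#' scene simulator. The right camera sits at `+baseline` along camera x, so the
#' right image coordinate is `fx (X - b) / Z + cx` with `b` in meters, and both
#' projections share the same vertical coordinate (rectified model).
#'
#' @inheritParams triangulate
#' @param X,Y,Z Point coordinates in meters (left-camera frame); `Z` must be
#'   positive.
#' @return A list with data frames `left` and `right` (columns `u`, `v`) and a
#'   `status` vector (`"ok"`/`"behind_camera"`). Rejected points have `NA`
#'   coordinates.
#' @export
project_stereo <- function(calib, X, Y, Z) {
  stopifnot(inherits(calib, "stereo_calibration"))
  n <- max(length(X), length(Y), length(Z))
  X <- rep_len(as.numeric(X), n)
  Y <- rep_len(as.numeric(Y), n)
  Z <- rep_len(as.numeric(Z), n)
  bad <- !is.finite(Z) | Z <= 0
  ul <- calib$fx * X / Z + calib$cx
  vv <- calib$fy * Y / Z + calib$cy
  ur <- calib$fx * (X - calib$baseline_mm / 1000) / Z + calib$cx
  ul[bad] <- NA_real_; vv[bad] <- NA_real_; ur[bad] <- NA_real_
  list(left = data.frame(u = ul, v = vv),
       right = data.frame(u = ur, v = vv),
       status = ifelse(bad, "behind_camera", "ok"))
}
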