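# Synthetic stereo fish-scene generator. Emulates the acquisition geometry of
# the field rig (42 mm baseline, 1920x1200 px, 25 fps, fish at ~0.7-4 m) with
# ground truth, so pipelines and statistics are testable without field video.
# Fins are modelled as planar, camera-facing ellipses: the pipelines only
# consume boxes, masks, matched points and depth rasters, so silhouette
# realism suffices.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# One master seed drives independent per-component sub-seeds so motion, noise
# and dropout can be varied in isolation.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Scene configuration for the stereo fish simulator
#'
#' Defaults emulate the field setup this package targets: a 42 mm baseline
#' 1920x1200 px rig at 25 fps and fish swimming 0.8--4 m in front of the
#' camera (the observed field ranges were roughly 0.7--3.75 m). Fish motion is
#' a correlated random walk; speeds are salmon-like (~0.8 body lengths/s for a
#' ~1 kg fish). Observation noise defaults (0.5 px localisation noise, 5%
#' detection dropout) are package conventions since no field values exist.
#'
#' @param n_fish Number of fish.
#' @param n_frames Number of frames.
#' @param fps Frame rate, Hz.
#' @param calib A [stereo_calibration()].
#' @param volume Named list `xlim`, `ylim`, `zlim` (meters, camera frame);
#'   `zlim[1]` must be positive.
#' @param speed_mean,speed_sd Swimming speed distribution, m/s (truncated
#'   Gaussian on `[0, 3 * speed_mean]`).
#' @param turn_sd Heading change per frame, radians.
#' @param fin_halfwidth_m Physical half-extent of the caudal fin, meters.
#' @param fin_aspect Vertical/horizontal fin extent ratio (before wobble).
#' @param pixel_noise_sd Gaussian pixel noise applied to detection box corners
#'   and mask centres, px.
#' @param dropout_p Per-side per-frame probability that a visible fin is not
#'   detected.
#' @param conf_beta Beta parameters of detection confidences; the default
#'   `c(8, 2)` puts most mass near 0.8.
#' @param n_matches_per_fin Feature-match point pairs generated per visible
#'   fin per frame.
#' @param match_jitter_sd Gaussian jitter on match point coordinates, px.
#' @param n_clutter_matches Spurious (non-fish) matches per frame.
#' @param background_depth_m Constant depth assigned to background pixels in
#'   the simulated metric depth raster (monocular models map unbounded
#'   backgrounds to a fixed distance).
#' @param seed Master seed; all randomness is derived from it.
#' @return An object of class `scene_config` (a named list).
#' @export
scene_config <- function(n_fish = 3, n_frames = 100, fps = 25,
                         calib = default_calibration(),
                         volume = list(xlim = c(-1.2, 1.2),
                                       ylim = c(-0.7, 0.7),
                                       zlim = c(0.8, 4.0)),
                         speed_mean = 0.35, speed_sd = 0.1, turn_sd = 0.15,
                         fin_halfwidth_m = 0.05, fin_aspect = 0.6,
                         pixel_noise_sd = 0.5, dropout_p = 0.05,
                         conf_beta = c(8, 2),
                         n_matches_per_fin = 8, match_jitter_sd = 0.5,
                         n_clutter_matches = 5,
                         background_depth_m = 8, seed = 1) {
  stopifnot(n_fish >= 0, n_frames >= 0, fps > 0,
            inherits(calib, "stereo_calibration"),
            volume$zlim[1] > 0, diff(volume$xlim) > 0,
            diff(volume$ylim) > 0, diff(volume$zlim) > 0,
            dropout_p >= 0, dropout_p <= 1, pixel_noise_sd >= 0,
            match_jitter_sd >= 0, fin_halfwidth_m > 0,
            length(conf_beta) == 2, all(conf_beta > 0))
  structure(as.list(environment()), class = "scene_config")
}

#' Simulate ground-truth fish trajectories
#'
#' Correlated random walk per fish: horizontal heading and pitch evolve by
#' Gaussian turns (`turn_sd`), speed by a Gaussian truncated to
#' `[0, 3 * speed_mean]`, and paths reflect at the volume boundaries (so
#' per-frame displacement never exceeds `3 * speed_mean / fps`). Fully
#' reproducible from the config seed.
#'
#' @param cfg A [scene_config()].
#' @return An object of class `scene_truth`: list with `pos` (array
#'   `n_fish x n_frames x 3`, meters), `orient` (fin wobble angle, radians),
#'   `vis_left`/`vis_right` (logical `n_fish x n_frames`; TRUE when the whole
#'   fin ellipse projects inside that image), and `cfg`.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nf <- cfg$n_fish; nt <- cfg$n_frames
  pos <- array(NA_real_, c(nf, nt, 3))
  orient <- matrix(0, nf, max(nt, 1))
  if (nf > 0 && nt > 0) {
    with_seed(cfg$seed, {
      dt <- 1 / cfg$fps
      for (i in seq_len(nf)) {
        p <- c(stats::runif(1, cfg$volume$xlim[1], cfg$volume$xlim[2]),
               stats::runif(1, cfg$volume$ylim[1], cfg$volume$ylim[2]),
               stats::runif(1, cfg$volume$zlim[1], cfg$volume$zlim[2]))
        az <- stats::runif(1, 0, 2 * pi)
        el <- stats::rnorm(1, 0, 0.3)
        wob <- stats::runif(1, 0, 2 * pi)
        for (t in seq_len(nt)) {
          pos[i, t, ] <- p
          orient[i, t] <- wob
          az <- az + stats::rnorm(1, 0, cfg$turn_sd)
          el <- 0.8 * el + stats::rnorm(1, 0, cfg$turn_sd / 2)
          wob <- wob + stats::rnorm(1, 0, 0.1)
          sp <- min(max(stats::rnorm(1, cfg$speed_mean, cfg$speed_sd), 0),
                    3 * cfg$speed_mean)
          step <- sp * dt * c(cos(el) * cos(az), sin(el), cos(el) * sin(az))
          p <- p + step
          # reflect at volume boundaries
          lims <- rbind(cfg$volume$xlim, cfg$volume$ylim, cfg$volume$zlim)
          for (k in 1:3) {
            if (p[k] < lims[k, 1]) p[k] <- 2 * lims[k, 1] - p[k]
            if (p[k] > lims[k, 2]) p[k] <- 2 * lims[k, 2] - p[k]
            p[k] <- min(max(p[k], lims[k, 1]), lims[k, 2])
          }
        }
      }
    })
  }
  truth <- list(pos = pos, orient = orient, cfg = cfg)
  vis <- fin_visibility(truth)
  truth$vis_left <- vis$left
  truth$vis_right <- vis$right
  structure(truth, class = "scene_truth")
}

# Projected fin ellipse parameters for fish i at frame t on one side.
# Returns list(u, v, a, b): centre and semi-axes in pixels.
fin_ellipse <- function(truth, i, t, side) {
  cfg <- truth$cfg; calib <- cfg$calib
  P <- truth$pos[i, t, ]
  pr <- project_stereo(calib, P[1], P[2], P[3])
  ctr <- if (side == "left") pr$left else pr$right
  a <- cfg$fin_halfwidth_m * calib$fx / P[3]
  aspect <- cfg$fin_aspect + 0.1 * sin(truth$orient[i, t])
  b <- cfg$fin_halfwidth_m * aspect * calib$fy / P[3]
  list(u = ctr$u, v = ctr$v, a = a, b = b)
}

# Full-ellipse-in-frame visibility per side.
fin_visibility <- function(truth) {
  cfg <- truth$cfg; calib <- cfg$calib
  nf <- dim(truth$pos)[1]; nt <- dim(truth$pos)[2]
  vl <- matrix(FALSE, nf, nt); vr <- matrix(FALSE, nf, nt)
  for (i in seq_len(nf)) {
    for (t in seq_len(nt)) {
      for (side in c("left", "right")) {
        e <- fin_ellipse(truth, i, t, side)
        ok <- e$u - e$a >= 0 && e$u + e$a <= calib$width - 1 &&
              e$v - e$b >= 0 && e$v + e$b <= calib$height - 1
        if (side == "left") vl[i, t] <- ok else vr[i, t] <- ok
      }
    }
  }
  list(left = vl, right = vr)
}

# Sub-pixel mask lattice: integer offsets (i, j) inside the ellipse, attached
# to the continuous centre. Symmetric by construction, so the centroid equals
# the centre to floating-point accuracy; rounding recovers a dense pixel
# raster for overlap computations.
ellipse_mask <- function(u0, v0, a, b, frame, side, parent_box = NULL) {
  ia <- max(floor(a), 1); ib <- max(floor(b), 1)
  i <- rep(-ia:ia, times = 2 * ib + 1)
  j <- rep(-ib:ib, each = 2 * ia + 1)
  keep <- (i / a)^2 + (j / b)^2 <= 1
  mask_region(u0 + i[keep], v0 + j[keep], frame, side, parent_box)
}

#' Render observation streams from a simulated scene
#'
#' Produces everything the pipelines consume: per-side MOT detections (fin
#' ellipse extents with Gaussian corner noise, Beta-distributed confidences,
#' Bernoulli dropout), per-detection oracle segmentation masks (sub-pixel
#' symmetric ellipse lattices, centre jittered by `pixel_noise_sd`), feature
#' matches (points sampled on the fin plane, jittered by `match_jitter_sd`,
#' plus clutter matches outside fish), and a lazy metric depth raster
#' (z-buffer of fin ellipses over `background_depth_m`).
#'
#' Fins are only rendered on a side while the whole ellipse is inside that
#' image (no partially clipped observations).
#'
#' @param truth A [simulate_trajectories()] result.
#' @param cfg The matching [scene_config()]; defaults to `truth$cfg`.
#' @return An object of class `fin_scene`: list with `cfg`, `truth`,
#'   `detections` (data frame: `frame`, `side`, `x`, `y`, `w`, `h`, `conf`,
#'   `truth_id`, `det`), `masks` (named list `"<frame>:<side>"` of
#'   [mask_region()] lists, parallel to the `det` index), `matches` (data
#'   frame: `frame`, `xl`, `yl`, `xr`, `yr`, `conf`), and `depth_map`
#'   (function(frame) -> height x width matrix of meters).
#' @export
render_observations <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "scene_truth"), inherits(cfg, "scene_config"))
  calib <- cfg$calib
  nf <- dim(truth$pos)[1]; nt <- dim(truth$pos)[2]

  det_list <- list(); mask_store <- list(); match_list <- list()
  with_seed(cfg$seed + 1L, {   # observation-noise generator
    for (t in seq_len(nt)) {
      f <- t - 1L  # 0-based frame index
      for (side in c("left", "right")) {
        vis <- if (side == "left") truth$vis_left else truth$vis_right
        key <- paste0(f, ":", side)
        masks_here <- list()
        det_here <- 0L
        for (i in seq_len(nf)) {
          if (!vis[i, t]) next
          if (stats::runif(1) < cfg$dropout_p) next
          e <- fin_ellipse(truth, i, t, side)
          # box: ellipse extent plus corner noise
          n4 <- stats::rnorm(4, 0, cfg$pixel_noise_sd)
          x1 <- e$u - e$a + n4[1]; y1 <- e$v - e$b + n4[2]
          x2 <- e$u + e$a + n4[3]; y2 <- e$v + e$b + n4[4]
          box <- c(x1, y1, max(x2 - x1, 1), max(y2 - y1, 1))
          conf <- stats::rbeta(1, cfg$conf_beta[1], cfg$conf_beta[2])
          det_here <- det_here + 1L
          det_list[[length(det_list) + 1L]] <- list(
            f, side, box[1], box[2], box[3], box[4], conf, i, det_here)
          # mask: centre jitter models segmentation boundary noise
          mj <- stats::rnorm(2, 0, cfg$pixel_noise_sd)
          masks_here[[det_here]] <- ellipse_mask(
            e$u + mj[1], e$v + mj[2], e$a, e$b, f, side, box)
        }
        mask_store[[key]] <- masks_here
      }
      # feature matches: fish visible in BOTH views (matcher is independent
      # of the detector, so dropout does not apply here)
      for (i in seq_len(nf)) {
        if (!(truth$vis_left[i, t] && truth$vis_right[i, t])) next
        el <- fin_ellipse(truth, i, t, "left")
        er <- fin_ellipse(truth, i, t, "right")
        nm <- cfg$n_matches_per_fin
        if (nm > 0) {
          r <- sqrt(stats::runif(nm)); th <- stats::runif(nm, 0, 2 * pi)
          du <- el$a * r * cos(th); dv <- el$b * r * sin(th)
          jit <- matrix(stats::rnorm(4 * nm, 0, cfg$match_jitter_sd), nm)
          match_list[[length(match_list) + 1L]] <- cbind(
            frame = f,
            xl = el$u + du + jit[, 1], yl = el$v + dv + jit[, 2],
            xr = er$u + du + jit[, 3], yr = er$v + dv + jit[, 4],
            conf = stats::rbeta(nm, cfg$conf_beta[1], cfg$conf_beta[2]))
        }
      }
      if (cfg$n_clutter_matches > 0) {
        nc <- cfg$n_clutter_matches
        xl <- stats::runif(nc, 0, calib$width - 1)
        yl <- stats::runif(nc, 0, calib$height - 1)
        match_list[[length(match_list) + 1L]] <- cbind(
          frame = t - 1L, xl = xl, yl = yl,
          xr = xl - stats::runif(nc, 5, 80), yr = yl,
          conf = stats::rbeta(nc, 2, 2))
      }
    }
  })

  detections <- if (length(det_list)) {
    g <- function(k, cast) cast(vapply(det_list, function(r) r[[k]],
                                       if (identical(cast, as.character))
                                         character(1) else numeric(1)))
    data.frame(frame = g(1, as.integer), side = g(2, as.character),
               x = g(3, as.numeric), y = g(4, as.numeric),
               w = g(5, as.numeric), h = g(6, as.numeric),
               conf = g(7, as.numeric), truth_id = g(8, as.integer),
               det = g(9, as.integer), stringsAsFactors = FALSE)
  } else
    data.frame(frame = integer(0), side = character(0), x = numeric(0),
               y = numeric(0), w = numeric(0), h = numeric(0),
               conf = numeric(0), truth_id = integer(0), det = integer(0))
  matches <- if (length(match_list)) {
    m <- do.call(rbind, match_list)
    data.frame(frame = as.integer(m[, "frame"]), xl = m[, "xl"],
               yl = m[, "yl"], xr = m[, "xr"], yr = m[, "yr"],
               conf = m[, "conf"])
  } else
    data.frame(frame = integer(0), xl = numeric(0), yl = numeric(0),
               xr = numeric(0), yr = numeric(0), conf = numeric(0))

  depth_map <- make_depth_backend(truth)

  structure(list(cfg = cfg, truth = truth, detections = detections,
                 masks = mask_store, matches = matches,
                 depth_map = depth_map),
            class = "fin_scene")
}

#' Oracle metric depth-map backend from scene truth
#'
#' Returns `function(frame)` producing the z-buffer of the left-view fin
#' ellipses over the constant background depth: each pixel holds the depth of
#' the nearest fin covering it, or `background_depth_m`.
#'
#' @param truth A [scene_truth][simulate_trajectories()] object.
#' @return A function mapping a 0-based frame index to a `height x width`
#'   numeric matrix (meters). Entry `[v + 1, u + 1]` corresponds to pixel
#'   `(u, v)`.
#' @export
make_depth_backend <- function(truth) {
  force(truth)
  cfg <- truth$cfg; calib <- cfg$calib
  function(frame) {
    t <- as.integer(frame) + 1L
    stopifnot(t >= 1, t <= dim(truth$pos)[2])
    Zmap <- matrix(cfg$background_depth_m, nrow = calib$height,
                   ncol = calib$width)
    idx <- which(truth$vis_left[, t])
    if (length(idx)) {
      # painter's order: far to near, nearer fins overwrite
      idx <- idx[order(truth$pos[idx, t, 3], decreasing = TRUE)]
      for (i in idx) {
        e <- fin_ellipse(truth, i, t, "left")
        us <- max(floor(e$u - e$a), 0):min(ceiling(e$u + e$a), calib$width - 1)
        vs <- max(floor(e$v - e$b), 0):min(ceiling(e$v + e$b), calib$height - 1)
        uu <- rep(us, times = length(vs)); vv <- rep(vs, each = length(us))
        inside <- ((uu - e$u) / e$a)^2 + ((vv - e$v) / e$b)^2 <= 1
        Zmap[cbind(vv[inside] + 1, uu[inside] + 1)] <- truth$pos[i, t, 3]
      }
    }
    Zmap
  }
}

#' @export
print.fin_scene <- function(x, ...) {
  cat(sprintf(
    "fin_scene: %d fish, %d frames, %d detections, %d matches (seed %d)\n",
    x$cfg$n_fish, x$cfg$n_frames, nrow(x$detections), nrow(x$matches),
    x$cfg$seed))
  invisible(x)
}
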