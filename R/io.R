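# Readers and writers for the external formats: calibration config
# (JSON, optionally YAML), MOT-style detection CSV, feature-match CSV, mask
# JSON (per-frame pixel coordinate lists), plain-text depth rasters, and the
# full simulator fixture bundle. All deliberately plain-text.

#' Read a stereo calibration config
#'
#' JSON (always) or YAML (if the `yaml` package is installed) with exactly the
#' keys `fx`, `fy`, `cx`, `cy`, `baseline_mm`, `width`, `height`. Unknown or
#' missing keys are errors (strict schema).
#'
#' @param path File path; format inferred from the extension
#'   (`.json` / `.yaml` / `.yml`).
#' @return A [stereo_calibration()].
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML calibration requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keys <- c("fx", "fy", "cx", "cy", "baseline_mm", "width", "height")
  extra <- setdiff(names(raw), keys)
  missing <- setdiff(keys, names(raw))
  if (length(missing)) stop("calibration config missing keys: ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("calibration config has unknown keys: ",
                          paste(extra, collapse = ", "))
  if (!all(vapply(raw[keys], function(x) is.numeric(x) && length(x) == 1,
                  logical(1)))) {
    stop("calibration values must be scalar numerics")
  }
  stereo_calibration(fx = raw$fx, fy = raw$fy, cx = raw$cx, cy = raw$cy,
                     baseline_mm = raw$baseline_mm, width = raw$width,
                     height = raw$height)
}

#' Write a stereo calibration config as JSON
#' @param calib A [stereo_calibration()].
#' @param path Output path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "stereo_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write MOT-style detection CSV
#'
#' Columns `frame,id,x,y,w,h,conf,class` (header required, UTF-8); `id` is -1
#' for raw detections.
#'
#' @param path CSV path.
#' @return Data frame with those columns.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "id", "x", "y", "w", "h", "conf")
  if (!all(req %in% names(d))) {
    stop("detection CSV must have header columns ", paste(req, collapse = ","))
  }
  if (is.null(d$class)) d$class <- "object"
  d
}

#' @rdname read_detections
#' @param detections Data frame with at least `frame,x,y,w,h,conf`; `id` and
#'   `class` are filled in if absent.
#' @export
write_detections <- function(detections, path) {
  d <- detections
  if (is.null(d$id)) d$id <- -1L
  if (is.null(d$class)) d$class <- "caudal_fin"
  utils::write.csv(d[, c("frame", "id", "x", "y", "w", "h", "conf", "class")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write feature-match CSV (`frame,xl,yl,xr,yr,conf`)
#' @param path CSV path.
#' @export
read_matches <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "xl", "yl", "xr", "yr", "conf")
  if (!all(req %in% names(m))) {
    stop("match CSV must have header columns ", paste(req, collapse = ","))
  }
  m[, req]
}

#' @rdname read_matches
#' @param matches Data frame with columns `frame,xl,yl,xr,yr,conf`.
#' @export
write_matches <- function(matches, path) {
  utils::write.csv(matches[, c("frame", "xl", "yl", "xr", "yr", "conf")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Masks for one side as JSON: array of {frame, det, box, u, v}.
write_masks_json <- function(masks, path) {
  items <- list()
  for (key in names(masks)) {
    for (m in masks[[key]]) {
      if (is.null(m)) next
      items[[length(items) + 1L]] <- list(
        frame = m$frame, side = m$side,
        det = length(items) * 0L + NA_integer_,  # fixed below
        box = m$parent_box, u = m$u, v = m$v)
    }
  }
  # det indices: position within the frame/side group, in written order
  if (length(items)) {
    grp <- paste(vapply(items, function(x) x$frame, integer(1)),
                 vapply(items, function(x) x$side, character(1)))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      for (k in seq_along(idx)) items[[idx[k]]]$det <- k
    }
  }
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_masks_json <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (it in items) {
    key <- paste0(it$frame, ":", it$side)
    m <- mask_region(unlist(it$u), unlist(it$v), frame = it$frame,
                     side = it$side,
                     parent_box = if (!is.null(it$box)) unlist(it$box))
    if (is.null(out[[key]])) out[[key]] <- list()
    out[[key]][[it$det]] <- m
  }
  out
}

#' Write a simulated scene to a fixture directory
#'
#' Emits per-side MOT detection CSVs, mask JSON, match CSV, ground-truth CSV,
#' calibration JSON and a manifest recording the generator config and seed.
#' Depth rasters (one whitespace-separated text matrix per frame) are written
#' only on request: they are large, and in-memory scenes carry a lazy raster
#' backend instead.
#'
#' @param scene A `fin_scene` from [render_observations()].
#' @param dir Output directory (created if needed).
#' @param write_depth Write per-frame depth rasters under `depth/`.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, write_depth = FALSE) {
  stopifnot(inherits(scene, "fin_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scene$cfg
  write_calibration(cfg$calib, file.path(dir, "calibration.json"))
  man <- unclass(cfg)
  man$calib <- NULL
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (side in c("left", "right")) {
    d <- scene$detections[scene$detections$side == side, , drop = FALSE]
    write_detections(d[order(d$frame, d$det),
                       c("frame", "x", "y", "w", "h", "conf")],
                     file.path(dir, paste0("detections_", side, ".csv")))
    keys <- names(scene$masks)[endsWith(names(scene$masks), paste0(":", side))]
    write_masks_json(scene$masks[keys],
                     file.path(dir, paste0("masks_", side, ".json")))
  }
  write_matches(scene$matches, file.path(dir, "matches.csv"))
  tr <- scene$truth
  nf <- dim(tr$pos)[1]; nt <- dim(tr$pos)[2]
  truth_df <- do.call(rbind, lapply(seq_len(max(nt, 0)), function(t) {
    data.frame(frame = t - 1L, fish = seq_len(nf),
               X = tr$pos[, t, 1], Y = tr$pos[, t, 2], Z = tr$pos[, t, 3],
               orient = tr$orient[, t],
               vis_left = tr$vis_left[, t], vis_right = tr$vis_right[, t])
  }))
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  if (write_depth) {
    ddir <- file.path(dir, "depth")
    dir.create(ddir, showWarnings = FALSE)
    for (t in seq_len(nt)) {
      utils::write.table(scene$depth_map(t - 1L),
                         file.path(ddir, sprintf("frame_%05d.tsv", t - 1L)),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a scene fixture directory back into memory
#'
#' Inverse of [write_scene()]. The ground truth (and with it the lazy depth
#' raster backend) is reconstructed from `truth.csv`; written depth rasters,
#' when present, take precedence for the raster backend.
#'
#' @param dir Directory written by [write_scene()] (or assembled by hand with
#'   the same layout).
#' @return A `fin_scene`.
#' @export
read_scene <- function(dir) {
  calib <- read_calibration(file.path(dir, "calibration.json"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- scene_config(
    n_fish = man$n_fish, n_frames = man$n_frames, fps = man$fps, calib = calib,
    volume = list(xlim = man$volume$xlim, ylim = man$volume$ylim,
                  zlim = man$volume$zlim),
    speed_mean = man$speed_mean, speed_sd = man$speed_sd,
    turn_sd = man$turn_sd, fin_halfwidth_m = man$fin_halfwidth_m,
    fin_aspect = man$fin_aspect, pixel_noise_sd = man$pixel_noise_sd,
    dropout_p = man$dropout_p, conf_beta = man$conf_beta,
    n_matches_per_fin = man$n_matches_per_fin,
    match_jitter_sd = man$match_jitter_sd,
    n_clutter_matches = man$n_clutter_matches,
    background_depth_m = man$background_depth_m, seed = man$seed)

  dets <- list()
  for (side in c("left", "right")) {
    d <- read_detections(file.path(dir, paste0("detections_", side, ".csv")))
    if (nrow(d)) {
      d$side <- side
      d$truth_id <- NA_integer_
      d <- d[order(d$frame), , drop = FALSE]
      d$det <- stats::ave(seq_len(nrow(d)), d$frame,
                          FUN = seq_along)
      dets[[side]] <- d[, c("frame", "side", "x", "y", "w", "h", "conf",
                            "truth_id", "det")]
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(frame = integer(0), side = character(0), x = numeric(0),
               y = numeric(0), w = numeric(0), h = numeric(0),
               conf = numeric(0), truth_id = integer(0), det = integer(0))
  rownames(detections) <- NULL

  masks <- c(read_masks_json(file.path(dir, "masks_left.json")),
             read_masks_json(file.path(dir, "masks_right.json")))

  matches <- read_matches(file.path(dir, "matches.csv"))

  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    td <- utils::read.csv(tf)
    nf <- cfg$n_fish; nt <- cfg$n_frames
    pos <- array(NA_real_, c(nf, nt, 3))
    orient <- matrix(0, nf, max(nt, 1))
    vl <- matrix(FALSE, nf, nt); vr <- matrix(FALSE, nf, nt)
    pos[cbind(td$fish, td$frame + 1, 1)] <- td$X
    pos[cbind(td$fish, td$frame + 1, 2)] <- td$Y
    pos[cbind(td$fish, td$frame + 1, 3)] <- td$Z
    orient[cbind(td$fish, td$frame + 1)] <- td$orient
    vl[cbind(td$fish, td$frame + 1)] <- td$vis_left
    vr[cbind(td$fish, td$frame + 1)] <- td$vis_right
    truth <- structure(list(pos = pos, orient = orient, cfg = cfg,
                            vis_left = vl, vis_right = vr),
                       class = "scene_truth")
  }

  ddir <- file.path(dir, "depth")
  depth_map <- if (dir.exists(ddir)) {
    function(frame) {
      unname(as.matrix(utils::read.table(
        file.path(ddir, sprintf("frame_%05d.tsv", as.integer(frame))))))
    }
  } else if (!is.null(truth)) {
    make_depth_backend(truth)
  }

  structure(list(cfg = cfg, truth = truth, detections = detections,
                 masks = masks, matches = matches, depth_map = depth_map),
            class = "fin_scene")
}

#' Packaged worked-example tables
#'
#' Small plain-text fixtures shipped with the package: `example_depth_table()`
#' returns per-individual depth estimates of the four pipelines for one frame
#' of field footage (nine tracked fish); `example_case_table()` returns the
#' per-case mean +/- sd closest-fish distances of the four pipelines together
#' with the independent sonar reference for the six object cases (BY, BW, CY,
#' CW, SY, SW: big/small cylinder or cube, yellow or white).
#'
#' @return A data frame.
#' @export
example_depth_table <- function() {
  utils::read.csv(system.file("extdata", "example_depth_ranking.csv",
                              package = "fintrack3d"))
}

#' @rdname example_depth_table
#' @export
example_case_table <- function() {
  utils::read.csv(system.file("extdata", "example_case_distances.csv",
                              package = "fintrack3d"))
}
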