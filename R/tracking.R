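# Multi-object tracking of caudal-fin detections. Association follows the
# two-stage (high/low confidence) IOU scheme popularised by ByteTrack: the
# field study's tracker parameters were never published, so the defaults here
# are package conventions, documented and configurable. No motion model is
# applied by default: association is against the last observed box.

#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` with `(x, y)` the top-left corner, in pixels.
#'
#' @param boxA,boxB Numeric vectors of length 4.
#' @return IOU in `[0, 1]`; 1 iff identical, 0 iff disjoint.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 2, 2))  # 1/7
#' @export
iou <- function(boxA, boxB) {
  stopifnot(length(boxA) == 4, length(boxB) == 4)
  if (boxA[3] <= 0 || boxA[4] <= 0 || boxB[3] <= 0 || boxB[4] <= 0) {
    stop("degenerate box: w and h must be positive")
  }
  iou_matrix(matrix(boxA, 1), matrix(boxB, 1))[1, 1]
}

# Vectorised IOU between two sets of boxes given as n x 4 matrices.
iou_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 4)
  B <- matrix(as.numeric(B), ncol = 4)
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  ax1 <- A[, 1]; ay1 <- A[, 2]; ax2 <- A[, 1] + A[, 3]; ay2 <- A[, 2] + A[, 4]
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  ix <- pmax(outer(ax1, bx1, pmin) * 0,
             outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax))
  iy <- pmax(outer(ay1, by1, pmin) * 0,
             outer(ay2, by2, pmin) - outer(ay1, by1, pmax))
  inter <- ix * iy
  areaA <- A[, 3] * A[, 4]
  areaB <- B[, 3] * B[, 4]
  un <- outer(areaA, areaB, "+") - inter
  inter / un
}

#' Default tracker parameters
#'
#' Two-stage association thresholds: detections with confidence at or above
#' `conf_high` drive track creation and first-stage matching (gate
#' `iou_gate_high`); detections in `[conf_low, conf_high)` are used only to
#' rescue unmatched active tracks (gate `iou_gate_low`). Tracks unmatched for
#' more than `track_buffer` frames are removed.
#'
#' @return A named list of parameters.
#' @export
tracker_params <- function(conf_high = 0.5, conf_low = 0.1,
                           iou_gate_high = 0.2, iou_gate_low = 0.5,
                           track_buffer = 30) {
  stopifnot(conf_low >= 0, conf_high >= conf_low, conf_high <= 1,
            iou_gate_high >= 0, iou_gate_high <= 1,
            iou_gate_low >= 0, iou_gate_low <= 1,
            track_buffer >= 0)
  list(conf_high = conf_high, conf_low = conf_low,
       iou_gate_high = iou_gate_high, iou_gate_low = iou_gate_low,
       track_buffer = track_buffer)
}

#' Track detections across frames
#'
#' Two-stage IOU association. Per frame: (1) active and lost tracks are
#' assigned to high-confidence detections by minimum-cost assignment on
#' `1 - IOU`, gated at `iou_gate_high`; (2) remaining *active* tracks are
#' matched against low-confidence detections, gated at `iou_gate_low` (lost
#' tracks may only be recovered in stage 1). Unmatched high-confidence
#' detections spawn new tracks; tracks unmatched for more than `track_buffer`
#' frames are removed and their IDs never reused.
#'
#' Determinism: within every frame detections are put in a canonical order
#' (decreasing confidence, then x, y, w, h) before association and tracks are
#' ordered by increasing ID, so the output is invariant under permutation of
#' the within-frame detection order.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`, `w`, `h`,
#'   `conf` (additional columns are carried along). Frames need not be
#'   contiguous; missing frames count toward the lost-track buffer.
#' @param params See [tracker_params()].
#' @return An object of class `fin_tracks`: a list with
#'   \describe{
#'   \item{tracks}{list of per-track records (`track_id`, `state`, `history`
#'     data frame of `frame`, `x`, `y`, `w`, `h`, `conf`).}
#'   \item{assignments}{data frame mapping input rows to tracks: `row`
#'     (row index into `detections`), `frame`, `track_id`.}
#'   }
#' @export
track_sequence <- function(detections, params = tracker_params()) {
  req <- c("frame", "x", "y", "w", "h", "conf")
  if (!all(req %in% names(detections))) {
    stop("detections must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(detections) == 0) {
    return(structure(list(tracks = list(),
                          assignments = data.frame(row = integer(0),
                                                   frame = integer(0),
                                                   track_id = integer(0))),
                     class = "fin_tracks"))
  }
  stopifnot(all(detections$w > 0), all(detections$h > 0),
            all(detections$conf >= 0), all(detections$conf <= 1))

  tracks <- list()          # all tracks ever created
  pool <- integer(0)        # indices of active/lost tracks
  next_id <- 1L
  assign_rows <- integer(0); assign_frames <- integer(0); assign_ids <- integer(0)

  frames <- sort(unique(detections$frame))
  det_frame <- detections$frame
  for (f in frames) {
    rows <- which(det_frame == f)
    d <- detections[rows, , drop = FALSE]
    # canonical within-frame order for deterministic tie-breaking
    ord <- order(-d$conf, d$x, d$y, d$w, d$h)
    rows <- rows[ord]; d <- d[ord, , drop = FALSE]

    # expire tracks that have been lost for longer than the buffer
    if (length(pool)) {
      expired <- vapply(pool, function(k) {
        f - tracks[[k]]$last_frame > params$track_buffer
      }, logical(1))
      for (k in pool[expired]) tracks[[k]]$state <- "removed"
      pool <- pool[!expired]
    }
    pool <- pool[order(vapply(pool, function(k) tracks[[k]]$track_id, integer(1)))]

    hi <- which(d$conf >= params$conf_high)
    lo <- which(d$conf >= params$conf_low & d$conf < params$conf_high)

    match_stage <- function(track_idx, det_idx, gate) {
      # returns matrix of (pool position, det position) matches
      if (!length(track_idx) || !length(det_idx)) {
        return(matrix(integer(0), ncol = 2))
      }
      tb <- t(vapply(track_idx, function(k) tracks[[k]]$last_box, numeric(4)))
      db <- as.matrix(d[det_idx, c("x", "y", "w", "h")])
      m <- iou_matrix(tb, db)
      sel <- assign_stereo(1 - m, min_iou = max(gate, 1e-12))
      cbind(track_idx[sel$left], det_idx[sel$right])
    }

    m1 <- match_stage(pool, hi, params$iou_gate_high)
    matched_tracks <- m1[, 1]; matched_dets <- m1[, 2]

    rem_active <- setdiff(pool[vapply(pool, function(k)
      tracks[[k]]$state == "active", logical(1))], matched_tracks)
    m2 <- match_stage(rem_active, lo, params$iou_gate_low)
    matched_tracks <- c(matched_tracks, m2[, 1])
    matched_dets <- c(matched_dets, m2[, 2])

    if (length(matched_tracks)) {
      for (ii in seq_along(matched_tracks)) {
        k <- matched_tracks[ii]; j <- matched_dets[ii]
        tracks[[k]]$history <- rbind(tracks[[k]]$history,
          data.frame(frame = f, x = d$x[j], y = d$y[j], w = d$w[j],
                     h = d$h[j], conf = d$conf[j]))
        tracks[[k]]$last_box <- c(d$x[j], d$y[j], d$w[j], d$h[j])
        tracks[[k]]$last_frame <- f
        tracks[[k]]$state <- "active"
        assign_rows <- c(assign_rows, rows[j])
        assign_frames <- c(assign_frames, f)
        assign_ids <- c(assign_ids, tracks[[k]]$track_id)
      }
    }

    # unmatched tracks fall to "lost"
    for (k in setdiff(pool, matched_tracks)) {
      if (tracks[[k]]$state == "active") tracks[[k]]$state <- "lost"
    }

    # unmatched high-confidence detections spawn new tracks
    for (j in setdiff(hi, matched_dets)) {
      tracks[[length(tracks) + 1L]] <- list(
        track_id = next_id,
        state = "active",
        history = data.frame(frame = f, x = d$x[j], y = d$y[j], w = d$w[j],
                             h = d$h[j], conf = d$conf[j]),
        last_box = c(d$x[j], d$y[j], d$w[j], d$h[j]),
        last_frame = f)
      pool <- c(pool, length(tracks))
      assign_rows <- c(assign_rows, rows[j])
      assign_frames <- c(assign_frames, f)
      assign_ids <- c(assign_ids, next_id)
      next_id <- next_id + 1L
    }
  }

  structure(list(
    tracks = tracks,
    assignments = data.frame(row = assign_rows, frame = assign_frames,
                             track_id = assign_ids)
  ), class = "fin_tracks")
}

#' @export
print.fin_tracks <- function(x, ...) {
  cat(sprintf("fin_tracks: %d tracks, %d assigned detections\n",
              length(x$tracks), nrow(x$assignments)))
  invisible(x)
}
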