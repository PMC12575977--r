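# Shared test helpers: independent oracles and tiny scene builders.

# All permutations of 1..n (n small), one per row.
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Exhaustive minimum-cost assignment on a (possibly rectangular) matrix:
# pads to square with a large constant, enumerates all permutations, and
# returns the minimum total over the real entries.
brute_min_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  pad <- max(abs(cost)) * n + 1
  m <- matrix(pad, n, n)
  m[seq_len(nr), seq_len(nc)] <- cost
  P <- perms(n)
  vals <- m[cbind(rep(seq_len(n), nrow(P)), as.vector(t(P)))]
  totals <- rowSums(matrix(vals, nrow(P), n, byrow = TRUE))
  min(totals) - (n - min(nr, nc)) * pad
}

# Total cost of a solve_assignment() result over the real entries.
assignment_cost <- function(cost, a) {
  i <- which(!is.na(a))
  sum(cost[cbind(i, a[i])])
}

# Small noiseless scene used across pipeline tests.
noiseless_config <- function(n_fish = 2, n_frames = 25, seed = 7, ...) {
  scene_config(n_fish = n_fish, n_frames = n_frames, pixel_noise_sd = 0,
               dropout_p = 0, match_jitter_sd = 0, n_clutter_matches = 0,
               conf_beta = c(60, 2),  # keep all detections above conf_high
               seed = seed, ...)
}

# Per-record 3D error against the nearest ground-truth fish in that frame.
nearest_truth_error <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(k) {
    t <- records$frame[k] + 1
    p <- truth$pos[, t, , drop = FALSE]
    min(sqrt((p[, 1, 1] - records$X[k])^2 + (p[, 1, 2] - records$Y[k])^2 +
             (p[, 1, 3] - records$Z[k])^2))
  }, numeric(1))
}

# Per-record depth error against the nearest ground-truth depth in that frame.
nearest_truth_z_error <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(k) {
    min(abs(truth$pos[, records$frame[k] + 1, 3] - records$Z[k]))
  }, numeric(1))
}

# Hand-built detection stream: one row per (frame, box).
det_stream <- function(frames, x, y = 100, w = 40, h = 30, conf = 0.9) {
  n <- length(frames)
  data.frame(frame = frames, x = rep_len(x, n), y = rep_len(y, n),
             w = rep_len(w, n), h = rep_len(h, n), conf = rep_len(conf, n))
}
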