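# Minimum-cost bipartite assignment (Hungarian algorithm, O(n^3) potentials /
# augmenting-path formulation). Implemented in-package because stereo matching
# and the tracker both need it with explicit gating and deterministic
# behaviour, and so tests can check it against an exhaustive permutation
# oracle.

#' Solve a minimum-cost assignment problem
#'
#' Finds the one-to-one row-to-column assignment minimising total cost.
#' Rectangular matrices are padded internally to square with a large constant;
#' padded (virtual) assignments are dropped from the result, so with `n` rows
#' and `m` columns exactly `min(n, m)` pairs are returned.
#'
#' @param cost Numeric matrix of finite costs (rows x columns).
#' @return Integer vector of length `nrow(cost)`: `res[i]` is the column
#'   assigned to row `i`, or `NA` for rows left unassigned (rectangular case).
#' @examples
#' solve_assignment(matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE))  # 1, 2
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (length(cost) == 0) return(integer(0))
  if (!all(is.finite(cost))) stop("assignment costs must be finite")
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  pad <- max(abs(cost)) * n + 1  # larger than any feasible total
  m <- matrix(pad, n, n)
  m[seq_len(nr), seq_len(nc)] <- cost

  # e-maxx style Hungarian: columns 0..n, column 0 virtual; 1-based storage.
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials, v[1] is virtual column 0
  p <- integer(n + 1)    # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- m[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          if (j > 0) v[j + 1] <- v[j + 1] - delta else v[1] <- v[1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  res <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= nr && j <= nc) res[i] <- j
  }
  res
}

#' Gated stereo assignment from an IOU cost matrix
#'
#' Runs [solve_assignment()] on a `1 - IOU` cost matrix and drops, after the
#' optimal assignment, pairs whose IOU falls below `min_iou`. The gate default
#' (0.1) rejects spurious completions the optimiser is forced into on
#' near-disjoint items.
#'
#' @param cost Matrix with entries `1 - IOU(left_i, right_j)`; see
#'   [iou_cost_matrix()].
#' @param min_iou Minimum IOU for a pair to be kept (default 0.1).
#' @return Data frame with one row per retained pair: `left`, `right` (row /
#'   column indices) and `iou`.
#' @export
assign_stereo <- function(cost, min_iou = 0.1) {
  cost <- as.matrix(cost)
  if (length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0) {
    return(data.frame(left = integer(0), right = integer(0), iou = numeric(0)))
  }
  col <- solve_assignment(cost)
  left <- which(!is.na(col))
  right <- col[left]
  iou <- 1 - cost[cbind(left, right)]
  keep <- iou >= min_iou
  data.frame(left = left[keep], right = right[keep], iou = iou[keep])
}
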