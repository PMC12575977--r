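# Behavioural distance statistics: per-frame closest-fish distance, per-case
# aggregation across replicates, MAE with a Student-t 95% CI against an
# independent (sonar) reference, depth-based ranking of individuals, and
# Savitzky-Golay trajectory smoothing.

#' Per-frame minimum distance series
#'
#' For each frame with at least one trajectory record, the minimum
#' `distance_m`; frames without records are absent from the result (missing,
#' excluded from aggregation).
#'
#' @param records A `fin_trajectories` data frame (or any data frame with
#'   `frame` and `distance_m`).
#' @return Data frame `frame`, `min_dist`, ordered by frame.
#' @export
min_distance_series <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(frame = integer(0), min_dist = numeric(0)))
  }
  agg <- stats::aggregate(records$distance_m, by = list(frame = records$frame),
                          FUN = min)
  names(agg)[2] <- "min_dist"
  agg[order(agg$frame), , drop = FALSE]
}

#' Summarise a case across replicates
#'
#' Pools the per-frame minimum distances of all replicates and reports their
#' mean and sample standard deviation (frame-level pooling; the alternative —
#' averaging replicate means first — is available via `agg`). Replicates with
#' no usable frames are dropped and do not count toward `n_replicates`.
#'
#' @param series_list List of [min_distance_series()] results (one per
#'   replicate), or a single such data frame.
#' @param case_label Optional case name (e.g. `"SY"`).
#' @param agg `"pooled"` (default) or `"replicate-means"`.
#' @return List of class `case_summary`: `case_label`, `mean_min_dist`,
#'   `sd_min_dist`, `n_frames`, `n_replicates`.
#' @export
summarize_case <- function(series_list, case_label = NA_character_,
                           agg = c("pooled", "replicate-means")) {
  agg <- match.arg(agg)
  if (is.data.frame(series_list)) series_list <- list(series_list)
  vals <- lapply(series_list, function(s) s$min_dist[is.finite(s$min_dist)])
  usable <- vapply(vals, length, integer(1)) > 0
  vals <- vals[usable]
  if (!length(vals)) stop("all replicates empty: nothing to summarise")
  pooled <- unlist(vals)
  if (agg == "pooled") {
    m <- mean(pooled)
    s <- if (length(pooled) > 1) stats::sd(pooled) else 0
  } else {
    rm_ <- vapply(vals, mean, numeric(1))
    m <- mean(rm_)
    s <- if (length(rm_) > 1) stats::sd(rm_) else 0
  }
  structure(list(case_label = case_label, mean_min_dist = m, sd_min_dist = s,
                 n_frames = length(pooled), n_replicates = length(vals)),
            class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat(sprintf("case %s: %.3f +/- %.3f m (%d frames, %d replicates)\n",
              x$case_label, x$mean_min_dist, x$sd_min_dist, x$n_frames,
              x$n_replicates))
  invisible(x)
}

#' Mean absolute error with Student-t confidence interval
#'
#' Given per-case estimated means and per-case reference values, computes
#' `e_i = |estimate_i - reference_i|`, `MAE = mean(e)` and the interval
#' `MAE +/- t(1 - alpha/2, n - 1) * sd(e) / sqrt(n)` (sample sd). This rule
#' reproduces published per-method error tables computed against a sonar
#' reference to three decimals.
#'
#' @param case_means Numeric vector of per-case estimates (meters).
#' @param reference Numeric vector of the same length: reference values.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return List of class `error_report`: `mae`, `ci_low`, `ci_high`,
#'   `n_cases`, `alpha`.
#' @examples
#' mae_with_ci(c(1.72, 1.19, 1.46, 1.06, 1.64, 1.00),
#'             c(1.72, 0.93, 1.72, 0.99, 1.23, 0.77))
#' @export
mae_with_ci <- function(case_means, reference, alpha = 0.05) {
  if (length(case_means) != length(reference)) {
    stop("case_means and reference must have equal length")
  }
  n <- length(case_means)
  if (n < 2) stop("need at least two cases")
  e <- abs(case_means - reference)
  mae <- mean(e)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(e) / sqrt(n)
  structure(list(mae = mae, ci_low = mae - half, ci_high = mae + half,
                 n_cases = n, alpha = alpha),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("MAE %.3f m, %d%% CI (%.3f, %.3f), n = %d\n", x$mae,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n_cases))
  invisible(x)
}

#' Rank individuals by depth
#'
#' Orders a set of individuals from closest to furthest by their estimated
#' depth; ties are broken by ascending ID.
#'
#' @param depths Named numeric vector (names = individual IDs) or a data
#'   frame with columns `id` and `depth`. Depths must be finite and positive.
#' @return List with `ranking` (data frame `id`, `depth`, `rank`, ordered
#'   closest to furthest), `closest` and `furthest` (single-row data frames).
#' @export
rank_depths <- function(depths) {
  if (is.data.frame(depths)) {
    id <- as.character(depths$id); d <- as.numeric(depths$depth)
  } else {
    id <- names(depths); d <- as.numeric(depths)
    if (is.null(id)) stop("depths must be named by individual ID")
  }
  if (!length(d)) stop("empty input")
  if (any(!is.finite(d)) || any(d <= 0)) stop("depths must be finite and positive")
  idn <- suppressWarnings(as.numeric(id))
  ord <- if (!anyNA(idn)) order(d, idn) else order(d, id)
  ranking <- data.frame(id = id[ord], depth = d[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  list(ranking = ranking,
       closest = ranking[1, , drop = FALSE],
       furthest = ranking[nrow(ranking), , drop = FALSE])
}

# Savitzky-Golay projection matrix: rows = evaluation offsets, fitted on
# window offsets -h..h with the given polynomial order.
sg_hat <- function(window, polyorder) {
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:polyorder, "^")
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay trajectory smoothing
#'
#' Per-coordinate Savitzky-Golay filtering: each interior sample is replaced
#' by the value at the centre of a least-squares polynomial fit over the
#' sliding window; the first and last half-windows are taken from the
#' polynomial fitted to the leading/trailing full window (so polynomials up to
#' `polyorder` are reproduced exactly everywhere). Series shorter than the
#' window are returned unchanged with a warning.
#'
#' @param series Numeric vector, matrix or data frame (columns = coordinates,
#'   rows = frames, assumed equally spaced).
#' @param window Odd window length (default 7).
#' @param polyorder Polynomial order, `< window` (default 2).
#' @return Smoothed object of the same shape as the input.
#' @export
smooth_trajectory <- function(series, window = 7, polyorder = 2) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  was_df <- is.data.frame(series)
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < window) {
    warning("series shorter than window: returned unsmoothed")
    return(series)
  }
  H <- sg_hat(window, polyorder)
  h <- (window - 1) / 2
  out <- x
  for (k in seq_len(ncol(x))) {
    y <- x[, k]
    sm <- numeric(n)
    # interior: centre row of the hat matrix slid along the series
    centre <- H[h + 1, ]
    for (i in (h + 1):(n - h)) sm[i] <- sum(centre * y[(i - h):(i + h)])
    # edges: evaluate the leading/trailing window fit at the edge offsets
    sm[1:h] <- (H %*% y[1:window])[1:h]
    sm[(n - h + 1):n] <- (H %*% y[(n - window + 1):n])[(window - h + 1):window]
    out[, k] <- sm
  }
  if (was_df) as.data.frame(out) else if (is.null(dim(series))) out[, 1] else out
}
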