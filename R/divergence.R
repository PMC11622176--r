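#' Sliding-window paired test of good vs bad population responses
#'
#' A window of `window_ms` is advanced in `step_ms` increments across the time
#' axis; in each window the per-neuron mean Z activity is computed for the
#' good and bad conditions and the two are compared across neurons with a
#' two-sided paired t test. Windows are indexed by their start time and
#' incomplete windows at the range edges are dropped, so a time axis spanning
#' -575..575 ms yields 1,101 complete 50-ms windows starting at -575..525 ms.
#'
#' @param z_good,z_bad matrices (neurons x time) of Z traces, same neuron
#'   order in both.
#' @param time_ms time axis (1-ms grid) matching the matrix columns.
#' @param window_ms window length, ms.
#' @param step_ms window increment, ms.
#' @return data frame with `window_start_ms`, `t`, `p` per window.
#' @export
sliding_paired_test <- function(z_good, z_bad, time_ms, window_ms = 50,
                                step_ms = 1) {
  stopifnot(identical(dim(z_good), dim(z_bad)), ncol(z_good) == length(time_ms))
  n <- nrow(z_good)
  if (n < 3) stop("paired test requires at least three neurons", call. = FALSE)
  d <- z_good - z_bad
  # window means via cumulative sums: mean over columns [s, s+w-1]
  cs <- cbind(0, t(apply(d, 1, cumsum)))
  w <- window_ms
  if (ncol(d) <= w) stop("time axis shorter than one window", call. = FALSE)
  starts <- seq(1L, ncol(d) - w, by = step_ms)
  wm <- (cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]) / w
  mu <- colMeans(wm)
  se <- apply(wm, 2, stats::sd) / sqrt(n)
  # se = 0 means every neuron shows the same difference: zero evidence when the
  # common difference is 0, unambiguous evidence otherwise
  tstat <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  data.frame(window_start_ms = time_ms[starts], t = tstat, p = p)
}

#' Divergence onset from a sliding-window p-value series
#'
#' The onset is the start time of the first run of at least `run_length`
#' consecutive windows with `p < alpha`; requiring a sustained run controls
#' the false-positive rate without a multiple-comparison correction across
#' windows. Returns `NA` when no such run exists.
#'
#' @param p_series data frame from [sliding_paired_test()] (or a numeric
#'   p-value vector with a parallel `window_start_ms` vector).
#' @param alpha per-window significance level.
#' @param run_length minimum number of consecutive significant windows.
#' @param window_start_ms window start times when `p_series` is a bare vector.
#' @param search_from if given, only runs whose first window starts at or
#'   after this time are eligible (e.g. `search_from = 0` restricts the onset
#'   search to post-stimulus windows; the significance mask is still returned
#'   for the whole grid). Default `NULL` searches the full grid.
#' @return list with `onset_ms` (NA if none) and `significant` (logical mask
#'   per window).
#' @export
onset_from_pseries <- function(p_series, alpha = 0.05, run_length = 10,
                               window_start_ms = NULL, search_from = NULL) {
  if (is.data.frame(p_series)) {
    p <- p_series$p; starts <- p_series$window_start_ms
  } else {
    p <- p_series
    starts <- window_start_ms %||% seq_along(p)
  }
  sig <- p < alpha
  search <- sig
  if (!is.null(search_from)) search[starts < search_from] <- FALSE
  r <- rle(search)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  onset <- if (length(hit)) starts[ends[hit[1]] - r$lengths[hit[1]] + 1L] else NA_real_
  list(onset_ms = onset, significant = sig)
}
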