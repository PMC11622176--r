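#' Minimum-jerk position profile
#'
#' Fraction of movement completed at normalized time `s` in `[0, 1]`:
#' `10 s^3 - 15 s^4 + 6 s^5`. Peak speed is `1.875 * amplitude / duration`,
#' so a 15-degree, 30-ms saccade peaks near 940 deg/s, far above the
#' 40 deg/s detection threshold.
#'
#' @param s normalized time, clamped to `[0, 1]`.
#' @return completion fraction in `[0, 1]`.
#' @keywords internal
min_jerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# add one saccade (in place on x/y vectors) from (x0,y0) to (x1,y1)
# starting at time t_start; t is the sample time vector
add_saccade <- function(t, x, y, t_start, from, to, dur_ms) {
  s <- (t - t_start) / dur_ms
  w <- min_jerk(s)
  active <- t >= t_start
  x[active] <- from[1] + (to[1] - from[1]) * w[active]
  y[active] <- from[2] + (to[2] - from[2]) * w[active]
  list(x = x, y = y)
}

#' Generate a 1 kHz eye-position trace for one target presentation
#'
#' Builds the gaze trajectory implied by an action label: `accept` saccades to
#' the target at `rt_ms` and holds inside the target window for at least the
#' acceptance duration; `return` saccades to the target and leaves the window
#' again in under that duration; `stay` never leaves the centre zone; `other`
#' saccades to a location outside both the target window and the centre zone;
#' `fixbreak` leaves the centre zone before target onset. Saccades follow a
#' minimum-jerk profile and white Gaussian position noise is added.
#'
#' @param target_pos numeric length-2, target position (x, y) in degrees.
#' @param action one of `"accept"`, `"return"`, `"stay"`, `"other"`,
#'   `"fixbreak"`.
#' @param rt_ms saccade onset time relative to target onset, ms; required for
#'   saccadic actions.
#' @param config a [task_config()].
#' @param dwell_ms for `return`, time spent near the target before the return
#'   saccade starts, ms (default drawn uniformly from 120-300 ms).
#' @return an object of class `eye_trace`: a data frame with columns `t_ms`
#'   (relative to target onset), `x_deg`, `y_deg`.
#' @export
generate_eye_trace <- function(target_pos, action, rt_ms = NA,
                               config = task_config(), dwell_ms = NULL) {
  action <- match.arg(action, c("accept", "return", "stay", "other", "fixbreak"))
  needs_rt <- action %in% c("accept", "return", "other")
  if (needs_rt) {
    if (!is.finite(rt_ms) || rt_ms <= 0)
      stop("rt_ms must be a positive time for saccadic actions", call. = FALSE)
    if (rt_ms + config$saccade_duration_ms >= config$trace_post_ms)
      stop("rt_ms exceeds the target epoch covered by the trace", call. = FALSE)
  }
  dt <- 1000 / config$eye_rate_hz
  t <- seq(-config$trace_pre_ms, config$trace_post_ms, by = dt)
  x <- numeric(length(t)); y <- numeric(length(t))
  dur <- config$saccade_duration_ms
  ctr <- c(0, 0)

  if (action %in% c("accept", "return")) {
    res <- add_saccade(t, x, y, rt_ms, ctr, target_pos, dur)
    x <- res$x; y <- res$y
    if (action == "return") {
      if (is.null(dwell_ms)) dwell_ms <- stats::runif(1, 120, 300)
      t_back <- rt_ms + dur + dwell_ms
      res <- add_saccade(t, x, y, t_back, target_pos, ctr, dur)
      x <- res$x; y <- res$y
    }
  } else if (action == "other") {
    # land away from both the target window and the centre zone
    ang <- atan2(target_pos[2], target_pos[1]) + 2 * pi / 3
    ecc <- sqrt(sum(target_pos^2))
    land <- ecc * c(cos(ang), sin(ang))
    res <- add_saccade(t, x, y, rt_ms, ctr, land, dur)
    x <- res$x; y <- res$y
  } else if (action == "fixbreak") {
    t_fb <- stats::runif(1, -min(250, config$trace_pre_ms - 20), -60)
    ang <- stats::runif(1, 0, 2 * pi)
    land <- 10 * c(cos(ang), sin(ang))
    res <- add_saccade(t, x, y, t_fb, ctr, land, dur)
    x <- res$x; y <- res$y
  } # stay: remain at centre

  if (config$eye_noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, config$eye_noise_sd)
    y <- y + stats::rnorm(length(t), 0, config$eye_noise_sd)
  }
  structure(data.frame(t_ms = t, x_deg = x, y_deg = y),
            class = c("eye_trace", "data.frame"),
            target_pos = target_pos, action_generated = action)
}
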