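#' Detect saccades in an eye trace
#'
#' Instantaneous speed is estimated by central differences of position,
#' smoothed with a short boxcar, and thresholded: a saccade onset is the first
#' sample of an upward crossing of `speed_threshold` within the epoch, with a
#' refractory gap separating successive events. The default 40 deg/s threshold
#' applied within 400 ms of target onset defines the saccade reaction time.
#'
#' @param trace an `eye_trace` (data frame with `t_ms`, `x_deg`, `y_deg`),
#'   uniformly sampled.
#' @param speed_threshold speed threshold, deg/s.
#' @param epoch length-2 window (ms, relative to target onset) within which
#'   onsets are accepted.
#' @param smooth_ms boxcar width for speed smoothing, ms (odd number of
#'   samples recommended).
#' @param refractory_ms minimum separation between events, ms.
#' @return data frame with one row per saccade: `onset_ms`, `peak_speed`,
#'   `landing_x`, `landing_y`. Zero rows if no crossing.
#' @export
detect_saccades <- function(trace, speed_threshold = 40, epoch = c(0, 400),
                            smooth_ms = 5, refractory_ms = 20) {
  t <- trace$t_ms
  dt <- diff(t)
  if (length(dt) < 2 || any(abs(dt - dt[1]) > 1e-6))
    stop("eye trace must be uniformly sampled", call. = FALSE)
  dt <- dt[1]
  n <- length(t)
  k <- max(1L, round(smooth_ms / dt))
  # boxcar-smooth positions and velocity components before taking the speed
  # magnitude: smoothing the (positive, Rayleigh-distributed) speed itself
  # would not average tracker noise out
  xs <- boxcar(trace$x_deg, k); ys <- boxcar(trace$y_deg, k)
  vx <- boxcar(c(0, (xs[3:n] - xs[1:(n - 2)]) / (2 * dt), 0) * 1000, k)
  vy <- boxcar(c(0, (ys[3:n] - ys[1:(n - 2)]) / (2 * dt), 0) * 1000, k)
  speed <- sqrt(vx^2 + vy^2)

  in_epoch <- t >= epoch[1] & t <= epoch[2]
  above <- speed > speed_threshold & in_epoch
  ups <- which(above & !c(FALSE, above[-n]))
  if (length(ups) == 0)
    return(data.frame(onset_ms = numeric(0), peak_speed = numeric(0),
                      landing_x = numeric(0), landing_y = numeric(0)))
  onsets <- t[ups]
  keep <- c(TRUE, diff(onsets) >= refractory_ms)
  ups <- ups[keep]; onsets <- onsets[keep]
  out <- lapply(seq_along(ups), function(i) {
    i0 <- ups[i]
    i1 <- min(n, i0 + round(80 / dt))          # saccades end well within 80 ms
    below <- which(speed[i0:i1] < speed_threshold)
    i_land <- if (length(below)) i0 + below[1] - 1L else i1
    data.frame(onset_ms = onsets[i], peak_speed = max(speed[i0:i1]),
               landing_x = trace$x_deg[i_land], landing_y = trace$y_deg[i_land])
  })
  do.call(rbind, out)
}

#' Classify the action of one target presentation
#'
#' Applies the task's action taxonomy to an eye trace: `accept` if gaze enters
#' the square window around the target and stays inside for at least
#' `hold_ms`; `return` if it enters and leaves again in under `hold_ms`;
#' `fixbreak` if gaze leaves the centre zone before target onset; `stay` if
#' gaze never leaves the centre zone; `other` if a gaze shift lands outside
#' both the target window and the centre zone. Excursions out of a region
#' shorter than `gap_tolerance_ms` are bridged (blink/noise tolerance). The
#' reaction time is the first saccade onset within `rt_epoch_ms` of target
#' onset and is reported for target-directed actions (accept, return).
#'
#' @param trace an `eye_trace` covering the target epoch.
#' @param target_pos target position (x, y), degrees.
#' @param window_side side of the square target window, degrees.
#' @param hold_ms dwell time distinguishing accept from return, ms.
#' @param center_zone_radius radius of the centre zone, degrees.
#' @param speed_threshold saccade detection threshold, deg/s.
#' @param rt_epoch_ms reaction-time acceptance epoch after target onset, ms.
#' @param gap_tolerance_ms excursions shorter than this do not break a dwell.
#' @return a list of class `action_label`: `label` and `rt_ms` (NA unless the
#'   action is target-directed).
#' @export
classify_action <- function(trace, target_pos, window_side = 8, hold_ms = 400,
                            center_zone_radius = 4, speed_threshold = 40,
                            rt_epoch_ms = 400, gap_tolerance_ms = 10) {
  t <- trace$t_ms
  if (max(t) < hold_ms + 100)
    stop("eye trace shorter than the target epoch", call. = FALSE)
  half <- window_side / 2
  dx <- abs(trace$x_deg - target_pos[1]); dy <- abs(trace$y_deg - target_pos[2])
  in_window <- dx <= half & dy <= half
  r_center <- sqrt(trace$x_deg^2 + trace$y_deg^2)
  in_center <- r_center <= center_zone_radius
  dt <- t[2] - t[1]
  gap_n <- max(1L, round(gap_tolerance_ms / dt))

  pre <- t < 0
  if (any(pre) && any(run_longer(!in_center & pre, gap_n)))
    return(structure(list(label = "fixbreak", rt_ms = NA_real_),
                     class = "action_label"))

  post <- t >= 0
  in_window_post <- bridge_gaps(in_window & post, gap_n)
  sac <- detect_saccades(trace, speed_threshold, epoch = c(0, rt_epoch_ms))
  rt <- if (nrow(sac)) sac$onset_ms[1] else NA_real_

  entry_idx <- which(in_window_post)[1]
  if (!is.na(entry_idx) && !is.na(rt)) {
    run_end <- entry_idx
    while (run_end < length(t) && in_window_post[run_end + 1L]) run_end <- run_end + 1L
    if (run_end == length(t)) {
      dwell <- t[run_end] - t[entry_idx]
      label <- if (dwell >= hold_ms) "accept" else "return"  # truncated dwell at trace end
    } else {
      dwell <- t[run_end + 1L] - t[entry_idx]
      label <- if (dwell >= hold_ms) "accept" else "return"
    }
    return(structure(list(label = label, rt_ms = rt), class = "action_label"))
  }
  out_center <- run_longer(!in_center & post, gap_n)
  label <- if (any(out_center)) "other" else "stay"
  structure(list(label = label, rt_ms = NA_real_), class = "action_label")
}

# centered boxcar smoothing with edge replication (no NA at the ends)
boxcar <- function(x, k) {
  if (k <= 1L) return(x)
  half <- k %/% 2
  padded <- c(rep(x[1], half), x, rep(x[length(x)], k - half - 1L))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[(half + 1L):(half + length(x))]
}

# TRUE where x is TRUE within a run of length >= n
run_longer <- function(x, n) {
  r <- rle(x)
  r$values <- r$values & r$lengths >= n
  inverse.rle(r)
}

# set FALSE-runs shorter than n (flanked by TRUE) to TRUE
bridge_gaps <- function(x, n) {
  r <- rle(x)
  if (length(r$values) > 2) {
    inner <- 2:(length(r$values) - 1)
    fix <- inner[!r$values[inner] & r$lengths[inner] < n]
    r$values[fix] <- TRUE
  }
  inverse.rle(r)
}

#' Tabulate chosen actions for bad objects per scene
#'
#' @param trials data frame with columns `scene`, `value`, `action` (labels in
#'   accept/return/stay/other/fixbreak); only bad-object presentations are
#'   counted, matching the convention of published action-count tables.
#' @param scenes scene identifiers to tabulate.
#' @return data frame of class `action_count_table` with per-scene columns
#'   `total`, `accept`, `return`, `stay`, `other`, `fixbreak`;
#'   `total` equals the sum of the five action counts by construction.
#' @export
action_count_table <- function(trials, scenes = 1:4) {
  acts <- c("accept", "return", "stay", "other", "fixbreak")
  if (nrow(trials) > 0) {
    if (any(is.na(trials$action)) || !all(trials$action %in% c(acts, "fixhold")))
      stop("trials contain unlabeled or unknown actions", call. = FALSE)
    trials <- trials[trials$value == "bad" & trials$action %in% acts, , drop = FALSE]
  }
  tab <- vapply(scenes, function(sc) {
    a <- trials$action[trials$scene == sc]
    vapply(acts, function(x) sum(a == x), 0L)
  }, integer(5))
  out <- data.frame(scene = scenes, total = colSums(tab), t(tab))
  names(out) <- c("scene", "total", acts)
  rownames(out) <- NULL
  structure(out, class = c("action_count_table", "data.frame"))
}

#' Per-scene action percentages
#'
#' Converts an action-count table to percentages of the scene total, rounded
#' half away from zero to one decimal (the convention that reproduces
#' published proportion figures from their count tables).
#'
#' @param counts an [action_count_table()] (or data frame with the same
#'   columns).
#' @return data frame with `scene` and one percentage column per action.
#' @export
proportion_table <- function(counts) {
  acts <- c("accept", "return", "stay", "other", "fixbreak")
  if (any(counts$total <= 0))
    stop("undefined proportion: scene total is zero", call. = FALSE)
  out <- data.frame(scene = counts$scene)
  for (a in acts) out[[a]] <- round_half_up(100 * counts[[a]] / counts$total, 1)
  out
}

#' Welch's t test comparing good- and bad-object reaction times
#'
#' @param rt_good,rt_bad reaction-time samples, ms (n >= 2 each).
#' @return list with `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
compare_rt_welch <- function(rt_good, rt_bad) {
  rt_good <- rt_good[is.finite(rt_good)]; rt_bad <- rt_bad[is.finite(rt_bad)]
  if (length(rt_good) < 2 || length(rt_bad) < 2)
    stop("each reaction-time sample needs at least two finite values", call. = FALSE)
  if (stats::sd(rt_good) == 0 && stats::sd(rt_bad) == 0 &&
      mean(rt_good) == mean(rt_bad))
    return(list(t = 0, df = length(rt_good) + length(rt_bad) - 2, p = 1))
  ht <- stats::t.test(rt_good, rt_bad, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Fisher's exact test of stay proportions: stable vs flexible scenes
#'
#' Builds the 2x2 table of stay vs not-stay counts for the stable scenes (1-2,
#' constant object values) against the flexible scenes (3-4, values swapped),
#' and tests whether staying is more frequent under stable values. The
#' reported odds ratio compares flexible to stable (sample cross-product and
#' the conditional-MLE estimate with its 95% CI), along with the phi
#' coefficient of the 2x2 table.
#'
#' @param counts an [action_count_table()] covering scenes 1-4.
#' @return list with `table` (2x2), `odds_ratio` (sample cross-product),
#'   `odds_ratio_cmle`, `conf_int`, `p` (exact two-sided), `phi`.
#' @export
fisher_stable_vs_flexible <- function(counts) {
  stopifnot(all(1:4 %in% counts$scene))
  stay <- c(stable = sum(counts$stay[counts$scene %in% 1:2]),
            flexible = sum(counts$stay[counts$scene %in% 3:4]))
  tot <- c(sum(counts$total[counts$scene %in% 1:2]),
           sum(counts$total[counts$scene %in% 3:4]))
  not_stay <- tot - stay
  if (any(tot == 0) || sum(stay) == 0 || sum(not_stay) == 0)
    stop("empty margin in the stay/not-stay table", call. = FALSE)
  tab <- rbind(stable = c(stay = stay[1], not_stay = not_stay[1]),
               flexible = c(stay = stay[2], not_stay = not_stay[2]))
  ht <- stats::fisher.test(tab)
  # sample odds of staying in flexible vs stable scenes
  or_sample <- (stay[2] * not_stay[1]) / (stay[1] * not_stay[2])
  num <- stay[1] * not_stay[2] - stay[2] * not_stay[1]
  phi <- num / sqrt(prod(c(rowSums(tab), colSums(tab))))
  list(table = tab, odds_ratio = unname(or_sample),
       odds_ratio_cmle = unname(1 / ht$estimate),
       conf_int = unname(rev(1 / ht$conf.int)),
       p = ht$p.value, phi = unname(abs(phi)))
}
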