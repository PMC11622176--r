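#' Peristimulus time histogram in 1-ms bins
#'
#' Aligns a spike train to a set of events and counts spikes in 1-ms bins over
#' the half-open window `[window[1], window[2])` relative to each event. The
#' same code path serves every alignment (scene, target, or saccade onset);
#' changing the alignment only changes the time origin.
#'
#' @param spike_times numeric spike times, ms (session clock).
#' @param events numeric event times, ms.
#' @param window length-2 half-open analysis window relative to the event, ms.
#' @param recording_span optional length-2 span of valid recording, ms; events
#'   whose window is truncated by the span are dropped with a warning.
#' @return an object of class `aligned_raster`: list with `counts` (trials x
#'   bins integer matrix), `time_ms` (bin start times), `window`, `events`.
#' @export
psth <- function(spike_times, events, window, recording_span = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (!is.null(recording_span)) {
    ok <- events + window[1] >= recording_span[1] &
      events + window[2] <= recording_span[2]
    if (any(!ok)) {
      warning(sum(!ok), " event(s) dropped: window truncated by recording span")
      events <- events[ok]
    }
  }
  time_ms <- window_bins(window)
  nb <- length(time_ms)
  counts <- matrix(0L, nrow = length(events), ncol = nb)
  for (i in seq_along(events)) {
    rel <- spike_times - events[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      counts[i, ] <- tabulate(floor(rel - window[1]) + 1L, nbins = nb)
  }
  structure(list(counts = counts, time_ms = time_ms, window = window,
                 events = events),
            class = "aligned_raster")
}

gaussian_kernel <- function(sigma_ms, truncate = 4) {
  half <- ceiling(truncate * sigma_ms)
  k <- stats::dnorm(-half:half, sd = sigma_ms)
  k / sum(k)   # renormalized after +/-4 sigma truncation (<0.01% mass lost)
}

# convolve a vector with a symmetric kernel, same-length output,
# zero-padded edges (mass near edges leaks outside the window)
conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  full <- stats::convolve(c(numeric(half), x, numeric(half)), kern,
                          type = "filter")
  full
}

#' Spike density function
#'
#' The trial-averaged 1-ms PSTH is scaled to spikes/s and convolved with a
#' normalized Gaussian kernel (default SD 20 ms, truncated at 4 SD and
#' renormalized). A single spike therefore peaks at
#' `1000 / (sigma * sqrt(2*pi))` spikes/s, and the time-integral of the SDF
#' equals the mean spike count (up to edge truncation).
#'
#' @param raster an [psth()] raster.
#' @param sigma_ms Gaussian SD, ms.
#' @return list of class `sdf_trace`: `time_ms`, `rate` (spikes/s),
#'   `n_trials`, `sigma_ms`.
#' @export
sdf <- function(raster, sigma_ms = 20) {
  check_scalar_pos(sigma_ms, "sigma_ms")
  n_trials <- nrow(raster$counts)
  mean_counts <- if (n_trials > 0) colMeans(raster$counts) else
    numeric(length(raster$time_ms))
  rate <- conv_same(mean_counts * 1000, gaussian_kernel(sigma_ms))
  structure(list(time_ms = raster$time_ms, rate = rate, n_trials = n_trials,
                 sigma_ms = sigma_ms),
            class = "sdf_trace")
}

#' Baseline firing statistics before scene onset
#'
#' Mean and SD of per-trial firing rates in a fixed pre-scene window
#' (default the 1,000 ms between 1,500 and 500 ms before scene onset), used
#' for the medium-spiny-neuron inclusion filter.
#'
#' @param spike_times numeric spike times, ms.
#' @param scene_onsets numeric scene-onset times, ms (>= 1 required).
#' @param window half-open baseline window relative to scene onset, ms.
#' @return list with `mean` and `sd` (spikes/s) and `n_trials`.
#' @export
baseline_stats <- function(spike_times, scene_onsets, window = c(-1500, -500)) {
  if (length(scene_onsets) < 1)
    stop("at least one scene onset is required", call. = FALSE)
  if (length(spike_times) && (min(scene_onsets) + window[1] < 0))
    stop("baseline window lies outside the recording", call. = FALSE)
  dur_s <- (window[2] - window[1]) / 1000
  rates <- vapply(scene_onsets, function(on)
    sum(spike_times >= on + window[1] & spike_times < on + window[2]) / dur_s,
    0)
  list(mean = mean(rates),
       sd = if (length(rates) > 1) stats::sd(rates) else 0,
       n_trials = length(rates))
}

#' Putative medium-spiny-neuron inclusion filter
#'
#' Retains neurons with baseline firing rates strictly below the ceiling
#' (default 10 spikes/s); faster units are treated as putative fast-spiking
#' interneurons and excluded.
#'
#' @param baseline_rates named numeric vector of baseline rates (spikes/s).
#' @param ceiling_rate exclusion threshold, spikes/s (strict `<`).
#' @return character vector of retained neuron names; excluded neurons are
#'   reported via `message()`.
#' @export
msn_inclusion_filter <- function(baseline_rates, ceiling_rate = 10) {
  keep <- baseline_rates < ceiling_rate
  if (any(!keep))
    message("excluded ", sum(!keep), " neuron(s) with baseline >= ",
            ceiling_rate, " spikes/s: ",
            paste(names(baseline_rates)[!keep], collapse = ", "))
  names(baseline_rates)[keep]
}

#' Z-score an aligned response against its pre-event baseline
#'
#' Computes the SDF of the raster, then subtracts the baseline mean rate and
#' divides by the baseline SD. The baseline mean is the average per-trial rate
#' in `baseline_window` (default the 500 ms before the alignment event) and
#' the SD is taken across per-trial window means. A floor on the SD guards
#' against silent baselines; floored traces are flagged.
#'
#' @param raster an [psth()] raster whose window contains `baseline_window`.
#' @param sigma_ms SDF Gaussian SD, ms.
#' @param baseline_window half-open baseline window relative to the event, ms.
#' @param sd_floor minimum baseline SD, spikes/s.
#' @param baseline optional externally supplied `list(mean, sd)` (spikes/s),
#'   e.g. to reuse one baseline across alignments; computed from the raster
#'   when NULL.
#' @return list of class `z_trace`: `time_ms`, `z`, `baseline_mean`,
#'   `baseline_sd`, `flagged` (TRUE if the SD floor was applied), `n_trials`.
#' @export
z_normalize <- function(raster, sigma_ms = 20, baseline_window = c(-500, 0),
                        sd_floor = 0.1, baseline = NULL) {
  tr <- sdf(raster, sigma_ms)
  if (is.null(baseline)) {
    if (baseline_window[1] < raster$window[1] ||
        baseline_window[2] > raster$window[2])
      stop("baseline window lies outside the raster window", call. = FALSE)
    bins <- raster$time_ms >= baseline_window[1] &
      raster$time_ms < baseline_window[2]
    dur_s <- (baseline_window[2] - baseline_window[1]) / 1000
    per_trial <- rowSums(raster$counts[, bins, drop = FALSE]) / dur_s
    baseline <- list(mean = mean(per_trial),
                     sd = if (length(per_trial) > 1) stats::sd(per_trial) else 0)
  }
  flagged <- baseline$sd < sd_floor
  denom <- max(baseline$sd, sd_floor)
  structure(list(time_ms = tr$time_ms, z = (tr$rate - baseline$mean) / denom,
                 baseline_mean = baseline$mean, baseline_sd = baseline$sd,
                 flagged = flagged, n_trials = tr$n_trials),
            class = "z_trace")
}

#' Mean activity in a half-open analysis window
#'
#' Arithmetic mean of a trace over `[start_ms, start_ms + dur_ms)`; on the
#' 1-ms grid the conventional 200-ms window "from 100 to 300 ms" uses exactly
#' the 200 bins 100..299.
#'
#' @param trace a `z_trace`, `sdf_trace`, or numeric vector with a `time_ms`
#'   attribute/element.
#' @param start_ms window start, ms.
#' @param dur_ms window duration, ms.
#' @return scalar mean.
#' @export
mean_window_activity <- function(trace, start_ms = 100, dur_ms = 200) {
  if (inherits(trace, "z_trace")) {
    vals <- trace$z; time <- trace$time_ms
  } else if (inherits(trace, "sdf_trace")) {
    vals <- trace$rate; time <- trace$time_ms
  } else {
    vals <- trace$values; time <- trace$time_ms
  }
  step <- time[2] - time[1]
  if (start_ms < time[1] || start_ms + dur_ms > time[length(time)] + step)
    stop("analysis window lies outside the trace", call. = FALSE)
  sel <- time >= start_ms & time < start_ms + dur_ms
  mean(vals[sel])
}
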