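#' Aligned Z traces for every neuron and condition of a session
#'
#' For each neuron and each combination of `group_vars`, aligns the spike
#' train to target onsets of the selected task, computes the spike density
#' function and Z-scores it against the 500 ms pre-onset baseline.
#'
#' @param session a `synthetic_session` (or equivalent list with `trials` and
#'   `spikes`).
#' @param neuron_ids neurons to process (default all).
#' @param group_vars trial columns defining the conditions.
#' @param task `"choice"` or `"fixation"`.
#' @param window psth window around target onset, ms; must extend beyond the
#'   analysis range by the smoothing width to avoid edge artefacts.
#' @param sigma_ms,baseline_window,sd_floor passed to [z_normalize()].
#' @param pool_baseline estimate one baseline (mean and SD of the per-trial
#'   pre-onset rates) per neuron from all trials of the task and reuse it for
#'   every condition (default), rather than re-estimating it per condition.
#'   Pre-onset activity does not depend on the condition of the upcoming
#'   target, and pooling makes the Z denominator far less noisy when
#'   conditions have few trials.
#' @return named list (neuron) of named lists (condition key, values joined by
#'   `_`) of `z_trace` objects; each has an `n_trials` element.
#' @export
compute_ztraces <- function(session, neuron_ids = names(session$spikes),
                            group_vars = c("value", "direction"),
                            task = "choice", window = c(-655, 680),
                            sigma_ms = 20, baseline_window = c(-500, 0),
                            sd_floor = 0.1, pool_baseline = TRUE) {
  trials <- session$trials[session$trials$task == task, , drop = FALSE]
  keys <- interaction(trials[group_vars], drop = TRUE, sep = "_")
  out <- list()
  for (id in neuron_ids) {
    st <- session$spikes[[id]]
    base <- if (pool_baseline)
      pretrial_baseline(st, trials$target_on_ms, baseline_window)
    per_cond <- list()
    for (k in levels(keys)) {
      onsets <- trials$target_on_ms[keys == k]
      if (length(onsets) == 0) next
      ras <- psth(st, onsets, window)
      per_cond[[k]] <- z_normalize(ras, sigma_ms, baseline_window, sd_floor,
                                   baseline = base)
    }
    out[[id]] <- per_cond
  }
  out
}

#' Pre-onset baseline statistics across a set of trials
#'
#' Mean and across-trial SD of the per-trial rate in `baseline_window` before
#' each onset, in the form [z_normalize()] accepts as an external baseline.
#'
#' @param spike_times numeric spike times, ms.
#' @param onsets event times, ms.
#' @param baseline_window half-open window relative to each onset, ms.
#' @return list with `mean` and `sd` (spikes/s) and `n_trials`.
#' @export
pretrial_baseline <- function(spike_times, onsets,
                              baseline_window = c(-500, 0)) {
  dur_s <- (baseline_window[2] - baseline_window[1]) / 1000
  per_trial <- vapply(onsets, function(on)
    sum(spike_times >= on + baseline_window[1] &
          spike_times < on + baseline_window[2]) / dur_s, 0)
  list(mean = mean(per_trial),
       sd = if (length(per_trial) > 1) stats::sd(per_trial) else 0,
       n_trials = length(per_trial))
}

#' Per-trial windowed Z activity for one neuron
#'
#' Counts spikes in `[start_ms, start_ms + dur_ms)` after each onset,
#' converts to rate and Z-scores with the supplied baseline; used for the
#' reaction-time quartile analysis, where the unit is the single trial.
#'
#' @param spike_times numeric spike times, ms.
#' @param onsets event times, ms.
#' @param start_ms,dur_ms analysis window relative to the event.
#' @param baseline list with `mean` and `sd` (spikes/s).
#' @param sd_floor floor on the baseline SD.
#' @return numeric vector of per-trial Z activities.
#' @export
trial_window_activity <- function(spike_times, onsets, start_ms = 100,
                                  dur_ms = 200, baseline, sd_floor = 0.1) {
  dur_s <- dur_ms / 1000
  rates <- vapply(onsets, function(on)
    sum(spike_times >= on + start_ms &
          spike_times < on + start_ms + dur_ms) / dur_s, 0)
  (rates - baseline$mean) / max(baseline$sd, sd_floor)
}
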