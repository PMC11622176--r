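#' Instantaneous firing rate of a ground-truth neuron
#'
#' `rate(t) = baseline + amplitude(value, direction) * g_fix * shape(t)`,
#' where `shape(t) = (u/tau) exp(1 - u/tau)` with `u = t - latency` (zero for
#' `u < 0`), a causal bump that rises from the response latency and peaks at
#' `t = latency + tau` with height 1, and `g_fix = fixation_gain` in the
#' fixation task (1 in the choice task). Total function: the rate is defined
#' and non-negative for every `t`.
#'
#' @param neuron a [neuron_truth()].
#' @param value `"good"` or `"bad"`.
#' @param direction `"contra"` or `"ipsi"`.
#' @param task `"choice"` or `"fixation"`.
#' @param t_ms times relative to object onset, ms (vectorized).
#' @param amp_mult optional trial-level amplitude multiplier (activity /
#'   reaction-time coupling).
#' @return instantaneous rate in spikes/s, same length as `t_ms`.
#' @export
rate_function <- function(neuron, value, direction, task = "choice", t_ms,
                          amp_mult = 1) {
  amp <- condition_amplitude(neuron, value, direction)
  if (task == "fixation") amp <- amp * neuron$fixation_gain
  u <- (t_ms - neuron$response_latency_ms) / neuron$decay_tau_ms
  shape <- ifelse(u > 0, u * exp(1 - u), 0)
  pmax(neuron$baseline_rate + amp * amp_mult * shape, 0)
}

condition_amplitude <- function(neuron, value, direction) {
  key <- paste(value, direction, sep = "_")
  switch(key,
         good_contra = neuron$amp_good_contra,
         bad_contra  = neuron$amp_bad_contra,
         good_ipsi   = neuron$amp_good_ipsi,
         bad_ipsi    = neuron$amp_bad_ipsi,
         stop("unknown condition: ", key, call. = FALSE))
}

#' Simulate a spike train from an inhomogeneous Poisson process
#'
#' Spikes are drawn over `[t_start, t_end)` by thinning: candidate events from
#' a homogeneous Poisson process at the rate ceiling are kept with probability
#' `rate(t) / ceiling`. The expected count over any interval therefore equals
#' the integral of the rate function. The rate is the neuron's baseline plus
#' one response bump per object presentation listed in `events`.
#'
#' @param neuron a [neuron_truth()].
#' @param events data frame of object presentations with columns
#'   `target_on_ms`, `value`, `direction` and optionally `amp_mult` (trial
#'   gain) and `task`; may have zero rows for a baseline-only train.
#' @param t_start,t_end simulation span, ms (session clock).
#' @param task task governing the fixation gain for events lacking a `task`
#'   column.
#' @return sorted numeric vector of spike times, ms.
#' @export
generate_spike_train <- function(neuron, events = NULL, t_start = 0, t_end,
                                 task = "choice") {
  stopifnot(t_end >= t_start)
  if (t_end == t_start) return(numeric(0))
  if (is.null(events)) events <- data.frame()
  amps <- if (nrow(events) > 0) {
    mult <- if ("amp_mult" %in% names(events)) events$amp_mult else 1
    tk <- if ("task" %in% names(events)) events$task else task
    gain <- ifelse(tk == "fixation", neuron$fixation_gain, 1)
    mapply(function(v, d) condition_amplitude(neuron, v, d),
           events$value, events$direction) * mult * gain
  } else numeric(0)
  ceiling_rate <- neuron$baseline_rate + max(c(amps, 0))
  n_cand <- stats::rpois(1, ceiling_rate * (t_end - t_start) / 1000)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, t_start, t_end))
  rate <- rep(neuron$baseline_rate, n_cand)
  if (nrow(events) > 0) {
    lat <- neuron$response_latency_ms; tau <- neuron$decay_tau_ms
    support <- lat + 10 * tau                       # bump mass beyond ~10 tau is negligible
    for (k in seq_len(nrow(events))) {
      on <- events$target_on_ms[k]
      i0 <- findInterval(on + lat, cand) + 1L
      i1 <- findInterval(on + support, cand)
      if (i1 < i0) next
      idx <- i0:i1
      u <- (cand[idx] - on - lat) / tau
      rate[idx] <- rate[idx] + amps[k] * u * exp(1 - u)
    }
  }
  cand[stats::runif(n_cand) < rate / ceiling_rate]
}
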