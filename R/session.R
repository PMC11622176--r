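#' Generate a complete synthetic recording session
#'
#' Simulates a choice-task session (and optionally a fixation-task block) with
#' known ground truth: a trial table of sequential target presentations, one
#' 1 kHz eye trace per choice presentation, and one inhomogeneous-Poisson
#' spike train per neuron driven by the presentations. Every trial has a
#' consistent event chronology (scene onset < fixation point < target onsets),
#' action labels are drawn from the behavioral ground truth, and the generated
#' eye trace realizes the drawn label (a trial labelled "return" contains a
#' saccade into the target window that exits again within the acceptance hold
#' time). A shared trial-level gain couples reaction times and response
#' amplitudes, so the same seed always yields byte-identical output.
#'
#' @param config a [task_config()].
#' @param behavior a [behavior_truth()].
#' @param neurons list of [neuron_truth()] objects (may be empty).
#' @param seed integer seed; mandatory for reproducibility.
#' @param include_fixation also simulate a fixation-task block with the same
#'   neurons (Scene 1 objects flashed while gaze holds the centre).
#' @param n_fixation_trials number of fixation-task trials.
#' @param generate_eye generate eye traces for choice presentations (skip to
#'   save time when only spikes are needed).
#' @return a list of class `synthetic_session`: `trials` (data frame, one row
#'   per target presentation), `eye` (named list of [generate_eye_trace()]
#'   outputs keyed by `presentation_id`), `spikes` (named list of spike-time
#'   vectors, ms), `ground_truth` (neuron truths and trial gains), plus the
#'   configs used.
#' @export
generate_session <- function(config = task_config(),
                             behavior = behavior_truth(),
                             neurons = list(),
                             seed,
                             include_fixation = FALSE,
                             n_fixation_trials = 20,
                             generate_eye = TRUE) {
  if (missing(seed) || !is.finite(seed)) config_error("seed", "is mandatory")
  validate_task_config(config); validate_behavior_truth(behavior)
  set.seed(as.integer(seed))

  actions <- c("accept", "return", "stay", "other", "fixbreak")
  rows <- list(); eyes <- list()
  cursor <- 2000  # leaves >=1500 ms of pre-scene baseline for the first block
  block_id <- 0L
  contra_angles <- c(0, 45, 315)  # recording from the left hemisphere

  for (scene in config$scenes) for (b in seq_len(config$n_trials_per_scene)) {
    block_id <- block_id + 1L
    scene_on <- cursor
    fp_on <- scene_on + 1000
    tgt_on <- fp_on + 700
    for (p in seq_len(config$max_presentations)) {
      value <- sample(c("good", "bad"), 1L)
      angle <- sample(config$target_angles, 1L)
      direction <- if (angle %in% contra_angles) "contra" else "ipsi"
      tgt <- config$target_eccentricity *
        c(cos(angle * pi / 180), sin(angle * pi / 180))
      g <- stats::rnorm(1)
      if (value == "good") {
        action <- if (stats::runif(1) < behavior$accept_good) "accept" else "return"
        rt_mu <- behavior$rt_mean_good[scene]; rt_sd <- behavior$rt_sd_good[scene]
      } else {
        action <- sample(actions, 1L, prob = behavior$bad_action_probs[scene, ])
        rt_mu <- behavior$rt_mean_bad[scene]; rt_sd <- behavior$rt_sd_bad[scene]
      }
      cpl <- behavior$rt_coupling
      rt <- rt_mu + rt_sd * (cpl * g + sqrt(1 - cpl^2) * stats::rnorm(1))
      rt <- min(max(rt, 110), 380)
      if (!(action %in% c("accept", "return", "other"))) rt <- NA_real_
      dwell <- if (action == "return") stats::runif(1, 120, 300) else NA_real_

      pid <- sprintf("b%04d_p%02d", block_id, p)
      rows[[length(rows) + 1L]] <- data.frame(
        presentation_id = pid, task = "choice", block = block_id,
        presentation = p, scene = scene, value = value, direction = direction,
        angle_deg = angle, tgt_x = tgt[1], tgt_y = tgt[2],
        scene_on_ms = scene_on, fp_on_ms = fp_on, target_on_ms = tgt_on,
        action = action, rt_ms = rt, trial_gain = g,
        stringsAsFactors = FALSE)
      if (generate_eye)
        eyes[[pid]] <- generate_eye_trace(tgt, action, rt, config, dwell_ms = dwell)

      dur <- config$saccade_duration_ms
      if (action == "accept") {
        cursor <- tgt_on + rt + dur + config$accept_hold_ms + 300
        break
      } else if (action == "return") {
        tgt_on <- tgt_on + rt + 2 * dur + dwell + 700
      } else {
        tgt_on <- tgt_on + config$fp_wait_stay_ms + 700
      }
      if (p == config$max_presentations) cursor <- tgt_on + 300
    }
    cursor <- cursor + stats::runif(1, 1500, 2000)  # inter-trial preparatory period
  }

  if (include_fixation) {
    for (ft in seq_len(n_fixation_trials)) {
      block_id <- block_id + 1L
      scene_on <- cursor
      fp_on <- scene_on + 1000
      obj_on <- fp_on + 700
      n_rep <- sample(seq(config$fixation_task_repeats[1],
                          config$fixation_task_repeats[2]), 1L)
      value <- sample(c("good", "bad"), 1L)
      side <- sample(c("contra", "ipsi"), 1L)
      for (r in seq_len(n_rep)) {
        pid <- sprintf("b%04d_f%02d", block_id, r)
        rows[[length(rows) + 1L]] <- data.frame(
          presentation_id = pid, task = "fixation", block = block_id,
          presentation = r, scene = 1L, value = value, direction = side,
          angle_deg = if (side == "contra") 0 else 180,
          tgt_x = NA_real_, tgt_y = NA_real_,
          scene_on_ms = scene_on, fp_on_ms = fp_on, target_on_ms = obj_on,
          action = "fixhold", rt_ms = NA_real_, trial_gain = stats::rnorm(1),
          stringsAsFactors = FALSE)
        obj_on <- obj_on + config$fixation_task_on_ms + config$fixation_task_isi_ms
        value <- if (value == "good") "bad" else "good"
      }
      cursor <- obj_on + 300 + stats::runif(1, 1500, 2000)
    }
  }

  trials <- do.call(rbind, rows)
  t_end <- cursor + 1000

  spikes <- list()
  for (nt in neurons) {
    ev <- trials[, c("target_on_ms", "value", "direction", "task")]
    ev$amp_mult <- exp(nt$rt_coupling * trials$trial_gain - nt$rt_coupling^2 / 2)
    spikes[[nt$neuron_id]] <- generate_spike_train(nt, ev, 0, t_end)
  }

  structure(list(trials = trials, eye = eyes, spikes = spikes,
                 ground_truth = list(neurons = neurons,
                                     trial_gain = trials$trial_gain),
                 config = config, behavior = behavior, t_end = t_end),
            class = "synthetic_session")
}

#' Simulate per-neuron feature vectors for the three response archetypes
#'
#' Draws the 2-D clustering feature (Z-scored mean activity after
#' contralateral good and bad object onsets) directly from archetype centroids
#' with isotropic Gaussian within-archetype scatter. The default centroids
#' follow the population means observed for the three response types
#' (good-preferring, bad-preferring, visual), and the default scatter keeps
#' between-centroid distances at least four times the within-archetype SD.
#'
#' @param n_per_cluster integer vector of counts for archetypes 1..3.
#' @param centers 3x2 matrix of (z_good, z_bad) centroids.
#' @param within_sd within-archetype SD (degenerate features if 0).
#' @return data frame with `neuron_id`, `z_good`, `z_bad`, `archetype`.
#' @export
simulate_cluster_features <- function(n_per_cluster = c(50, 50, 50),
                                      centers = matrix(c(2.9, 1.8,
                                                         1.7, 2.5,
                                                         2.7, 3.0),
                                                       nrow = 3, byrow = TRUE),
                                      within_sd = 0.25) {
  stopifnot(length(n_per_cluster) == 3L, nrow(centers) == 3L)
  arch <- rep(c("cluster1_good", "cluster2_bad", "cluster3_visual"), n_per_cluster)
  k <- rep(1:3, n_per_cluster)
  n <- length(k)
  data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    z_good = centers[k, 1] + stats::rnorm(n, 0, within_sd),
    z_bad = centers[k, 2] + stats::rnorm(n, 0, within_sd),
    archetype = arch, stringsAsFactors = FALSE)
}

#' Simulate population Z traces with a known good/bad divergence onset
#'
#' Generates per-neuron Z-scored rate traces for the good and bad conditions:
#' unit-variance temporally correlated baseline noise (white noise smoothed
#' with a Gaussian kernel, mimicking spike-density smoothing) plus, in the
#' good condition, a value effect that ramps up linearly over `ramp_ms`
#' starting at `onset_ms`, with log-normal per-neuron amplitude scatter.
#'
#' @param n_neurons number of neurons.
#' @param onset_ms true divergence onset, ms after object onset.
#' @param effect_size asymptotic good-bad difference, Z units.
#' @param ramp_ms linear rise time of the effect, ms.
#' @param time_ms time axis, ms (1-ms grid).
#' @param noise_sd marginal SD of the baseline noise, Z units.
#' @param smooth_sigma_ms Gaussian smoothing SD of the noise, ms.
#' @param amp_sdlog log-normal SD of per-neuron effect amplitudes.
#' @return list with matrices `z_good`, `z_bad` (neurons x time) and `time_ms`.
#' @export
simulate_population_ztraces <- function(n_neurons = 40, onset_ms = 120,
                                        effect_size = 2, ramp_ms = 100,
                                        time_ms = -575:575, noise_sd = 1,
                                        smooth_sigma_ms = 20, amp_sdlog = 0.2) {
  nt <- length(time_ms)
  smooth_unit_noise <- function() {
    kw <- 4 * smooth_sigma_ms
    kern <- stats::dnorm(-kw:kw, sd = smooth_sigma_ms)
    kern <- kern / sqrt(sum(kern^2))    # unit marginal variance after smoothing
    raw <- matrix(stats::rnorm(n_neurons * (nt + 2 * kw)), n_neurons)
    t(apply(raw, 1, function(x) stats::convolve(x, kern, type = "filter")))
  }
  ramp <- pmin(pmax((time_ms - onset_ms) / ramp_ms, 0), 1)
  amp <- stats::rlnorm(n_neurons, 0, amp_sdlog) * effect_size
  list(z_good = noise_sd * smooth_unit_noise() + outer(amp, ramp),
       z_bad = noise_sd * smooth_unit_noise(),
       time_ms = time_ms)
}

#' Simulate trial-level activity and reaction times for latency analysis
#'
#' A reduced generator for calibration studies of the reaction-time quartile
#' analysis: each trial has a latent gain `g ~ N(0,1)`; windowed activity is
#' `g` plus independent noise, and the reaction time is
#' `rt_mean + rt_sd * (rt_coupling * g + sqrt(1 - rt_coupling^2) * z)`. With
#' `rt_coupling = 0` activity and reaction time are independent (the null);
#' negative coupling produces the observed faster-saccade/higher-activity
#' association.
#'
#' @param n_neurons neurons per simulated population.
#' @param n_trials trials per neuron.
#' @param rt_coupling coupling in `[-1, 1]`.
#' @param activity_noise_sd SD of the activity noise relative to the gain.
#' @param rt_mean,rt_sd reaction-time distribution, ms.
#' @return data frame with `neuron_id`, `trial`, `rt_ms`, `activity`.
#' @export
simulate_latency_trials <- function(n_neurons = 38, n_trials = 32,
                                    rt_coupling = -0.5, activity_noise_sd = 1,
                                    rt_mean = 234, rt_sd = 47) {
  n <- n_neurons * n_trials
  g <- stats::rnorm(n)
  data.frame(
    neuron_id = rep(sprintf("n%03d", seq_len(n_neurons)), each = n_trials),
    trial = rep(seq_len(n_trials), n_neurons),
    rt_ms = rt_mean + rt_sd * (rt_coupling * g +
                                 sqrt(1 - rt_coupling^2) * stats::rnorm(n)),
    activity = g + stats::rnorm(n, 0, activity_noise_sd),
    stringsAsFactors = FALSE)
}
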