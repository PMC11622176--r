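# shared fixtures, built in code

# small session with no neurons (behavior-only)
make_behavior_session <- function(seed = 1, blocks = 3) {
  generate_session(task_config(n_trials_per_scene = blocks), behavior_truth(),
                   list(), seed = seed)
}

# well-separated 2-D blobs for clustering tests
make_blobs <- function(n_per = 30, centers = matrix(c(0, 0, 4, 0, 2, 4),
                                                    nrow = 3, byrow = TRUE),
                       sd = 0.3, k = 3) {
  centers <- centers[seq_len(k), , drop = FALSE]
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  data.frame(neuron_id = sprintf("n%03d", seq_len(nrow(x))),
             z_good = x[, 1], z_bad = x[, 2],
             truth = rep(seq_len(k), each = n_per))
}

# raster with prescribed spike times on a single trial
single_trial_raster <- function(spike_times, window = c(-200, 400)) {
  psth(spike_times, events = 0, window = window)
}

# balanced activity records for mixed-model tests: n_neurons neurons split
# over two monkeys, 2x2 value x direction cells
make_activity_records <- function(n_neurons = 20, value_effect = 0,
                                  neuron_sd = 0.3, noise_sd = 0.5) {
  cells <- expand.grid(value = c("good", "bad"),
                       direction = c("contra", "ipsi"),
                       stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(n_neurons), function(i)
    transform(cells, neuron_id = sprintf("n%02d", i),
              monkey_id = ifelse(i <= n_neurons / 2, "C", "S"))))
  b <- rnorm(n_neurons, 0, neuron_sd)
  recs$activity <- b[match(recs$neuron_id, sprintf("n%02d", seq_len(n_neurons)))] +
    value_effect * (recs$value == "good") + rnorm(nrow(recs), 0, noise_sd)
  recs
}
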