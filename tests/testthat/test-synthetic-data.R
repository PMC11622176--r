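# session generator, rate function and Poisson spike simulation

test_that("identical seed gives byte-identical sessions; configs are validated", {
  cfg <- task_config(n_trials_per_scene = 10)
  s1 <- generate_session(cfg, behavior_truth(), list(), seed = 1)
  s2 <- generate_session(cfg, behavior_truth(), list(), seed = 1)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$eye, s2$eye)
  # 10 blocks per scene, 4 scenes
  expect_equal(length(unique(s1$trials$block)), 40)
  expect_true(all(s1$trials$scene_on_ms < s1$trials$fp_on_ms &
                    s1$trials$fp_on_ms < s1$trials$target_on_ms))

  expect_error(task_config(accept_hold_ms = -1), "accept_hold_ms")
  expect_error(task_config(fixation_task_repeats = c(1, 5)), "fixation_task_repeats")
  expect_error(behavior_truth(rt_mean_good = rep(700, 4)), "rt_mean")
  expect_error(neuron_truth("x", baseline_rate = 12), "baseline_rate")
  expect_error(generate_session(task_config(), behavior_truth(), list()), "seed")
})

test_that("degenerate action probabilities force the drawn label", {
  probs <- matrix(rep(c(0, 1, 0, 0, 0), each = 4), nrow = 4)  # return only
  bt <- behavior_truth(bad_action_probs = probs)
  ses <- generate_session(task_config(n_trials_per_scene = 10), bt, list(), seed = 3)
  bad <- ses$trials[ses$trials$value == "bad", ]
  expect_true(nrow(bad) > 15)
  expect_true(all(bad$action == "return"))
})

test_that("generated action frequencies stay inside the binomial 95% band", {
  # all-bad presentations with the scene-3 calibration (return .918, stay .067)
  probs <- matrix(rep(c(6, 1282, 94, 9, 5) / 1396, each = 4), nrow = 4)
  bt <- behavior_truth(bad_action_probs = probs, accept_good = 0)
  ses <- generate_session(task_config(n_trials_per_scene = 30), bt, list(), seed = 11)
  ch <- ses$trials
  labs <- vapply(seq_len(nrow(ch)), function(i)
    classify_action(ses$eye[[ch$presentation_id[i]]],
                    c(ch$tgt_x[i], ch$tgt_y[i]))$label, "")
  bad <- ch$value == "bad"
  n <- sum(bad)
  p_hat <- mean(labs[bad] == "return")
  p0 <- 1282 / 1396
  expect_lt(abs(p_hat - p0), 1.96 * sqrt(p0 * (1 - p0) / n) + 1e-9)
})

test_that("rate function is causal, condition-selective and peaks at latency + tau", {
  nt <- neuron_truth("n1", "cluster2_bad", baseline_rate = 4,
                     amp_good_contra = 0, response_latency_ms = 150,
                     decay_tau_ms = 120)
  t <- seq(-200, 800, by = 1)
  r_good <- rate_function(nt, "good", "contra", "choice", t)
  r_bad <- rate_function(nt, "bad", "contra", "choice", t)
  # before latency: baseline for every condition
  expect_true(all(r_bad[t <= 150] == 4))
  # bad-preferring archetype with amp_good = 0: flat for good
  expect_true(all(r_good == 4))
  # closed-form maximum of the alpha bump
  expect_equal(t[which.max(r_bad)], 150 + 120)
  expect_equal(max(r_bad), 4 + nt$amp_bad_contra, tolerance = 1e-10)
  # fixation task attenuates by the fixation gain
  r_fix <- rate_function(nt, "bad", "contra", "fixation", t)
  expect_equal(max(r_fix) - 4, (max(r_bad) - 4) * nt$fixation_gain,
               tolerance = 1e-10)
})

test_that("homogeneous spike trains match the Poisson mean and empty spans give no spikes", {
  nt <- neuron_truth("n1", "cluster1_good", baseline_rate = 5)
  set.seed(42)
  counts <- replicate(500, length(generate_spike_train(nt, NULL, 0, 10000)))
  # mean 50 expected; SE = sqrt(50/500) = 0.32
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 500))
  expect_identical(generate_spike_train(nt, NULL, 0, 0), numeric(0))
})

test_that("inhomogeneous trains pass the time-rescaling uniformity check", {
  nt <- neuron_truth("n1", "cluster1_good", baseline_rate = 5,
                     amp_good_contra = 30, response_latency_ms = 100,
                     decay_tau_ms = 120)
  ev <- data.frame(target_on_ms = seq(1000, 199000, by = 2000),
                   value = "good", direction = "contra")
  set.seed(7)
  spk <- generate_spike_train(nt, ev, 0, 200000)
  # time-rescaling: integrated rate between consecutive spikes ~ Exp(1)
  grid <- seq(0, 200000, by = 1)
  rate <- rep(nt$baseline_rate, length(grid))
  for (on in ev$target_on_ms) {
    u <- (grid - on - 100) / 120
    rate <- rate + 30 * ifelse(u > 0, u * exp(1 - u), 0)
  }
  cumint <- cumsum(rate) / 1000  # expected counts on the 1-ms grid
  lam <- approx(grid, cumint, xout = spk)$y
  isi <- diff(lam)
  u <- 1 - exp(-isi)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # Poisson calibration: count over the whole span within 3 SE of the integral
  expect_lt(abs(length(spk) - max(cumint)), 3 * sqrt(max(cumint)))
})

test_that("eye traces realize their action labels", {
  cfg <- task_config()
  set.seed(1)
  tr_stay <- generate_eye_trace(c(15, 0), "stay", NA, cfg)
  expect_identical(nrow(detect_saccades(tr_stay, epoch = c(-300, 1100))), 0L)

  tr_acc <- generate_eye_trace(c(15, 0), "accept", rt_ms = 180, cfg)
  s <- detect_saccades(tr_acc)
  expect_equal(nrow(s), 1L)
  expect_lt(abs(s$onset_ms[1] - 180), 5)
  half <- cfg$target_window_side / 2
  inw <- abs(tr_acc$x_deg - 15) <= half & abs(tr_acc$y_deg) <= half
  entry <- tr_acc$t_ms[which(inw & tr_acc$t_ms >= 0)[1]]
  expect_lt(abs(entry - 180), 40)
  expect_gte(sum(inw & tr_acc$t_ms >= entry), 400)

  tr_ret <- generate_eye_trace(c(15, 0), "return", rt_ms = 250, cfg,
                               dwell_ms = 200)
  expect_identical(classify_action(tr_ret, c(15, 0))$label, "return")
  expect_error(generate_eye_trace(c(15, 0), "return", rt_ms = 2000, cfg),
               "target epoch")
  expect_error(generate_eye_trace(c(15, 0), "accept", rt_ms = NA, cfg),
               "rt_ms")
})

test_that("classifier round trip recovers drawn labels on >= 99% of trials", {
  ses <- generate_session(task_config(n_trials_per_scene = 25),
                          behavior_truth(), list(), seed = 21)
  ch <- ses$trials
  labs <- vapply(seq_len(nrow(ch)), function(i)
    classify_action(ses$eye[[ch$presentation_id[i]]],
                    c(ch$tgt_x[i], ch$tgt_y[i]))$label, "")
  expect_gte(mean(labs == ch$action), 0.99)
})
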