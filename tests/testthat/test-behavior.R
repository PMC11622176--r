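# saccade detection, action classification, and behavioral statistics

test_that("saccade detector handles flat traces, steps, and the epoch limit", {
  cfg <- task_config(eye_noise_sd = 0)
  flat <- generate_eye_trace(c(15, 0), "stay", NA, cfg)
  expect_identical(nrow(detect_saccades(flat)), 0L)

  step <- generate_eye_trace(c(15, 0), "accept", rt_ms = 250, cfg)
  ev <- detect_saccades(step)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_ms - 250), 5)
  expect_gt(ev$peak_speed, 40)
  expect_equal(ev$landing_x, 15, tolerance = 0.5)

  # crossing after the epoch end is not reported (no reaction time recorded)
  late <- generate_eye_trace(c(15, 0), "accept", rt_ms = 450, cfg)
  expect_identical(nrow(detect_saccades(late, epoch = c(0, 400))), 0L)

  bad <- data.frame(t_ms = c(0, 1, 3, 4), x_deg = 0, y_deg = 0)
  expect_error(detect_saccades(bad), "uniformly sampled")
})

test_that("action classification follows the dwell-time rule table", {
  cfg <- task_config(eye_noise_sd = 0)
  # dwell > hold -> accept; dwell < hold -> return (rule table around 400 ms)
  for (case in list(list(dwell = 450, label = "accept"),
                    list(dwell = 340, label = "return"),
                    list(dwell = 120, label = "return"))) {
    act <- if (case$label == "accept") "accept" else "return"
    tr <- generate_eye_trace(c(15, 0), act, rt_ms = 200, cfg,
                             dwell_ms = if (act == "return") case$dwell else NULL)
    got <- classify_action(tr, c(15, 0))
    expect_identical(got$label, case$label)
    expect_lt(abs(got$rt_ms - 200), 5)
  }
  tr_stay <- generate_eye_trace(c(15, 0), "stay", NA, cfg)
  got <- classify_action(tr_stay, c(15, 0))
  expect_identical(got$label, "stay")
  expect_true(is.na(got$rt_ms))
  tr_other <- generate_eye_trace(c(15, 0), "other", rt_ms = 220, cfg)
  expect_identical(classify_action(tr_other, c(15, 0))$label, "other")
  tr_fb <- generate_eye_trace(c(15, 0), "fixbreak", NA, cfg)
  expect_identical(classify_action(tr_fb, c(15, 0))$label, "fixbreak")
  expect_error(classify_action(tr_stay[tr_stay$t_ms < 100, ], c(15, 0)),
               "shorter")
})

test_that("dwell measurement verified against an exhaustive dwell grid", {
  # independent oracle: construct noise-free traces entering the window at a
  # known time and exiting after an exact dwell; label by the 400 ms rule
  cfg <- task_config(eye_noise_sd = 0)
  for (dwell in c(150, 250, 350, 390, 420, 500)) {
    expected <- if (dwell >= 400) "accept" else "return"
    act <- if (dwell >= 400) "accept" else "return"
    tr <- generate_eye_trace(c(15, 0), act, rt_ms = 150, cfg,
                             dwell_ms = if (act == "return") dwell - 30 else NULL)
    expect_identical(classify_action(tr, c(15, 0))$label, expected,
                     label = paste("dwell", dwell))
  }
})

test_that("action counts: totals, order invariance, empty input", {
  trials <- data.frame(
    scene = rep(1:4, each = 10),
    value = "bad",
    action = rep(c("return", "stay", "other", "fixbreak", "return"), 8))
  tab <- action_count_table(trials)
  expect_equal(tab$total, unname(rowSums(tab[, c("accept", "return", "stay",
                                                 "other", "fixbreak")])))
  perm <- trials[sample(nrow(trials)), ]
  expect_equal(action_count_table(perm), tab)
  empty <- action_count_table(trials[0, ])
  expect_true(all(empty$total == 0))
  trials$action[3] <- NA
  expect_error(action_count_table(trials), "unlabeled")
})

test_that("proportion table reproduces the published per-scene percentages", {
  cnt_c <- load_action_counts("C")
  expect_equal(cnt_c$total, unname(rowSums(cnt_c[, 3:7])))
  p_c <- proportion_table(cnt_c)
  expect_equal(p_c$return, c(75.3, 78.1, 91.8, 85.1))
  expect_equal(p_c$stay[2:4], c(20.2, 6.7, 11.3))
  p_s <- proportion_table(load_action_counts("S"))
  expect_equal(p_s$return[2:3], c(70.7, 79.7))
  expect_equal(p_s$stay, c(23.5, 28.3, 19.5, 20.1))
  # proportions across all actions sum to 100 within rounding slack
  sums <- rowSums(p_c[, -1])
  expect_true(all(abs(sums - 100) <= 0.2))
  # zero counts give 0.0; zero totals are an error
  z <- proportion_table(data.frame(scene = 1, total = 10, accept = 0,
                                   return = 10, stay = 0, other = 0,
                                   fixbreak = 0))
  expect_identical(z$accept, 0)
  expect_error(proportion_table(data.frame(scene = 1, total = 0, accept = 0,
                                           return = 0, stay = 0, other = 0,
                                           fixbreak = 0)), "zero")
})

test_that("Welch test matches its closed form and is antisymmetric", {
  expect_equal(compare_rt_welch(c(200, 210, 220), c(200, 210, 220)),
               list(t = 0, df = 4, p = 1))
  set.seed(1)
  g <- rnorm(1000, 160, 21); b <- rnorm(1000, 234, 47)
  res <- compare_rt_welch(g, b)
  # closed-form Welch statistic
  tw <- (mean(g) - mean(b)) / sqrt(var(g) / 1000 + var(b) / 1000)
  dfw <- (var(g) / 1000 + var(b) / 1000)^2 /
    ((var(g) / 1000)^2 / 999 + (var(b) / 1000)^2 / 999)
  expect_equal(res$t, tw, tolerance = 1e-12)
  expect_equal(res$df, dfw, tolerance = 1e-9)
  expect_lt(res$p, 1e-10)
  flipped <- compare_rt_welch(b, g)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p, res$p)
  expect_error(compare_rt_welch(200, c(1, 2)), "at least two")
})

test_that("Fisher stay test: cross-product odds ratios and invariances", {
  res_c <- fisher_stable_vs_flexible(load_action_counts("C"))
  expect_equal(res_c$odds_ratio, (261 * 2290) / (598 * 2608), tolerance = 1e-12)
  # the published CI brackets the sample odds ratio
  expect_gt(res_c$odds_ratio, 0.32); expect_lt(res_c$odds_ratio, 0.45)
  expect_lt(res_c$conf_int[1], res_c$odds_ratio)
  expect_gt(res_c$conf_int[2], res_c$odds_ratio)
  expect_lt(res_c$p, 1e-30)

  res_s <- fisher_stable_vs_flexible(load_action_counts("S"))
  expect_equal(res_s$odds_ratio, (578 * 2304) / (802 * 2343), tolerance = 1e-12)
  expect_gt(res_s$odds_ratio, 0.62); expect_lt(res_s$odds_ratio, 0.80)

  # equal stay proportions -> OR 1, p 1
  eq <- data.frame(scene = 1:4, total = 100, accept = 0, return = 80,
                   stay = 20, other = 0, fixbreak = 0)
  res_eq <- fisher_stable_vs_flexible(eq)
  expect_equal(res_eq$odds_ratio, 1)
  expect_equal(res_eq$p, 1)

  # swapping both rows and both columns leaves p unchanged
  swapped <- fisher.test(res_c$table[2:1, 2:1])$p.value
  expect_equal(res_c$p, swapped, tolerance = 1e-12)
})

test_that("generated-label round trip holds per label class", {
  cfg <- task_config()
  set.seed(33)
  for (act in c("accept", "return", "stay", "other", "fixbreak")) {
    ok <- 0
    for (i in 1:25) {
      rt <- runif(1, 130, 350)
      tr <- generate_eye_trace(c(15, 0), act,
                               rt_ms = if (act %in% c("accept", "return", "other")) rt else NA,
                               cfg)
      ok <- ok + (classify_action(tr, c(15, 0))$label == act)
    }
    expect_gte(ok / 25, 0.99)
  }
})
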