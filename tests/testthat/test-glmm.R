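# mixed-model fitting, parametric-bootstrap comparison, post hocs, wilcoxon

test_that("fixed effects are recovered and shifts move only the intercept", {
  set.seed(50)
  recs <- make_activity_records(n_neurons = 50, value_effect = 1,
                                neuron_sd = 0.3, noise_sd = 0.5)
  fit <- fit_mixed_model(recs, activity ~ value * direction)
  # treatment coding: "good" is the non-reference level of factor(value)
  est <- fit$fixef[["valuegood"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))[["valuegood"]]
  expect_lt(abs(est - 1), 2 * se)
  expect_lt(abs(est - 1), 0.15)

  recs2 <- recs; recs2$activity <- recs$activity + 7
  fit2 <- fit_mixed_model(recs2, activity ~ value * direction)
  expect_equal(fit2$fixef[["(Intercept)"]], fit$fixef[["(Intercept)"]] + 7,
               tolerance = 1e-6)
  expect_equal(fit2$fixef[-1], fit$fixef[-1], tolerance = 1e-6)
})

test_that("full 16-cell design: simulated effects recovered within 2 SE", {
  # a single 2-SE check fails for ~5% of noise draws by construction, so the
  # property is asserted over five independent simulations: at least four of
  # five recover both marginal effects within 2 SE
  set.seed(51)
  truth_value <- 0.8; truth_dir <- -0.4
  cells <- expand.grid(scene = as.character(1:4), value = c("good", "bad"),
                       direction = c("contra", "ipsi"),
                       stringsAsFactors = FALSE)
  ok <- replicate(5, {
    recs <- do.call(rbind, lapply(1:50, function(i)
      transform(cells, neuron_id = sprintf("n%02d", i),
                monkey_id = ifelse(i <= 25, "C", "S"))))
    b <- rnorm(50, 0, 0.3)
    recs$activity <- b[match(recs$neuron_id, sprintf("n%02d", 1:50))] +
      truth_value * (recs$value == "good") +
      truth_dir * (recs$direction == "ipsi") + rnorm(nrow(recs), 0, 0.5)
    fit <- fit_mixed_model(recs)  # default scene * value * direction
    # marginal effects via emmeans contrasts ("bad - good", "contra - ipsi")
    ph_v <- posthoc_pairwise(fit, ~ value, m = 1)
    ph_d <- posthoc_pairwise(fit, ~ direction, m = 1)
    abs(-ph_v$contrasts$estimate[1] - truth_value) < 2 * ph_v$contrasts$SE[1] &&
      abs(-ph_d$contrasts$estimate[1] - truth_dir) < 2 * ph_d$contrasts$SE[1]
  })
  expect_gte(sum(ok), 4)
})

test_that("zero between-neuron variance gives a flagged boundary fit", {
  set.seed(52)
  recs <- make_activity_records(n_neurons = 30, neuron_sd = 0, noise_sd = 0.5)
  fit <- fit_mixed_model(recs, activity ~ value)
  expect_true(fit$singular)
  expect_lt(max(fit$varcomp$sdcor[fit$varcomp$grp != "Residual"]), 0.1)
})

test_that("full-model deviance never exceeds the nested null's", {
  set.seed(53)
  for (i in 1:5) {
    recs <- make_activity_records(n_neurons = 16,
                                  value_effect = runif(1, 0, 0.5))
    full <- fit_mixed_model(recs, activity ~ value * direction)
    null <- fit_mixed_model(recs, activity ~ 1)
    expect_lte(full$deviance, null$deviance + 1e-8)
  }
})

test_that("internal profiled deviance matches lme4 exactly", {
  set.seed(54)
  recs <- make_activity_records(n_neurons = 24, value_effect = 0.6)
  fit <- fit_mixed_model(recs, activity ~ value * direction)
  s <- fast_structure_from_fit(fit)
  dev <- lmm_devfun(s, recs$activity)
  # at lme4's own optimum the profiled deviance reproduces lme4's deviance
  expect_lt(abs(dev(match_theta(fit)) - fit$deviance), 1e-3)
  # and at arbitrary theta it reproduces lme4's deviance function
  lmod <- lme4::lFormula(activity ~ value * direction + (1 | monkey_id) +
                           (1 | monkey_id:neuron_id),
                         data = fit$data, REML = FALSE)
  df4 <- do.call(lme4::mkLmerDevfun, lmod)
  for (th in list(c(0.5, 0.5), c(0.1, 2), c(3, 0.01))) {
    # lme4 orders terms by decreasing level count: neuron-in-monkey first
    expect_lt(abs(dev(th) - df4(c(th[2], th[1]))), 1e-6)
  }
  # the internal optimizer reaches the same optimum (deviance and beta)
  opt <- fit_lmm_fast(s, recs$activity)
  expect_lt(abs(opt$deviance - fit$deviance), 1e-3)
  expect_equal(unname(opt$beta), unname(fit$fixef), tolerance = 1e-3)
  expect_equal(opt$sigma, fit$sigma, tolerance = 1e-3)
})

test_that("bootstrap comparison: reproducibility, null, power, pbkrtest cross-check", {
  set.seed(55)
  recs <- make_activity_records(n_neurons = 20, value_effect = 0)
  full <- fit_mixed_model(recs, activity ~ value * direction)
  null <- fit_mixed_model(recs, activity ~ 1)

  b1 <- parametric_bootstrap_compare(full, null, n_iter = 99, seed = 7)
  b2 <- parametric_bootstrap_compare(full, null, n_iter = 99, seed = 7)
  expect_identical(b1$p, b2$p)
  expect_identical(b1$boot_dev_diffs, b2$boot_dev_diffs)
  expect_gt(b1$p, 0.05)  # no effect was simulated

  # identical models: observed deviance difference ~ 0 -> p ~ 1
  b0 <- parametric_bootstrap_compare(full, full, n_iter = 49, seed = 8)
  expect_lt(abs(b0$observed_dev_diff), 1e-6)
  expect_gt(b0$p, 0.9)

  # strong effect: p at the add-one floor for n_iter = 999
  set.seed(56)
  recs_eff <- make_activity_records(n_neurons = 20, value_effect = 2)
  full_e <- fit_mixed_model(recs_eff, activity ~ value * direction)
  null_e <- fit_mixed_model(recs_eff, activity ~ 1)
  be <- parametric_bootstrap_compare(full_e, null_e, n_iter = 999, seed = 9)
  expect_lte(be$p, 0.005)

  # cross-check against pbkrtest on the same data: identical observed LRT
  # statistic; bootstrap p consistent within binomial error
  set.seed(57)
  recs_m <- make_activity_records(n_neurons = 20, value_effect = 0.25)
  full_m <- fit_mixed_model(recs_m, activity ~ value)
  null_m <- fit_mixed_model(recs_m, activity ~ 1)
  bm <- parametric_bootstrap_compare(full_m, null_m, n_iter = 399, seed = 10)
  pb <- pbkrtest::PBmodcomp(full_m$model, null_m$model, nsim = 399, seed = 11)
  stat_pb <- pb$test["LRT", "stat"]
  expect_equal(bm$observed_dev_diff, stat_pb, tolerance = 1e-3)
  p_pb <- pb$test["PBtest", "p.value"]
  se_each <- sqrt(max(p_pb, 0.01) * (1 - max(p_pb, 0.01)) / 400)
  expect_lt(abs(bm$p - p_pb), 4 * sqrt(2) * se_each + 0.01)

  expect_error(parametric_bootstrap_compare(null_m, full_m, n_iter = 9),
               "nested")
})

test_that("post hocs: exact-zero contrast, Bonferroni threshold, omnibus gate", {
  set.seed(58)
  recs <- make_activity_records(n_neurons = 16, value_effect = 0)
  # symmetrize so the good and bad cells are numerically identical
  good <- recs$value == "good"
  key <- paste(recs$neuron_id, recs$direction)
  recs$activity[good] <- recs$activity[!good][match(key[good], key[!good])]
  fit <- fit_mixed_model(recs, activity ~ value * direction)
  ph <- posthoc_pairwise(fit, ~ value, m = 12)
  expect_equal(ph$contrasts$estimate[1], 0, tolerance = 1e-8)
  expect_equal(ph$contrasts$p[1], 1, tolerance = 1e-6)
  expect_false(ph$contrasts$significant[1])
  # significance is declared exactly at raw p < alpha / m (0.05/12 = 0.0041667)
  expect_identical(ph$contrasts$significant,
                   ph$contrasts$p < 0.05 / 12)
  expect_equal(0.05 / 12, 0.0041667, tolerance = 1e-5)

  # good-contra elevation: that pairwise cell contrast is significant
  set.seed(59)
  recs2 <- make_activity_records(n_neurons = 30, value_effect = 0)
  lift <- recs2$value == "good" & recs2$direction == "contra"
  recs2$activity[lift] <- recs2$activity[lift] + 1.5
  fit2 <- fit_mixed_model(recs2, activity ~ value * direction)
  ph2 <- posthoc_pairwise(fit2, ~ value * direction, m = 12)
  row <- ph2$contrasts$contrast == "bad contra - good contra"
  expect_identical(sum(row), 1L)
  expect_true(ph2$contrasts$significant[row])
  expect_lt(ph2$contrasts$estimate[row], 0)  # good contra is elevated
  expect_equal(ph2$contrasts$effect_size[row],
               ph2$contrasts$estimate[row] / fit2$sigma, tolerance = 1e-12)

  fake_lrt <- structure(list(p = 0.5), class = "bootstrap_lrt")
  expect_error(posthoc_pairwise(fit2, ~ value, m = 12, lrt = fake_lrt),
               "refused")
})

test_that("choice-vs-fixation wilcoxon: trivial cases and power", {
  x <- rnorm(8)
  expect_equal(choice_vs_fixation_wilcoxon(x, x), list(W = 0, p = 1, n = 8,
                                                       median_diff = 0))
  expect_error(choice_vs_fixation_wilcoxon(rnorm(4), rnorm(4)), "five")
  set.seed(60)
  a <- rnorm(12); b <- a + rnorm(12, 0.3, 0.5)
  expect_equal(choice_vs_fixation_wilcoxon(a, b)$p,
               choice_vs_fixation_wilcoxon(b, a)$p, tolerance = 1e-12)
  # gain-like elevation in the choice task, N = 16 pairs: detected in >= 80%
  set.seed(61)
  hits <- replicate(100, {
    fx <- rnorm(16, 1, 0.6)
    ch <- fx + rnorm(16, 0.5, 0.4)
    choice_vs_fixation_wilcoxon(ch, fx)$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
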