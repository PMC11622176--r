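---
title: "Methods: simulation and analysis of proactive-inhibition sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of proactive-inhibition sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(proactstriat)
```

`proactstriat` simulates oculomotor choice sessions in which a subject
repeatedly decides whether to pursue or reject visual objects of known value,
and provides the full analysis chain used to characterise value coding in the
recorded neurons: trial classification from eye traces, spike-density
estimation, Z-normalisation, response-type clustering, divergence-onset
estimation, reaction-time coupling, and mixed-effects modelling. This
vignette documents the statistical model behind each stage, the default
parameters, and the reasoning behind the less obvious design choices.

## Task and session simulation

A session interleaves blocks of a **choice task** (a scene of objects
appears; one object is the target; the subject accepts it by fixating it for
more than 400 ms, or rejects it by returning to center, staying at center, or
making a saccade elsewhere) with an optional **fixation task** in which the
object is task-irrelevant. Four scene types cross stable/flexible value
contexts. `generate_session()` draws trial outcomes from a configurable
ground-truth action distribution (`behavior_truth()`), then renders each
trial as a 1-kHz two-channel eye trace and as spike trains for a simulated
neuron population.

**Eye traces.** Saccades are minimum-jerk position profiles (smooth, bell-
shaped velocity, peak well above the detection threshold) plus white fixation
jitter of 0.05° SD. The jitter SD is deliberately small relative to the 40°/s
velocity criterion at 1 kHz (0.05° per ms ≈ 50°/s instantaneous for a single
sample, but velocity is estimated over a 5-ms window where the jitter
averages out), so classification noise comes from the generator's labelled
randomness, not from numerical artefacts.

**Spike trains.** Each neuron is an inhomogeneous Poisson process simulated
by thinning. Rate profiles come from three archetypes: `cluster1_good`
(phasic excitation for good objects), `cluster2_bad` (sustained elevation for
bad objects, the proactive-inhibition signature), and `cluster3_visual`
(value-indifferent visual response). Baseline rates are uniform on 2–8
spikes/s — below the 10 spikes/s medium-spiny-neuron criterion.

**Amplitude scaling.** Archetype response amplitudes are specified at a
reference baseline of 5 spikes/s and scaled by `sqrt(baseline/5)` for each
neuron. Because the across-trial SD of a Poisson rate estimate grows with the
square root of the rate, this keeps the *Z-scored* effect size homogeneous
across neurons, which is what makes the feature clouds used for clustering
compact. Per-neuron log-normal amplitude jitter (`sdlog` 0.1) is shared
across conditions, with smaller independent per-condition jitter (`sdlog`
0.05), so that a strong neuron is strong in all conditions.

## Trial classification

`detect_saccade()` flags the first sample where the 5-ms eye speed exceeds
40°/s within 400 ms of target onset; its time is the reaction time.
`classify_action()` is a deterministic rule table: *accept* if gaze enters
the 8°-side window around the target and dwells ≥ 400 ms; *return* if it
enters and leaves sooner; *stay* if gaze never leaves the central zone;
*other* for saccades landing elsewhere; *fixbreak* when fixation is lost
before the target epoch. Round-trip agreement between generated labels and
re-classified labels exceeds 99% (see the acceptance tests).

## Spike preprocessing and Z traces

`psth()` aligns spikes to events on a 1-ms grid; `sdf()` smooths with a
Gaussian kernel (σ = 20 ms), giving spikes/s. A single spike therefore peaks
at `1000/(20*sqrt(2*pi))` ≈ 19.95 spikes/s — a closed form used as a unit
test anchor. Baseline statistics use the [−1500, −500) ms pre-scene window;
neurons with baseline ≥ 10 spikes/s are excluded
(`msn_inclusion_filter()`).

`z_normalize()` converts an SDF to baseline-SD units using the mean and
across-trial SD of the per-trial rate in the [−500, 0) ms pre-target window,
with an SD floor of 0.1 spikes/s. By default `compute_ztraces()` estimates
**one pooled baseline per neuron** from all trials of a task rather than one
per condition: pre-target activity cannot depend on the value of a target
that has not appeared, and per-condition SD estimates from ~10–15 trials
carry heavy-tailed `1/chi` noise that can inflate Z amplitudes two-fold for
individual neurons, which destabilises everything downstream (most visibly
the silhouette-based choice of K).

## Response-type clustering

Each neuron is summarised by two features (`build_features()`): mean Z in the
100–300 ms post-target window for good-contra and for bad-contra trials.
`silhouette_simulation()` repeats k-means (single random start per rep) for
K = 2…6 and averages silhouette widths over `reps` repetitions; the K with
the highest mean silhouette is chosen and confirmed by a one-way ANOVA with
Bonferroni-corrected pairwise comparisons across K. `assign_clusters()` then
runs k-means with many starts and names clusters canonically by the good−bad
centroid contrast: `cluster1` has the largest contrast (good-preferring),
`cluster2` the smallest (bad-preferring), remaining clusters in decreasing
order. Canonical naming makes cluster identities stable across seeds and
machines.

## Divergence onset

`sliding_paired_test()` computes a paired t test of good vs bad Z across
neurons in 50-ms windows stepped by 1 ms over [−575, +575] ms; the first
window covers [−575, −525) and the last [+525, +575), giving 1,101 windows.
`onset_from_pseries()` declares the divergence onset at the first run of at
least 10 consecutive windows with p < 0.05.

Two properties of this rule matter in practice and are documented here
because they are easy to miss:

1. **The run-length criterion has a high false-run rate on smoothed traces.**
   Adjacent 50-ms windows share 49 ms of data, and spike-density smoothing
   (σ = 20 ms) correlates neighbouring samples, so the effective number of
   independent tests is far smaller than 1,101 — but each "test" is also far
   from independent of its neighbours, which makes *runs* of spuriously
   significant windows common. Simulating null populations (no true
   difference) shows that a run of ≥ 10 significant windows occurs somewhere
   in the full grid in roughly 80% of populations, and before +95 ms in
   roughly 20% even when the search is restricted to post-stimulus times.
   This rate is scale-invariant (it does not shrink with noise amplitude) —
   it is a property of the rule, not of the effect size.
2. **Consequently, single-population onsets are noisy; medians across
   populations are stable.** The package therefore (a) exposes
   `search_from` in `onset_from_pseries()` so the search can be restricted
   to post-stimulus windows (the pipeline uses `search_from = 0`), and (b)
   measures injected change points as the **median onset across simulated
   replicates**, which recovers a +120 ms injected onset to within a few ms.
   Comparing two clusters' onsets from one population pair misorders them in
   ~20% of draws regardless of the true separation; ordering claims should
   be made on replicate medians.

## Reaction-time (latency) modulation

`split_by_rt()` divides a neuron's trials of one condition into reaction-time
quartiles (fast → slow; at least 8 valid trials). `latency_correlation()` is
the Pearson correlation between the group index (1–4) and the group-mean
windowed activity; degenerate groups (zero variance) are flagged and given
r = 0. `population_median_test()` is a two-sided Wilcoxon signed-rank test of
the per-neuron correlations against zero. The default activity window is
100–300 ms after target onset (`latency_window = c(100, 200)` as start and
duration); an alternative 50–200 ms window can be configured — both appear in
the literature on this analysis and the package treats the window as an
explicit parameter rather than baking one in.

Calibration (see `tests/testthat/test-acceptance.R`): with activity and
reaction time independent the test rejects at the nominal 5% rate; with a
moderate negative coupling (−0.5) between trial gain and reaction time it
detects the association in > 80% of populations of 38 neurons.

## Mixed-effects modelling

`fit_mixed_model()` fits a Gaussian mixed model by maximum likelihood
(`lme4`), with fixed effects given by the formula (default
`activity ~ scene * value * direction`) and random intercepts for monkey and
neuron-within-monkey. `parametric_bootstrap_compare()` tests nested models
by simulating replicate responses from the fitted null model, refitting both
models to each replicate with a fast profiled-deviance evaluator, and
computing an add-one bootstrap p value for the observed deviance difference.
Deviance differences smaller than the optimiser's resolution (10⁻³) are
treated as ties. Under a true null the procedure rejects at the nominal rate
(acceptance criterion 6). `posthoc_pairwise()` provides
Bonferroni-corrected `emmeans` contrasts but refuses to run when the omnibus
comparison is not significant; `choice_vs_fixation_wilcoxon()` contrasts
the same neurons' windowed activity across tasks.

## Pipeline

`run_pipeline()` chains all stages — simulate → behavior → preprocess →
cluster → diverge → latency → glmm — deterministically from a single
mandatory seed, writing CSV tables, JSON statistics, a `summary.json`, and a
`run.log` recording every parameter. A thin command-line front end with one
subcommand per stage is installed at
`system.file("scripts", "proactstriat.R", package = "proactstriat")`:

```sh
Rscript proactstriat.R all --config run.yaml --out results/ --seed 1
```

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "results")
res$summary$chosen_k
res$summary$divergence_onsets_ms
```

## Limitations

* The simulator is a calibration instrument, not a biophysical model: spike
  trains are Poisson, eye traces are minimum-jerk, and values/contexts enter
  only through rate profiles and action probabilities.
* The bundled action-count tables are small summary fixtures; session-level
  behavioural claims beyond them require simulation.
* The divergence run-length rule is reported as specified, but, as derived
  above, single-population onsets should be interpreted with its false-run
  rate in mind; prefer replicate medians.
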