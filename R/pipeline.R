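#' Default pipeline configuration
#'
#' Assembles the run configuration for [run_pipeline()]: simulation sizes, the
#' task/behavior/neuron ground truth, and analysis switches. Sizes default to
#' a small demonstration run (two simulated subjects, a few scene blocks per
#' scene, a few neurons per archetype) that completes in about a minute.
#'
#' @param seed mandatory integer seed for the whole run.
#' @param n_trials_per_scene scene blocks per scene and subject.
#' @param n_per_archetype neurons per archetype and subject (length 3 or 1).
#' @param n_fixation_trials fixation-task trials per subject.
#' @param silhouette_reps repetitions for [silhouette_simulation()].
#' @param bootstrap_iter iterations for [parametric_bootstrap_compare()].
#' @param latency_window `c(start, duration)` ms for the reaction-time
#'   quartile analysis (the normative 100-300 ms window; set `c(50, 150)` for
#'   the alternative figure-legend window).
#' @param posthoc_m Bonferroni divisor for the target-onset post hocs.
#' @param figures write overview figures (requires ggplot2).
#' @param write_eye write per-presentation eye-trace CSVs.
#' @param task,behavior optional [task_config()] / [behavior_truth()]
#'   overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            n_trials_per_scene = 8,
                            n_per_archetype = c(5, 5, 5),
                            n_fixation_trials = 16,
                            silhouette_reps = 100,
                            bootstrap_iter = 199,
                            latency_window = c(100, 200),
                            posthoc_m = 12,
                            figures = FALSE,
                            write_eye = FALSE,
                            task = NULL,
                            behavior = NULL) {
  if (missing(seed) || !is.finite(seed)) config_error("seed", "is mandatory")
  structure(list(seed = as.integer(seed),
                 n_trials_per_scene = n_trials_per_scene,
                 n_per_archetype = n_per_archetype,
                 n_fixation_trials = n_fixation_trials,
                 silhouette_reps = silhouette_reps,
                 bootstrap_iter = bootstrap_iter,
                 latency_window = latency_window,
                 posthoc_m = posthoc_m,
                 figures = figures, write_eye = write_eye,
                 task = task %||% task_config(n_trials_per_scene = n_trials_per_scene),
                 behavior = behavior %||% behavior_truth()),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes all stages on synthetic sessions for two simulated subjects:
#' session simulation, eye-trace action classification and behavioral
#' statistics, spike preprocessing with the medium-spiny-neuron filter,
#' k-means response typing with silhouette K selection, divergence-onset
#' estimation per cluster, reaction-time quartile correlation, and the mixed
#' model with parametric-bootstrap comparison plus choice-vs-fixation
#' contrast. All tabular outputs are written as CSV, metadata and statistics
#' as JSON, and a `summary.json` collects the headline results. The run is
#' fully determined by `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param through last stage to execute, one of `"simulate"`, `"behavior"`,
#'   `"preprocess"`, `"cluster"`, `"diverge"`, `"latency"`, `"glmm"`
#'   (default: all). Earlier stages a stage depends on always run; the
#'   `summary.json` is written only on a full run.
#' @return list with all stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir, through = "glmm") {
  stopifnot(inherits(config, "pipeline_config"))
  stage_order <- c("simulate", "behavior", "preprocess", "cluster",
                   "diverge", "latency", "glmm")
  through <- match.arg(through, stage_order)
  want <- function(s) match(s, stage_order) <= match(through, stage_order)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("stages: through %s", through),
                 sprintf("run started: %s", format(Sys.time())),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(unclass(config)),
                                       "\n", fixed = TRUE)[[1]]))

  # ---- stage: simulate ------------------------------------------------------
  sessions <- run_stage("simulate", {
    lapply(stats::setNames(nm = c("C", "S")), function(mk) {
      set.seed(config$seed + 100L * match(mk, c("C", "S")))
      neurons <- make_neuron_population(config$n_per_archetype)
      neurons <- lapply(neurons, function(nt) {
        nt$neuron_id <- paste0(mk, "_", nt$neuron_id); nt })
      generate_session(config$task, config$behavior, neurons,
                       seed = config$seed + match(mk, c("C", "S")) - 1L,
                       include_fixation = TRUE,
                       n_fixation_trials = config$n_fixation_trials)
    })
  })
  set.seed(config$seed + 1000L)  # stream for the analysis stages
  for (mk in names(sessions))
    write_session(sessions[[mk]], file.path(out_dir, paste0("session_", mk)),
                  write_eye = config$write_eye)

  # ---- stage: behavior ------------------------------------------------------
  behavior_res <- if (want("behavior")) run_stage("behavior", {
    res <- list()
    for (mk in names(sessions)) {
      ses <- sessions[[mk]]
      ch <- ses$trials[ses$trials$task == "choice", ]
      cls <- vapply(seq_len(nrow(ch)), function(i) {
        tr <- ses$eye[[ch$presentation_id[i]]]
        al <- classify_action(tr, c(ch$tgt_x[i], ch$tgt_y[i]),
                              window_side = ses$config$target_window_side,
                              hold_ms = ses$config$accept_hold_ms,
                              center_zone_radius = ses$config$center_zone_radius)
        c(al$label, al$rt_ms)
      }, character(2))
      ch$action_classified <- cls[1, ]
      ch$rt_classified <- suppressWarnings(as.numeric(cls[2, ]))
      agree <- mean(ch$action_classified == ch$action)
      counts <- action_count_table(
        data.frame(scene = ch$scene, value = ch$value,
                   action = ch$action_classified))
      # small demo runs can leave a scene without bad-object presentations;
      # proportions are only defined for scenes that have any
      props <- proportion_table(counts[counts$total > 0, , drop = FALSE])
      welch <- lapply(sort(unique(ch$scene)), function(sc) {
        g <- ch$rt_classified[ch$scene == sc & ch$value == "good" &
                                ch$action_classified == "accept"]
        b <- ch$rt_classified[ch$scene == sc & ch$value == "bad" &
                                ch$action_classified == "return"]
        if (sum(is.finite(g)) < 2 || sum(is.finite(b)) < 2) return(NULL)
        c(list(scene = sc), compare_rt_welch(g, b))
      })
      # degenerate on very small runs (e.g. no stay actions at all)
      fis <- tryCatch(fisher_stable_vs_flexible(counts),
                      error = function(e) {
                        message("fisher test skipped for ", mk, ": ",
                                conditionMessage(e))
                        NULL
                      })
      res[[mk]] <- list(trials = ch, agreement = agree, counts = counts,
                        proportions = props, welch = welch,
                        fisher = if (!is.null(fis))
                          fis[c("odds_ratio", "p", "phi")])
      utils::write.csv(counts, file.path(out_dir, sprintf("action_counts_%s.csv", mk)),
                       row.names = FALSE)
      utils::write.csv(props, file.path(out_dir, sprintf("proportions_%s.csv", mk)),
                       row.names = FALSE)
    }
    write_json_file(lapply(res, function(r)
      r[c("agreement", "welch", "fisher")]),
      file.path(out_dir, "behavior_stats.json"))
    res
  })

  # ---- stage: preprocess ----------------------------------------------------
  prep <- if (want("preprocess")) run_stage("preprocess", {
    res <- list()
    for (mk in names(sessions)) {
      ses <- sessions[[mk]]
      scene_on <- unique(ses$trials$scene_on_ms[ses$trials$task == "choice"])
      bl <- vapply(names(ses$spikes), function(id)
        baseline_stats(ses$spikes[[id]], scene_on)$mean, 0)
      keep <- msn_inclusion_filter(bl)
      res[[mk]] <- list(
        baseline = bl, kept = keep,
        z_vd = compute_ztraces(ses, keep, c("value", "direction")),
        z_svd = compute_ztraces(ses, keep, c("scene", "value", "direction")),
        z_fix = compute_ztraces(ses, keep, c("value", "direction"),
                                task = "fixation"))
    }
    res
  })

  # ---- stage: cluster -------------------------------------------------------
  clust <- if (want("cluster")) run_stage("cluster", {
    zg <- do.call(c, unname(lapply(prep, function(p)
      lapply(p$z_vd, function(z)
        list(good_contra = z$good_contra, bad_contra = z$bad_contra)))))
    features <- build_features(zg)
    ksel <- silhouette_simulation(features, reps = config$silhouette_reps)
    assign <- assign_clusters(features, k = ksel$chosen_k)
    features$cluster <- assign$labels[features$neuron_id]
    utils::write.csv(features, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    write_json_file(list(summary = ksel$summary, chosen_k = ksel$chosen_k,
                         confirmed = ksel$confirmed),
                    file.path(out_dir, "kselection.json"))
    list(features = features, ksel = ksel, assign = assign)
  })

  # ---- stage: diverge -------------------------------------------------------
  diverge <- if (want("diverge")) run_stage("diverge", {
    time_ms <- -575:575
    all_z <- do.call(c, unname(lapply(prep, function(p) p$z_vd)))
    res <- list(); rows <- list()
    for (cl in sort(unique(clust$features$cluster))) {
      ids <- clust$features$neuron_id[clust$features$cluster == cl]
      ids <- ids[vapply(ids, function(id)
        !is.null(all_z[[id]]$good_contra) && !is.null(all_z[[id]]$bad_contra), TRUE)]
      if (length(ids) < 3) next
      get_mat <- function(cond) t(vapply(ids, function(id) {
        zt <- all_z[[id]][[cond]]
        zt$z[zt$time_ms >= time_ms[1] & zt$time_ms <= time_ms[length(time_ms)]]
      }, numeric(length(time_ms))))
      ps <- sliding_paired_test(get_mat("good_contra"), get_mat("bad_contra"),
                                time_ms)
      on <- onset_from_pseries(ps, search_from = 0)
      res[[cl]] <- on$onset_ms
      rows[[cl]] <- cbind(cluster = cl, ps,
                          significant = on$significant)
    }
    utils::write.csv(do.call(rbind, rows), file.path(out_dir, "divergence.csv"),
                     row.names = FALSE)
    write_json_file(res, file.path(out_dir, "onsets.json"))
    res
  })

  # ---- stage: latency -------------------------------------------------------
  latency <- if (want("latency")) run_stage("latency", {
    rows <- list()
    for (mk in names(sessions)) {
      ses <- sessions[[mk]]
      ch <- behavior_res[[mk]]$trials
      ch <- ch[is.finite(ch$rt_classified), ]
      scene_on <- unique(ses$trials$scene_on_ms[ses$trials$task == "choice"])
      for (id in prep[[mk]]$kept) {
        st <- ses$spikes[[id]]
        for (v in c("good", "bad")) for (d in c("contra", "ipsi")) {
          sel <- ch$value == v & ch$direction == d
          if (sum(sel) < 8) next
          zt <- prep[[mk]]$z_vd[[id]][[paste(v, d, sep = "_")]]
          base <- list(mean = zt$baseline_mean, sd = zt$baseline_sd)
          act <- trial_window_activity(st, ch$target_on_ms[sel],
                                       config$latency_window[1],
                                       config$latency_window[2], base)
          df <- data.frame(neuron_id = id, rt_ms = ch$rt_classified[sel],
                           activity = act)
          lc <- latency_correlations_by_neuron(df)
          if (!is.null(lc) && nrow(lc))
            rows[[length(rows) + 1L]] <- cbind(condition = paste(v, d, sep = "_"), lc)
        }
      }
    }
    corr <- do.call(rbind, rows)
    utils::write.csv(corr, file.path(out_dir, "latency_corr.csv"),
                     row.names = FALSE)
    med <- list()
    if (!is.null(corr)) {
      corr$cluster <- clust$features$cluster[match(corr$neuron_id,
                                                   clust$features$neuron_id)]
      for (cl in sort(unique(corr$cluster))) for (cd in unique(corr$condition)) {
        rs <- corr$r[corr$cluster == cl & corr$condition == cd]
        rs <- rs[is.finite(rs)]
        if (length(rs) >= 5) {
          tst <- population_median_test(rs)
          med[[paste(cl, cd, sep = ".")]] <-
            list(median_r = stats::median(rs), n = length(rs), p = tst$p)
        }
      }
    }
    write_json_file(med, file.path(out_dir, "medians.json"))
    list(correlations = corr, medians = med)
  })

  # ---- stage: glmm ----------------------------------------------------------
  glmm <- if (want("glmm")) run_stage("glmm", {
    recs <- list()
    for (mk in names(sessions)) for (id in prep[[mk]]$kept) {
      z <- prep[[mk]]$z_svd[[id]]
      for (k in names(z)) {
        parts <- strsplit(k, "_")[[1]]
        recs[[length(recs) + 1L]] <- data.frame(
          monkey_id = mk, neuron_id = id, scene = parts[1], value = parts[2],
          direction = parts[3],
          activity = mean_window_activity(z[[k]], 100, 200))
      }
    }
    records <- do.call(rbind, recs)
    full <- fit_mixed_model(records, activity ~ scene * value * direction)
    null <- fit_mixed_model(records, activity ~ 1)
    lrt <- parametric_bootstrap_compare(full, null, n_iter = config$bootstrap_iter)
    posthoc <- if (lrt$p < 0.05)
      posthoc_pairwise(full, ~ value * direction, m = config$posthoc_m,
                       lrt = lrt, by = "scene") else NULL
    # choice vs fixation for bad-preferring neurons recorded in both tasks
    cl2 <- clust$features$neuron_id[clust$features$cluster == "cluster2"]
    cf <- lapply(c("bad_contra", "bad_ipsi"), function(cond) {
      pm <- do.call(rbind, lapply(names(sessions), function(mk) {
        ids <- intersect(cl2, prep[[mk]]$kept)
        ids <- ids[vapply(ids, function(id)
          !is.null(prep[[mk]]$z_vd[[id]][[cond]]) &&
            !is.null(prep[[mk]]$z_fix[[id]][[cond]]), TRUE)]
        if (!length(ids)) return(NULL)
        data.frame(
          choice = vapply(ids, function(id)
            mean_window_activity(prep[[mk]]$z_vd[[id]][[cond]], 100, 200), 0),
          fixation = vapply(ids, function(id)
            mean_window_activity(prep[[mk]]$z_fix[[id]][[cond]], 100, 200), 0))
      }))
      if (is.null(pm) || nrow(pm) < 5) return(NULL)
      c(list(condition = cond),
        choice_vs_fixation_wilcoxon(pm$choice, pm$fixation))
    })
    write_json_file(list(observed_dev_diff = lrt$observed_dev_diff, p = lrt$p,
                         n_iter = lrt$n_iter, n_fail = lrt$n_fail,
                         choice_vs_fixation = cf),
                    file.path(out_dir, "lrt.json"))
    if (!is.null(posthoc))
      utils::write.csv(posthoc$contrasts, file.path(out_dir, "posthoc.csv"),
                       row.names = FALSE)
    list(records = records, full = full, null = null, lrt = lrt,
         posthoc = posthoc, choice_vs_fixation = cf)
  })

  # ---- summary --------------------------------------------------------------
  summary <- NULL
  if (through == "glmm") {
  truth_arch <- vapply(
    do.call(c, unname(lapply(sessions, function(s) s$ground_truth$neurons))),
    function(nt) nt$archetype, "")
  names(truth_arch) <- vapply(
    do.call(c, unname(lapply(sessions, function(s) s$ground_truth$neurons))),
    function(nt) nt$neuron_id, "")
  summary <- list(
    seed = config$seed,
    classifier_agreement = vapply(behavior_res, function(r) r$agreement, 0),
    chosen_k = clust$ksel$chosen_k,
    cluster_sizes = as.list(table(clust$features$cluster)),
    archetype_sizes = as.list(table(truth_arch[clust$features$neuron_id])),
    divergence_onsets_ms = diverge,
    glmm_bootstrap_p = glmm$lrt$p,
    fisher = lapply(behavior_res, function(r) r$fisher))
  write_json_file(summary, file.path(out_dir, "summary.json"))
  }
  writeLines(c(log_lines, sprintf("run finished: %s", format(Sys.time()))),
             file.path(out_dir, "run.log"))

  if (isTRUE(config$figures) && want("cluster"))
    pipeline_figures(behavior_res, clust, out_dir)

  invisible(list(sessions = sessions, behavior = behavior_res, prep = prep,
                 clusters = clust, divergence = diverge, latency = latency,
                 glmm = glmm, summary = summary))
}

# overview figures (proportions bar chart, feature scatter); optional
pipeline_figures <- function(behavior_res, clust, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not available; figures skipped")
    return(invisible(NULL))
  }
  props <- do.call(rbind, lapply(names(behavior_res), function(mk) {
    p <- behavior_res[[mk]]$proportions
    long <- utils::stack(p[, -1])
    data.frame(monkey = mk, scene = p$scene, action = long$ind, pct = long$values)
  }))
  g1 <- ggplot2::ggplot(props, ggplot2::aes(x = factor(scene), y = pct, fill = action)) +
    ggplot2::geom_col() + ggplot2::facet_wrap(~monkey) +
    ggplot2::labs(x = "Scene", y = "% of bad-object presentations")
  ggplot2::ggsave(file.path(out_dir, "fig_behavior_proportions.png"), g1,
                  width = 7, height = 4, dpi = 120)
  g2 <- ggplot2::ggplot(clust$features,
                        ggplot2::aes(z_good, z_bad, color = cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Z (good, contra)", y = "Z (bad, contra)")
  ggplot2::ggsave(file.path(out_dir, "fig_features_scatter.png"), g2,
                  width = 5, height = 4, dpi = 120)
  invisible(NULL)
}
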