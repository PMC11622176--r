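#' Build the 2-D clustering feature matrix
#'
#' One row per neuron: the Z-scored mean activity in the 200-ms window from
#' 100 to 300 ms after onset of the contralateral good object (`z_good`) and
#' the contralateral bad object (`z_bad`). Neurons missing either condition
#' are dropped with a warning.
#'
#' @param ztraces named list (per neuron) of lists with elements `good_contra`
#'   and `bad_contra`, each a `z_trace` from [z_normalize()].
#' @param window_start_ms,window_dur_ms analysis window.
#' @return data frame with `neuron_id`, `z_good`, `z_bad`.
#' @export
build_features <- function(ztraces, window_start_ms = 100, window_dur_ms = 200) {
  rows <- lapply(names(ztraces), function(id) {
    zt <- ztraces[[id]]
    if (is.null(zt$good_contra) || is.null(zt$bad_contra)) {
      warning("neuron ", id, " dropped: missing contralateral condition")
      return(NULL)
    }
    data.frame(neuron_id = id,
               z_good = mean_window_activity(zt$good_contra, window_start_ms, window_dur_ms),
               z_bad = mean_window_activity(zt$bad_contra, window_start_ms, window_dur_ms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, c("z_good", "z_bad")])
}

#' Select the number of clusters by repeated silhouette analysis
#'
#' For each candidate `K`, k-means is re-run `reps` times and the mean
#' silhouette width of each run is recorded. By default each repetition
#' resamples the k-means initialization (fresh random centers on the full
#' data); `mode = "bootstrap"` instead resamples neurons with replacement.
#' Candidate values of `K` are then compared by one-way ANOVA with pairwise
#' Welch t tests at the Bonferroni level `alpha / choose(length(k_range), 2)`;
#' the chosen `K` maximizes the mean silhouette and is flagged as unconfirmed
#' if any pairwise comparison against it fails.
#'
#' @param features feature data frame from [build_features()] (or any numeric
#'   matrix-like with columns `z_good`, `z_bad`).
#' @param k_range candidate cluster counts.
#' @param reps repetitions per `K`.
#' @param mode `"init"` (initialization resampling) or `"bootstrap"`
#'   (resampling neurons).
#' @param alpha familywise significance level for the post hoc confirmation.
#' @return list of class `k_selection`: `summary` (per-K mean/SD silhouette),
#'   `chosen_k`, `confirmed`, `anova` (F and p, or NULL when reps < 2),
#'   `posthoc` (pairwise table), `reps`, `mode`.
#' @export
silhouette_simulation <- function(features, k_range = 2:6, reps = 5000,
                                  mode = c("init", "bootstrap"), alpha = 0.05) {
  mode <- match.arg(mode)
  x <- feature_matrix(features)
  if (nrow(unique(x)) <= max(k_range))
    stop("degenerate features: fewer distinct points than clusters", call. = FALSE)
  sil <- matrix(NA_real_, nrow = reps, ncol = length(k_range),
                dimnames = list(NULL, paste0("K", k_range)))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    for (r in seq_len(reps)) {
      if (mode == "init") {
        km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
        d <- stats::dist(x)
      } else {
        idx <- sample(nrow(x), replace = TRUE)
        xb <- x[idx, , drop = FALSE]
        if (nrow(unique(xb)) <= k) { sil[r, j] <- NA; next }
        km <- suppressWarnings(stats::kmeans(xb, centers = k, nstart = 10))
        d <- stats::dist(xb)
      }
      sil[r, j] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    }
  }
  means <- colMeans(sil, na.rm = TRUE)
  sds <- apply(sil, 2, stats::sd, na.rm = TRUE)
  summary_df <- data.frame(k = k_range, mean_silhouette = unname(means),
                           sd_silhouette = unname(sds))
  chosen_k <- k_range[which.max(means)]

  anova_res <- NULL; posthoc <- NULL; confirmed <- NA
  if (reps >= 2) {
    long <- data.frame(sil = as.vector(sil),
                       k = factor(rep(k_range, each = reps)))
    long <- long[is.finite(long$sil), ]
    fit <- stats::aov(sil ~ k, data = long)
    an <- summary(fit)[[1]]
    anova_res <- list(F = an$`F value`[1], p = an$`Pr(>F)`[1])
    pairs <- utils::combn(seq_along(k_range), 2)
    m <- ncol(pairs)
    posthoc <- data.frame(k1 = k_range[pairs[1, ]], k2 = k_range[pairs[2, ]],
                          p = NA_real_, significant = NA)
    for (i in seq_len(m)) {
      a <- sil[, pairs[1, i]]; b <- sil[, pairs[2, i]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      p <- if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
        if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0  # degenerate repetitions
      } else stats::t.test(a, b)$p.value
      posthoc$p[i] <- p
      posthoc$significant[i] <- p < alpha / m
    }
    involves <- posthoc$k1 == chosen_k | posthoc$k2 == chosen_k
    confirmed <- all(posthoc$significant[involves])
  }
  structure(list(summary = summary_df, chosen_k = chosen_k,
                 confirmed = confirmed, anova = anova_res, posthoc = posthoc,
                 reps = reps, mode = mode),
            class = "k_selection")
}

#' Assign canonical cluster labels by k-means
#'
#' Runs k-means with many restarts (best within-cluster sum of squares kept)
#' and renames clusters deterministically so downstream analyses can refer to
#' them by response type. For `K = 3`: `cluster1` is the centroid with the
#' largest good-minus-bad contrast (good-preferring), `cluster2` the smallest
#' (bad-preferring), and `cluster3` the remainder (value-insensitive visual
#' response). For other `K`, clusters are ordered by decreasing contrast.
#'
#' @param features feature data frame from [build_features()].
#' @param k number of clusters (>= 2).
#' @param nstart k-means restarts.
#' @return list of class `cluster_assignment`: `labels` (named character
#'   vector per neuron), `centroids` (data frame), `fit` (the `kmeans`
#'   object).
#' @export
assign_clusters <- function(features, k = 3, nstart = 50) {
  stopifnot(k >= 2)
  x <- feature_matrix(features)
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart))
  contrast <- km$centers[, "z_good"] - km$centers[, "z_bad"]
  ord <- order(contrast, decreasing = TRUE)
  # canonical order: cluster1 = max contrast, cluster2 = min contrast,
  # remaining clusters by decreasing contrast
  canon <- if (k >= 3) c(ord[1], ord[k], ord[seq(2, k - 1)]) else ord
  new_name <- character(k)
  new_name[canon] <- paste0("cluster", seq_len(k))
  labels <- new_name[km$cluster]
  names(labels) <- features$neuron_id
  centroids <- data.frame(cluster = new_name,
                          z_good = km$centers[, "z_good"],
                          z_bad = km$centers[, "z_bad"],
                          size = km$size, stringsAsFactors = FALSE)
  centroids <- centroids[order(centroids$cluster), ]
  rownames(centroids) <- NULL
  structure(list(labels = labels, centroids = centroids, fit = km),
            class = "cluster_assignment")
}
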