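#' Split trials into reaction-time quartile groups
#'
#' Trials are ranked by reaction time (ties broken by original trial order)
#' and split into four groups of as-equal-as-possible size, group 1 having the
#' shortest latencies. When the trial count is not a multiple of four the
#' remainder goes to the fastest groups, so 10 trials split 3/3/2/2.
#'
#' @param trials data frame with columns `rt_ms` (finite) and any per-trial
#'   covariates to carry along.
#' @param n_groups number of groups.
#' @param min_trials minimum number of trials required (default 8 = 2 per
#'   quartile); fewer raises a warning and returns NULL.
#' @return the input data frame with an integer `rt_group` column, or NULL.
#' @export
split_by_rt <- function(trials, n_groups = 4, min_trials = 8) {
  trials <- trials[is.finite(trials$rt_ms), , drop = FALSE]
  n <- nrow(trials)
  if (n < min_trials) {
    warning("fewer than ", min_trials, " trials with valid reaction times; skipped")
    return(NULL)
  }
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(trials$rt_ms)  # stable: ties keep trial order
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), sizes)
  trials$rt_group <- grp
  trials
}

#' Correlation between reaction-time group order and mean activity
#'
#' Pearson correlation of the group indices (1..4, fastest to slowest) with
#' the per-group mean activities. Zero variance in the means yields a flagged
#' `r = 0`.
#'
#' @param group_means numeric vector of mean activities, ordered by group.
#' @return list with `r` and `flagged` (TRUE when the means were constant).
#' @export
latency_correlation <- function(group_means) {
  k <- length(group_means)
  if (stats::sd(group_means) == 0)
    return(list(r = 0, flagged = TRUE))
  list(r = stats::cor(seq_len(k), group_means), flagged = FALSE)
}

#' Per-neuron latency correlations for one condition
#'
#' Convenience wrapper: splits each neuron's trials into reaction-time
#' quartiles, averages activity per group, and computes the group-order
#' correlation.
#'
#' @param trials data frame with `neuron_id`, `rt_ms`, `activity` (windowed
#'   mean activity per trial).
#' @param min_trials minimum valid trials per neuron.
#' @return data frame with `neuron_id`, `r`, `flagged`.
#' @export
latency_correlations_by_neuron <- function(trials, min_trials = 8) {
  ids <- unique(trials$neuron_id)
  rows <- lapply(ids, function(id) {
    tr <- split_by_rt(trials[trials$neuron_id == id, , drop = FALSE],
                      min_trials = min_trials)
    if (is.null(tr)) return(NULL)
    gm <- tapply(tr$activity, tr$rt_group, mean)
    lc <- latency_correlation(as.numeric(gm))
    data.frame(neuron_id = id, r = lc$r, flagged = lc$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test of the population median correlation
#'
#' Tests whether the median of per-neuron latency correlations differs from
#' zero (two-sided).
#'
#' @param r_values numeric vector of correlation coefficients (n >= 5).
#' @return list with `W` (signed-rank statistic) and `p`.
#' @export
population_median_test <- function(r_values) {
  r_values <- r_values[is.finite(r_values)]
  if (length(r_values) < 5)
    stop("population median test requires at least five values", call. = FALSE)
  if (all(r_values == 0)) return(list(W = 0, p = 1))
  ht <- suppressWarnings(stats::wilcox.test(r_values, mu = 0))
  list(W = unname(ht$statistic), p = ht$p.value)
}
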