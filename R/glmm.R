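#' Fit a linear mixed model of windowed neuronal activity
#'
#' Fits `fixed` (e.g. `activity ~ scene * value * direction`) with random
#' intercepts for each grouping term in `random` (default monkey and
#' neuron-within-monkey) by maximum likelihood, so that deviances of nested
#' models are directly comparable. Responses are per-neuron condition means
#' (the mean windowed PSTH of each neuron), not per-trial values. Singular
#' fits (a variance component estimated at the zero boundary) are flagged but
#' still returned.
#'
#' @param records data frame of activity records; factors used in `fixed` are
#'   converted to factors.
#' @param fixed two-sided fixed-effects formula.
#' @param random character vector of random-intercept grouping terms, each a
#'   variable name or `:`-interaction of variable names.
#' @param include_session also add a session random intercept (named by the
#'   `session_id` column) when available.
#' @return object of class `lmm_fit`: `model` (the `lmerMod`), `deviance`,
#'   `fixef`, `varcomp` (per-term SDs), `sigma`, `singular`, plus the design
#'   pieces needed for bootstrapping.
#' @export
fit_mixed_model <- function(records,
                            fixed = activity ~ scene * value * direction,
                            random = c("monkey_id", "monkey_id:neuron_id"),
                            include_session = FALSE) {
  if (include_session && "session_id" %in% names(records))
    random <- c(random, "session_id")
  vars <- unique(unlist(strsplit(random, ":", fixed = TRUE)))
  for (v in c(vars, all.vars(fixed[[3]])))
    if (!is.numeric(records[[v]])) records[[v]] <- factor(records[[v]])
  re_terms <- paste0("(1 | ", random, ")")
  form <- stats::as.formula(paste(deparse(fixed[[2]]), "~",
                                  paste(deparse(fixed[[3]], width.cutoff = 500), collapse = ""),
                                  "+", paste(re_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  model <- lme4::lmer(form, data = records, REML = FALSE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(
    model = model, data = records, fixed = fixed, random = random,
    deviance = stats::deviance(model), fixef = lme4::fixef(model),
    varcomp = vc[, c("grp", "sdcor")],
    sigma = stats::sigma(model), singular = lme4::isSingular(model),
    response = deparse(fixed[[2]])), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML):", deparse(x$fixed), "\n")
  cat("Random intercepts:", paste(x$random, collapse = ", "), "\n")
  cat("Deviance:", format(x$deviance), if (x$singular) " (singular fit)" else "", "\n")
  invisible(x)
}

# ---- fast profiled ML deviance for Gaussian random-intercept LMMs ----------
# Used by the parametric bootstrap, where ~2e5 refits make lme4's per-fit
# set-up cost prohibitive. Validated against lme4's deviance in the test
# suite; lme4 remains the user-facing fitter.

# struct: design pieces shared by all bootstrap responses
lmm_structure <- function(X, flist) {
  n <- nrow(X)
  f2i <- lapply(flist, function(f) as.integer(droplevels(as.factor(f))))
  q <- vapply(f2i, max, 1L)
  Z <- matrix(0, n, sum(q))
  off <- c(0L, cumsum(q))
  for (k in seq_along(f2i)) Z[cbind(seq_len(n), off[k] + f2i[[k]])] <- 1
  list(X = X, Z = Z, n = n, p = ncol(X), q = q,
       idx = rep(seq_along(q), q),
       ZtZ = crossprod(Z), ZtX = crossprod(Z, X), XtX = crossprod(X))
}

# profiled ML deviance as a function of theta (relative RE standard
# deviations); even in each theta component, so optimization is unconstrained
lmm_devfun <- function(s, y) {
  Zty <- drop(crossprod(s$Z, y)); Xty <- drop(crossprod(s$X, y))
  yty <- sum(y * y)
  qtot <- sum(s$q); m <- qtot + s$p
  zi <- seq_len(qtot); xi <- qtot + seq_len(s$p)
  M <- matrix(0, m, m); M[xi, xi] <- s$XtX
  rhs <- numeric(m); rhs[xi] <- Xty
  n <- s$n; idx <- s$idx; ZtZ <- s$ZtZ; ZtX <- s$ZtX
  function(theta) {
    th <- abs(theta)[idx]
    AtA <- ZtZ * tcrossprod(th); diag(AtA) <- diag(AtA) + 1
    AtX <- ZtX * th
    M[zi, zi] <- AtA; M[zi, xi] <- AtX; M[xi, zi] <- t(AtX)
    R <- chol(M)
    rhs[zi] <- Zty * th
    u <- backsolve(R, rhs, transpose = TRUE)
    r2 <- yty - sum(u * u)
    2 * sum(log(diag(R)[zi])) + n * (1 + log(2 * pi * r2 / n))
  }
}

# minimize the profiled deviance; returns deviance, |theta|, beta, sigma
fit_lmm_fast <- function(s, y, start = NULL) {
  f <- lmm_devfun(s, y)
  k <- length(s$q)
  if (is.null(start)) start <- rep(0.5, k)
  if (k == 1L) {
    opt <- stats::optim(start, f, method = "Brent",
                        lower = 0, upper = max(10, 4 * start))
  } else {
    opt <- stats::optim(start, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-7, maxit = 500))
  }
  theta <- abs(opt$par)
  # recover beta and sigma at the optimum
  th <- theta[s$idx]
  qtot <- sum(s$q); zi <- seq_len(qtot); xi <- qtot + seq_len(s$p)
  AtA <- s$ZtZ * tcrossprod(th); diag(AtA) <- diag(AtA) + 1
  AtX <- s$ZtX * th
  M <- rbind(cbind(AtA, AtX), cbind(t(AtX), s$XtX))
  rhs <- c(drop(crossprod(s$Z, y)) * th, drop(crossprod(s$X, y)))
  sol <- solve(M, rhs)
  r2 <- sum(y * y) - sum(sol * rhs)
  list(deviance = opt$value, theta = theta, beta = sol[xi],
       sigma = sqrt(r2 / s$n))
}

# grouping-factor list for a fit's random terms
random_flist <- function(fit) {
  lapply(fit$random, function(term) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    interaction(fit$data[vars], drop = TRUE)
  })
}

fast_structure_from_fit <- function(fit) {
  X <- stats::model.matrix(stats::as.formula(paste("~", deparse(fit$fixed[[3]], width.cutoff = 500))),
                           data = fit$data)
  lmm_structure(X, random_flist(fit))
}

#' Parametric-bootstrap comparison of nested mixed models
#'
#' Assesses whether the full model fits better than the nested null: the
#' observed deviance difference is referred to its bootstrap distribution,
#' obtained by repeatedly simulating responses from the fitted null model
#' (fixed effects plus fresh random-effect and residual draws) and refitting
#' both models to each simulated response. The p value uses the add-one rule
#' `p = (1 + #{boot >= observed}) / (1 + n_iter)`, so it is never exactly
#' zero. Replicates with failed refits are discarded and counted; more than
#' 5% failures raises a warning.
#'
#' @param full_fit,null_fit `lmm_fit` objects on the same records, null nested
#'   in full.
#' @param n_iter bootstrap iterations.
#' @param seed optional integer seed for the bootstrap draws.
#' @return object of class `bootstrap_lrt`: `observed_dev_diff`, `p`,
#'   `n_iter`, `boot_dev_diffs`, `n_fail`.
#' @export
parametric_bootstrap_compare <- function(full_fit, null_fit, n_iter = 10000,
                                         seed = NULL) {
  stopifnot(inherits(full_fit, "lmm_fit"), inherits(null_fit, "lmm_fit"))
  if (nrow(full_fit$data) != nrow(null_fit$data))
    stop("full and null models must be fitted to the same records", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  s_full <- fast_structure_from_fit(full_fit)
  s_null <- fast_structure_from_fit(null_fit)
  if (s_null$p > s_full$p)
    stop("null model must be nested in the full model", call. = FALSE)

  # observed difference, computed with the same evaluator used for the
  # bootstrap replicates so observed and simulated deviances are commensurate
  obs_full <- fit_lmm_fast(s_full, full_fit$data[[full_fit$response]],
                           start = pmax(match_theta(full_fit), 0.05))
  obs_null <- fit_lmm_fast(s_null, null_fit$data[[null_fit$response]],
                           start = pmax(match_theta(null_fit), 0.05))
  observed <- obs_null$deviance - obs_full$deviance

  n <- s_null$n
  qtot <- sum(s_null$q)
  mu <- drop(s_null$X %*% obs_null$beta)
  th <- obs_null$theta[s_null$idx]
  sig <- obs_null$sigma
  start_full <- pmax(rep(mean(obs_null$theta), length(s_full$q)), 0.1)
  start_null <- pmax(obs_null$theta, 0.1)

  boot <- numeric(n_iter); fail <- 0L
  for (i in seq_len(n_iter)) {
    u <- stats::rnorm(qtot) * th
    y <- mu + sig * (drop(s_null$Z %*% u) + stats::rnorm(n))
    dd <- tryCatch({
      fn <- fit_lmm_fast(s_null, y, start = start_null)$deviance
      ff <- fit_lmm_fast(s_full, y, start = start_full)$deviance
      fn - ff
    }, error = function(e) NA_real_)
    boot[i] <- dd
    if (!is.finite(dd)) fail <- fail + 1L
  }
  ok <- is.finite(boot)
  if (fail > 0.05 * n_iter)
    warning("more than 5% of bootstrap refits failed (", fail, "/", n_iter, ")")
  # deviance differences below optimizer precision are ties, not exceedances
  # (the profiled-deviance optimum is resolved to ~1e-3 in absolute terms,
  # negligible against the O(1)+ scale of real deviance differences)
  tol <- max(1e-3, 1e-6 * abs(observed))
  p <- (1 + sum(boot[ok] >= observed - tol)) / (1 + sum(ok))
  structure(list(observed_dev_diff = observed, p = p, n_iter = n_iter,
                 boot_dev_diffs = boot[ok], n_fail = fail),
            class = "bootstrap_lrt")
}

# per-term relative SDs from the lme4 fit, ordered like fit$random
match_theta <- function(fit) {
  vc <- fit$varcomp
  sds <- vc$sdcor[match(fit$random, vc$grp)]
  sds[is.na(sds)] <- 0
  sds / fit$sigma
}

#' @export
print.bootstrap_lrt <- function(x, ...) {
  cat("Parametric bootstrap LRT (", x$n_iter, " iterations)\n", sep = "")
  cat("Observed deviance difference:", format(x$observed_dev_diff), "\n")
  cat("p =", format(x$p), if (x$n_fail) paste0("(", x$n_fail, " failed refits)") else "", "\n")
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc contrasts
#'
#' Estimated marginal means for each factor cell of the fitted model and all
#' pairwise t contrasts (unadjusted p compared against `alpha / m`). Post hocs
#' are only meaningful after a significant omnibus comparison, so a
#' non-significant `lrt` is refused.
#'
#' @param fit an `lmm_fit` retained by the bootstrap comparison.
#' @param specs factors defining the cells, e.g. `~ value * direction`.
#' @param m Bonferroni divisor (number of planned pairwise tests).
#' @param lrt optional `bootstrap_lrt` for the omnibus gate.
#' @param by optional conditioning factor name (contrasts within its levels).
#' @param alpha familywise level.
#' @return list of class `posthoc_table`: `emmeans` (cell means and SEs),
#'   `contrasts` (estimate, SE, t, raw p, 95% CI, effect size, significance at
#'   `alpha / m`), `m`, `alpha`.
#' @export
posthoc_pairwise <- function(fit, specs, m, lrt = NULL, by = NULL,
                             alpha = 0.05) {
  if (!is.null(lrt) && lrt$p >= alpha)
    stop("omnibus model comparison is not significant; post hoc tests refused",
         call. = FALSE)
  emm <- emmeans::emmeans(fit$model, specs = specs, by = by,
                          data = fit$data, lmer.df = "satterthwaite")
  cells <- as.data.frame(emm)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  cdf <- as.data.frame(summary(ctr, infer = c(TRUE, TRUE)))
  sigma <- fit$sigma
  out <- data.frame(contrast = cdf$contrast)
  if (!is.null(by)) out[[by]] <- cdf[[by]]
  out$estimate <- cdf$estimate
  out$SE <- cdf$SE
  out$df <- cdf$df
  out$t <- cdf$t.ratio
  out$p <- cdf$p.value
  out$lower_cl <- cdf$lower.CL
  out$upper_cl <- cdf$upper.CL
  out$effect_size <- cdf$estimate / sigma
  out$significant <- cdf$p.value < alpha / m
  structure(list(emmeans = cells, contrasts = out, m = m, alpha = alpha),
            class = "posthoc_table")
}

#' Paired Wilcoxon comparison of choice- vs fixation-task activity
#'
#' Two-sided Wilcoxon signed-rank test on per-neuron differences of mean
#' windowed activity between the choice and fixation tasks (neurons recorded
#' in both).
#'
#' @param choice_means,fixation_means paired per-neuron means, same order.
#' @return list with `W`, `p`, `n`, `median_diff`.
#' @export
choice_vs_fixation_wilcoxon <- function(choice_means, fixation_means) {
  stopifnot(length(choice_means) == length(fixation_means))
  ok <- is.finite(choice_means) & is.finite(fixation_means)
  x <- choice_means[ok]; y <- fixation_means[ok]
  if (length(x) < 5)
    stop("paired comparison requires at least five neuron pairs", call. = FALSE)
  if (all(x == y)) return(list(W = 0, p = 1, n = length(x), median_diff = 0))
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value, n = length(x),
       median_diff = stats::median(x - y))
}
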