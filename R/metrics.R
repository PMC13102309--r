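#' Simulated performance of a fitted model
#'
#' Runs the model autonomously on fresh realizations of the task — its own
#' choices, its own rewards — and averages the fraction of trials on which it
#' chose the better option. Averaging over simulations absorbs the
#' stochasticity of the softmax choice rule. With `mode = "matched"` the
#' reversal schedule of a supplied trial table is reused on every simulation
#' (the posterior-predictive style check); rewards are still drawn fresh.
#'
#' @param fit A `metarl_fit`, or a named parameter list (then give `model`).
#' @param cfg Task configuration to simulate on (defaults to the fit's).
#' @param n_sims Number of simulated sessions to average (default 100).
#' @param seed Integer seed.
#' @param model Model id when `fit` is a plain parameter list.
#' @param mode `"fresh"` (new schedule each simulation) or `"matched"`.
#' @param trials Trial table providing the schedule for `mode = "matched"`.
#' @return Mean fraction of better-option choices, in \[0, 1\].
#' @examples
#' ag <- agent_spec("mf", list(alpha = 0.9, beta = 15))
#' model_performance(ag$params, task_config(), n_sims = 10, seed = 1,
#'                   model = "mf")
#' @export
model_performance <- function(fit, cfg = NULL, n_sims = 100, seed = NULL,
                              model = NULL, mode = c("fresh", "matched"),
                              trials = NULL) {
  mode <- match.arg(mode)
  if (inherits(fit, "metarl_fit")) {
    model <- fit$model
    params <- fit$params
    cfg <- cfg %||% fit$cfg
    q0 <- fit$settings$q0
    reward_scale <- fit$settings$reward_scale
  } else {
    params <- fit
    q0 <- 50
    reward_scale <- 100
    if (is.null(model)) stop_input("`model` is required for parameter lists.")
  }
  if (is.null(cfg)) stop_input("`cfg` is required.")
  stopifnot(n_sims >= 1)
  agent <- agent_spec(model, params, q0 = q0, reward_scale = reward_scale)
  sched <- if (mode == "matched") {
    if (is.null(trials)) stop_input("`trials` is required for matched mode.")
    trials[c("trial", "block", "better_option")]
  } else NULL
  perfs <- purrr::map_dbl(seq_len(n_sims), function(i) {
    tt <- run_episode(agent, cfg, seed = child_seed(seed, i),
                      schedule = sched)
    mean(tt$correct)
  })
  mean(perfs)
}

#' Metacognitive efficiency ratio
#'
#' Backward-model simulated performance divided by Forward-model simulated
#' performance. Values near 1 indicate a first-order observer; values above 1
#' are permitted (an error-monitoring analogue).
#'
#' @param perf_backward,perf_forward Simulated performances.
#' @return The elementwise ratio.
#' @export
metarl_ratio <- function(perf_backward, perf_forward) {
  if (any(perf_forward == 0)) {
    stop_input("`perf_forward` must be positive.")
  }
  perf_backward / perf_forward
}

#' Quadratic scoring rule
#'
#' `1 - mean(((conf - 1)/4 - correct)^2)`: confidence normalized to the unit
#' interval is scored against trial correctness. The maximum of 1 is reached
#' only under perfect normalized calibration.
#'
#' @param trials A trial tibble with `confidence` and `correct`.
#' @return The QSR score (at most 1).
#' @export
qsr <- function(trials) {
  1 - mean((normalize_confidence(trials$confidence) - trials$correct)^2)
}

#' Scaled quadratic scoring rule
#'
#' Maximizes the QSR over an affine rescaling `(H - L) * conf + L` of the
#' empirical confidences with bounds `L, H` in \[1, 5\], `L < H`, then applies
#' the same `(x - 1)/4` normalization. Note the rescaling acts on confidences
#' that already live on \[1, 5\], so the identity map (`H - L = 1, L = 0`) is
#' not representable inside the bound box; the returned score is the maximum
#' of the written objective over the feasible box, found by multi-start
#' bounded optimization (the objective is a concave quadratic in (L, H)).
#'
#' @param trials A trial tibble.
#' @param n_starts Number of optimizer starts.
#' @return A one-row tibble with `scaled_qsr`, `L`, `H`.
#' @export
scaled_qsr <- function(trials, n_starts = 5) {
  conf <- trials$confidence
  correct <- trials$correct
  fn <- function(par) {
    lh <- lh_from_par(par[1], par[2])
    cc <- ((lh["H"] - lh["L"]) * conf + lh["L"] - 1) / 4
    mean((cc - correct)^2)   # minimized; score = 1 - this
  }
  ans <- multistart_optim(fn, c(LH_BOUNDS$L[1], LH_BOUNDS$v[1]),
                          c(LH_BOUNDS$L[2], LH_BOUNDS$v[2]),
                          n_restarts = n_starts, seed = 1L)
  lh <- lh_from_par(ans$par[1], ans$par[2])
  tibble::tibble(scaled_qsr = 1 - ans$value, L = lh[["L"]], H = lh[["H"]])
}

#' Confidence bias
#'
#' The mean reported confidence on the \[1, 5\] scale; an over/under-confidence
#' summary.
#' @param trials A trial tibble.
#' @return Mean confidence.
#' @export
confidence_bias <- function(trials) {
  if (nrow(trials) == 0) stop_input("`trials` is empty.")
  mean(trials$confidence)
}

#' Lag-1 autocorrelation of confidence ratings
#'
#' Pearson correlation between consecutive confidence reports. Constant
#' sequences have no defined correlation and return `NaN` with a warning.
#'
#' @param trials A trial tibble with at least 3 trials.
#' @return Correlation in \[-1, 1\], or `NaN` for constant input.
#' @export
conf_autocorr_lag1 <- function(trials) {
  conf <- trials$confidence
  n <- length(conf)
  if (n < 3) stop_input("at least 3 trials are required.")
  if (stats::sd(conf) == 0) {
    warn("confidence sequence is constant; autocorrelation is undefined.")
    return(NaN)
  }
  cor(conf[-n], conf[-1])
}

#' Chance-level exclusion filter
#'
#' Chi-square goodness-of-fit of observed correct/incorrect counts against
#' the 50/50 split expected under random guessing,
#' `chi2 = sum((O - E)^2 / E)` with `E = n_total / 2` per category. A
#' subject-condition is excluded when the statistic does not exceed the
#' critical value 3.841 (1 degree of freedom, p = .05) — i.e. performance
#' indistinguishable from chance — or when performance is at or below 0.5
#' (the test is two-sided but only above-chance performers are retained).
#'
#' @param n_correct,n_total Correct and total trial counts.
#' @return A one-row tibble with `chi2` and `excluded`.
#' @examples
#' exclusion_chi_square(300, 400)
#' @export
exclusion_chi_square <- function(n_correct, n_total) {
  if (n_total <= 0) stop_input("`n_total` must be positive.")
  if (n_correct < 0 || n_correct > n_total) {
    stop_input("`n_correct` must lie in [0, n_total].")
  }
  e <- n_total / 2
  chi2 <- (n_correct - e)^2 / e + ((n_total - n_correct) - e)^2 / e
  tibble::tibble(chi2 = chi2,
                 excluded = chi2 <= 3.841 | n_correct <= e)
}

#' Convenience wrappers for the standard group comparisons
#'
#' Thin delegations to the standard statistics routines so cohort summaries
#' can mirror the usual report layout: paired Wilcoxon signed-rank for two
#' groups, Pearson correlation for two variables, and Fisher's z for
#' comparing two correlations.
#'
#' @param a,b For `"wilcoxon"`/`"pearson"`: the two numeric samples. For
#'   `"fisher_z"`: `c(r, n)` pairs (correlation and its sample size).
#' @param kind Test to run.
#' @param paired Passed to [stats::wilcox.test()].
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(a, b, kind = c("wilcoxon", "pearson", "fisher_z"),
                           paired = TRUE) {
  kind <- match.arg(kind)
  if (kind == "wilcoxon") {
    ht <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
    tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                   method = "wilcoxon")
  } else if (kind == "pearson") {
    ht <- stats::cor.test(a, b, method = "pearson")
    tibble::tibble(statistic = unname(ht$estimate), p_value = ht$p.value,
                   method = "pearson")
  } else {
    stopifnot(length(a) == 2, length(b) == 2)
    z <- (atanh(a[1]) - atanh(b[1])) /
      sqrt(1 / (a[2] - 3) + 1 / (b[2] - 3))
    tibble::tibble(statistic = z, p_value = 2 * pnorm(-abs(z)),
                   method = "fisher_z")
  }
}

#' Full metacognition report for one subject-condition
#'
#' Combines the empirical summaries (performance, QSR, scaled-QSR,
#' confidence bias, lag-1 autocorrelation, exclusion filter) with the
#' simulated performances of supplied Forward and Backward fits and their
#' ratio.
#'
#' @param trials A trial tibble for one subject-condition.
#' @param forward,backward `metarl_fit` objects (optional; the model-based
#'   columns are `NA` when absent).
#' @param n_sims Simulations per performance estimate.
#' @param seed Integer seed for the performance simulations.
#' @return A one-row tibble of class `metarl_report`.
#' @export
metacog_report <- function(trials, forward = NULL, backward = NULL,
                           n_sims = 100, seed = 1L) {
  n <- nrow(trials)
  excl <- exclusion_chi_square(sum(trials$correct), n)
  perf_f <- if (!is.null(forward)) {
    model_performance(forward, n_sims = n_sims, seed = child_seed(seed, 1))
  } else NA_real_
  perf_b <- if (!is.null(backward)) {
    model_performance(backward, n_sims = n_sims, seed = child_seed(seed, 2))
  } else NA_real_
  out <- tibble::tibble(
    subject = trials$subject[1], condition = trials$condition[1],
    n_trials = n,
    perf_empirical = performance(trials),
    perf_forward = perf_f, perf_backward = perf_b,
    metarl_ratio = if (is.na(perf_f) || is.na(perf_b)) NA_real_
                   else metarl_ratio(perf_b, perf_f),
    qsr = qsr(trials),
    scaled_qsr = scaled_qsr(trials)$scaled_qsr,
    confidence_bias = confidence_bias(trials),
    conf_autocorr_lag1 = suppressWarnings(conf_autocorr_lag1(trials)),
    chi2 = excl$chi2, excluded = excl$excluded)
  class(out) <- c("metarl_report", class(out))
  out
}
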