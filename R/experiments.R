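# Validation experiment drivers: simulate a cohort, fit Forward and Backward
# models per agent, and summarize the metacognition measures. These are the
# harnesses behind the package's self-checks (first-order independence,
# parameter recovery, confidence-noise sensitivity, difficulty invariance).

# Fit both directions for one agent's table and estimate simulated
# performances and their ratio.
fit_and_score <- function(trials, settings, cfg = NULL, model = "mf",
                          seed = 1L) {
  cfg <- cfg %||% attr(trials, "task_config")
  fwd <- fit_forward(trials, model, settings, cfg = cfg)
  bwd <- fit_backward(trials, model, settings, cfg = cfg)
  perf_f <- model_performance(fwd, cfg = cfg, n_sims = settings$n_perf_sims,
                              seed = child_seed(seed, 1))
  perf_b <- model_performance(bwd, cfg = cfg, n_sims = settings$n_perf_sims,
                              seed = child_seed(seed, 2))
  list(forward = fwd, backward = bwd, perf_forward = perf_f,
       perf_backward = perf_b, ratio = metarl_ratio(perf_b, perf_f))
}

#' First-order independence sweep
#'
#' Simulates the 30-agent sweep cohorts of first-order model-free agents
#' (see [first_order_sweep_specs()]), fits Forward and Backward models to
#' each agent, and returns the per-agent simulated performances and
#' MetaRL.Ratio. Because these agents' confidence is a deterministic function
#' of the information driving their choices, the cohort-mean ratio should sit
#' at 1 regardless of the swept choice parameter.
#'
#' @param kind `"beta"` (learning rates {.2,.5,.9} x 10 inverse temperatures
#'   in \[5, 90\]) or `"alpha"` (inverse temperatures {5,15,40} x 10 learning
#'   rates in \[.05, 1\]).
#' @param cfg Task configuration (default: low-variance task).
#' @param settings [fit_settings()]; sweeps are usually run with reduced
#'   restarts.
#' @param seed Integer seed.
#' @return A tibble with one row per agent: the generating `alpha`/`beta`,
#'   empirical performance, Forward/Backward simulated performance, and
#'   `ratio`.
#' @export
run_first_order_sweep <- function(kind = c("beta", "alpha"),
                                  cfg = task_config(),
                                  settings = fit_settings(n_restarts = 20),
                                  seed = 1L) {
  kind <- match.arg(kind)
  specs <- first_order_sweep_specs(kind)
  cohort <- generate_cohort(specs, cfg, seed = seed)
  tabs <- split(cohort$trials, cohort$trials$subject)
  purrr::imap_dfr(tabs, function(tt, id) {
    attr(tt, "task_config") <- cfg
    truth <- cohort$truth[cohort$truth$subject == id, ]
    sc <- fit_and_score(tt, settings, cfg = cfg,
                        seed = child_seed(seed, 500 + match(id, names(tabs))))
    tibble::tibble(subject = id, alpha = truth$alpha, beta = truth$beta,
                   perf_empirical = performance(tt),
                   perf_forward = sc$perf_forward,
                   perf_backward = sc$perf_backward, ratio = sc$ratio)
  })
}

#' Parameter-recovery experiment
#'
#' Simulates first-order agents with parameters drawn uniformly within the
#' fitting bounds (learning rate in \[0, 1\], inverse temperature in
#' \[0, 100\], reporting bounds drawn in \[1, 5\] and ordered), fits the
#' Backward (and optionally Forward) model to each, and returns generating
#' and recovered parameters side by side.
#'
#' @param n_agents Number of simulated agents.
#' @param cfg Task configuration.
#' @param settings [fit_settings()].
#' @param seed Integer seed.
#' @param directions Which fits to run (`"backward"`, `"forward"`, or both).
#' @return A tibble with one row per agent and direction: true and recovered
#'   `alpha`, `beta`, `L`, `H`.
#' @export
run_recovery <- function(n_agents = 30, cfg = task_config(),
                         settings = fit_settings(n_restarts = 20),
                         seed = 1L, directions = "backward") {
  specs <- with_seed(seed, purrr::map(seq_len(n_agents), function(i) {
    lh <- sort(runif(2, 1, 5))
    agent_spec("mf", list(alpha = runif(1, 0, 1), beta = runif(1, 0, 100)),
               conf_bounds = lh)
  }))
  cohort <- generate_cohort(specs, cfg, seed = child_seed(seed, 77))
  tabs <- split(cohort$trials, cohort$trials$subject)
  purrr::imap_dfr(tabs, function(tt, id) {
    attr(tt, "task_config") <- cfg
    truth <- cohort$truth[cohort$truth$subject == id, ]
    purrr::map_dfr(directions, function(dir) {
      fit <- if (dir == "backward") {
        fit_backward(tt, "mf", settings, cfg = cfg)
      } else {
        fit_forward(tt, "mf", settings, cfg = cfg)
      }
      tibble::tibble(subject = id, direction = dir,
                     alpha_true = truth$alpha, beta_true = truth$beta,
                     L_true = truth$L, H_true = truth$H,
                     alpha_hat = fit$params$alpha, beta_hat = fit$params$beta,
                     L_hat = fit$params$L, H_hat = fit$params$H,
                     objective = fit$objective)
    })
  })
}

#' Confidence-noise ladder experiment
#'
#' Simulates model-free agents, replaces their confidence reports with
#' perfectly diagnostic binary confidence corrupted by Gaussian noise at each
#' level of `sigmas` ([hmeta_confidences()]), and fits Forward and Backward
#' models at every noise level. Choices are identical across levels, so
#' Forward performance stays flat while Backward performance should fall as
#' noise rises.
#'
#' @param n_agents Number of agents (>= 20 recommended).
#' @param sigmas Noise standard-deviation ladder.
#' @param cfg Task configuration.
#' @param settings [fit_settings()].
#' @param seed Integer seed.
#' @return A tibble with one row per agent x noise level: `sigma`,
#'   `perf_forward`, `perf_backward`.
#' @export
run_noise_ladder <- function(n_agents = 20, sigmas = c(0, 1, 2, 4),
                             cfg = task_config(),
                             settings = fit_settings(n_restarts = 20),
                             seed = 1L) {
  specs <- with_seed(seed, purrr::map(seq_len(n_agents), function(i) {
    agent_spec("mf", list(alpha = runif(1, 0.5, 1), beta = runif(1, 5, 40)))
  }))
  cohort <- generate_cohort(specs, cfg, seed = child_seed(seed, 33))
  tabs <- split(cohort$trials, cohort$trials$subject)
  purrr::imap_dfr(tabs, function(tt, id) {
    attr(tt, "task_config") <- cfg
    i <- match(id, names(tabs))
    fwd <- fit_forward(tt, "mf", settings, cfg = cfg)
    perf_f <- model_performance(fwd, cfg = cfg,
                                n_sims = settings$n_perf_sims,
                                seed = child_seed(seed, 200 + i))
    purrr::map_dfr(seq_along(sigmas), function(k) {
      noisy <- hmeta_confidences(tt, sigma = sigmas[k],
                                 seed = child_seed(seed, 1000 * k + i))
      attr(noisy, "task_config") <- cfg
      bwd <- fit_backward(noisy, "mf", settings, cfg = cfg)
      perf_b <- model_performance(bwd, cfg = cfg,
                                  n_sims = settings$n_perf_sims,
                                  seed = child_seed(seed, 5000 * k + i))
      tibble::tibble(subject = id, sigma = sigmas[k],
                     perf_forward = perf_f, perf_backward = perf_b,
                     alpha_backward = bwd$params$alpha,
                     beta_backward = bwd$params$beta)
    })
  })
}

#' Task-difficulty invariance experiment
#'
#' Runs the same population of first-order model-free agents in the
#' low-variance (reward scale 8) and high-variance (scale 16) conditions,
#' fits Forward and Backward models in each, and returns the per-agent
#' performances and MetaRL.Ratio per condition. Performance measures should
#' drop with difficulty while the ratio stays put.
#'
#' @param n_agents Number of agents (>= 30 recommended).
#' @param settings [fit_settings()].
#' @param seed Integer seed.
#' @return A tibble with one row per agent x condition.
#' @export
run_difficulty_invariance <- function(n_agents = 30,
                                      settings = fit_settings(n_restarts = 20),
                                      seed = 1L) {
  pars <- with_seed(seed, purrr::map(seq_len(n_agents), function(i) {
    list(alpha = runif(1, 0.2, 1), beta = runif(1, 5, 40))
  }))
  purrr::map_dfr(c("low_variance", "high_variance"), function(cond) {
    cfg <- task_config(cond)
    specs <- purrr::map(pars, \(p) agent_spec("mf", p))
    cohort <- generate_cohort(specs, cfg,
                              seed = child_seed(seed, if (cond == "low_variance") 1 else 2))
    tabs <- split(cohort$trials, cohort$trials$subject)
    purrr::imap_dfr(tabs, function(tt, id) {
      attr(tt, "task_config") <- cfg
      i <- match(id, names(tabs))
      sc <- fit_and_score(tt, settings, cfg = cfg,
                          seed = child_seed(seed, 300 + i))
      tibble::tibble(subject = id, condition = cond,
                     alpha = pars[[i]]$alpha, beta = pars[[i]]$beta,
                     perf_empirical = performance(tt),
                     perf_forward = sc$perf_forward,
                     perf_backward = sc$perf_backward, ratio = sc$ratio)
    })
  })
}
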