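#' Define a synthetic agent
#'
#' An agent couples a choice model with a rule for reporting confidence. The
#' default (`confidence_mode = "model_scaled"`) is a first-order agent: its
#' confidence is its own chosen-option probability mapped onto the rating
#' scale with bounds `conf_bounds` (optionally leak-integrated with weight
#' `lambda`). `"hmeta"` agents instead report perfectly diagnostic binary
#' confidence — highest when correct, lowest when incorrect — corrupted by
#' truncated, quantized Gaussian noise of scale `noise_sigma`
#' (see [hmeta_confidences()]).
#'
#' @param model `"mf"`, `"mf4"`, `"hsmm"`, `"mixture"`, `"random"`, or
#'   `"omniscient"`.
#' @param params Named list of model parameters (see [replay_pchoice()]).
#' @param conf_bounds Length-2 reporting bounds `c(L, H)`.
#' @param confidence_mode `"model_scaled"` or `"hmeta"`.
#' @param noise_sigma Confidence-noise scale (rating units) for hmeta agents.
#' @param lambda Optional leak weight for the agent's own reports.
#' @param q0 Initial option value for Q-learning models.
#' @param reward_scale Reward units per softmax unit (see
#'   [replay_pchoice()]).
#' @return A `metarl_agent` object.
#' @export
agent_spec <- function(model, params = list(), conf_bounds = c(1, 5),
                       confidence_mode = c("model_scaled", "hmeta"),
                       noise_sigma = 0, lambda = NULL, q0 = 50,
                       reward_scale = 100) {
  confidence_mode <- match.arg(confidence_mode)
  stopifnot(noise_sigma >= 0, length(conf_bounds) == 2,
            conf_bounds[1] < conf_bounds[2])
  structure(list(model = model, params = params, conf_bounds = conf_bounds,
                 confidence_mode = confidence_mode,
                 noise_sigma = noise_sigma, lambda = lambda, q0 = q0,
                 reward_scale = reward_scale),
            class = "metarl_agent")
}

#' @rdname agent_spec
#' @export
agent_random <- function() agent_spec("random")

#' @rdname agent_spec
#' @export
agent_omniscient <- function() agent_spec("omniscient")

#' Simulate a cohort of agents
#'
#' Runs each agent on its own realization of the task and stacks the trial
#' tables (subjects `agent01`, `agent02`, ...). Ground-truth parameters are
#' returned alongside so recovery experiments can join on `subject`.
#'
#' @param specs A list of [agent_spec()] objects.
#' @param cfg A [task_config()].
#' @param seed Integer seed; agent i runs under a deterministic child seed.
#' @return A list with `trials` (stacked tibble) and `truth` (one row per
#'   agent with the generating parameters).
#' @export
generate_cohort <- function(specs, cfg, seed = 1L) {
  ids <- sprintf("agent%02d", seq_along(specs))
  tabs <- purrr::imap(specs, function(sp, i) {
    tt <- run_episode(sp, cfg, seed = child_seed(seed, i), subject = ids[i])
    if (sp$confidence_mode == "hmeta") {
      tt <- hmeta_confidences(tt, sigma = sp$noise_sigma,
                              seed = child_seed(seed, 100000 + i))
    }
    tt
  })
  truth <- purrr::imap_dfr(specs, function(sp, i) {
    tibble::tibble(subject = ids[i], model = sp$model,
                   !!!sp$params, L = sp$conf_bounds[1],
                   H = sp$conf_bounds[2],
                   confidence_mode = sp$confidence_mode,
                   noise_sigma = sp$noise_sigma)
  })
  trials <- dplyr::bind_rows(tabs)
  attr(trials, "task_config") <- cfg
  list(trials = trials, truth = truth)
}

#' Replace confidences with noisy perfectly-diagnostic reports
#'
#' Builds the Hmeta(sigma^2) confidence pattern: the highest rating (5) on
#' correct trials and the lowest (1) on incorrect trials, corrupted by
#' Gaussian noise with standard deviation `sigma`, truncated to \[1, 5\] and
#' quantized to a 0.01 grid (continuous-slider granularity). With
#' `sigma = 0` the reports are exactly binary and perfectly separate correct
#' from incorrect trials.
#'
#' @param trials A trial tibble.
#' @param sigma Noise standard deviation in rating units (`>= 0`).
#' @param seed Integer seed.
#' @param quantum Quantization step; `0` disables quantization.
#' @return The trial tibble with `confidence` replaced.
#' @export
hmeta_confidences <- function(trials, sigma, seed = NULL, quantum = 0.01) {
  stopifnot(sigma >= 0)
  base <- ifelse(trials$correct == 1L, 5, 1)
  conf <- with_seed(seed, base + rnorm(nrow(trials), sd = sigma))
  conf <- pmin(pmax(conf, 1), 5)
  if (quantum > 0) conf <- round(conf / quantum) * quantum
  trials$confidence <- conf
  trials
}

#' Agent grids for the first-order independence sweeps
#'
#' Builds the 30-agent populations used to check that metacognitive
#' efficiency is independent of the choice parameters: the `"beta"` sweep
#' crosses learning rates {.2, .5, .9} with 10 equidistant inverse
#' temperatures spanning \[5, 90\] (endpoints included); the `"alpha"` sweep
#' crosses inverse temperatures {5, 15, 40} with 10 equidistant learning
#' rates spanning \[.05, 1\]. All agents are first-order: confidence is their
#' scaled chosen-option probability (full-scale bounds 1 and 5).
#'
#' @param kind Which parameter is swept over 10 points.
#' @return A list of [agent_spec()] objects (length 30).
#' @export
first_order_sweep_specs <- function(kind = c("beta", "alpha")) {
  kind <- match.arg(kind)
  grid <- if (kind == "beta") {
    expand.grid(alpha = c(0.2, 0.5, 0.9),
                beta = seq(5, 90, length.out = 10))
  } else {
    expand.grid(alpha = seq(0.05, 1, length.out = 10),
                beta = c(5, 15, 40))
  }
  purrr::pmap(grid, function(alpha, beta) {
    agent_spec("mf", list(alpha = alpha, beta = beta))
  })
}
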