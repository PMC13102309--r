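#' Configure the two-armed reversal bandit task
#'
#' The task presents two options whose rewards are drawn from Gaussian
#' distributions with means `mean_low` and `mean_high`; which option carries
#' the high mean reverses, unsignalled, every `block_len_min` to
#' `block_len_max` trials. A session runs for `n_trials` trials. The
#' `condition` label selects the reward noise: the low-variance condition uses
#' a Gaussian scale of 8 reward units and the high-variance condition a scale
#' of 16. The condition value is treated as the standard deviation of the
#' reward distribution throughout (some descriptions of such designs call 8
#' and 16 "variances"; here they parameterize the Gaussian scale).
#'
#' @param condition `"low_variance"` or `"high_variance"`; sets the default
#'   `reward_sd` (8 or 16).
#' @param mean_low,mean_high Mean reward of the worse / better option.
#' @param reward_sd Gaussian scale of the reward noise, in reward units.
#'   Defaults from `condition`.
#' @param block_len_min,block_len_max Bounds (inclusive) of the uniformly
#'   drawn block length, in trials.
#' @param n_blocks Nominal number of blocks (used for validation only; blocks
#'   are drawn until `n_trials` is reached and the last block is truncated).
#' @param n_trials Total number of trials in a session.
#' @return A `task_config` object (a named list).
#' @examples
#' cfg <- task_config()
#' cfg_hv <- task_config("high_variance")
#' @export
task_config <- function(condition = c("low_variance", "high_variance"),
                        mean_low = 40, mean_high = 60, reward_sd = NULL,
                        block_len_min = 18, block_len_max = 22,
                        n_blocks = 20, n_trials = 400) {
  condition <- match.arg(condition)
  if (is.null(reward_sd)) {
    reward_sd <- if (condition == "low_variance") 8 else 16
  }
  cfg <- structure(
    list(condition = condition, mean_low = mean_low, mean_high = mean_high,
         reward_sd = reward_sd, block_len_min = as.integer(block_len_min),
         block_len_max = as.integer(block_len_max),
         n_blocks = as.integer(n_blocks), n_trials = as.integer(n_trials)),
    class = "task_config")
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  if (cfg$mean_low >= cfg$mean_high) {
    stop_input("`mean_low` (%s) must be below `mean_high` (%s).",
               cfg$mean_low, cfg$mean_high)
  }
  if (cfg$reward_sd <= 0) stop_input("`reward_sd` must be positive.")
  if (cfg$block_len_min > cfg$block_len_max || cfg$block_len_min < 1) {
    stop_input("block length bounds must satisfy 1 <= min <= max.")
  }
  if (cfg$n_trials < 1) stop_input("`n_trials` must be at least 1.")
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> %s: rewards N(%g, %g^2) / N(%g, %g^2), reversals every %d-%d trials, %d trials\n",
    x$condition, x$mean_high, x$reward_sd, x$mean_low, x$reward_sd,
    x$block_len_min, x$block_len_max, x$n_trials))
  invisible(x)
}

#' Draw a reversal schedule
#'
#' Draws block lengths uniformly on `block_len_min:block_len_max` until the
#' session length is reached (the final block is truncated so that the total
#' is exactly `n_trials`), assigns the first block's better option uniformly
#' at random, and alternates the better option at every block boundary.
#'
#' @param cfg A [task_config()].
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A tibble with one row per trial: `trial`, `block`, `better_option`,
#'   plus a `block_lengths` attribute holding the drawn lengths.
#' @examples
#' sched <- draw_reversal_schedule(task_config(), seed = 1)
#' table(attr(sched, "block_lengths"))
#' @export
draw_reversal_schedule <- function(cfg, seed = NULL) {
  validate_task_config(cfg)
  with_seed(seed, {
    lens <- integer(0)
    total <- 0L
    while (total < cfg$n_trials) {
      lens_range <- cfg$block_len_min:cfg$block_len_max
      l <- lens_range[sample.int(length(lens_range), 1L)]
      if (total + l > cfg$n_trials) l <- cfg$n_trials - total
      lens <- c(lens, l)
      total <- total + l
    }
    first <- sample(1:2, 1L)
    block <- rep(seq_along(lens), lens)
    better <- rep(ifelse(seq_along(lens) %% 2L == 1L, first, 3L - first), lens)
    out <- tibble::tibble(trial = seq_len(cfg$n_trials), block = block,
                          better_option = as.integer(better))
    attr(out, "block_lengths") <- lens
    out
  })
}

#' Draw rewards for chosen actions
#'
#' Rewards are Gaussian with mean `mean_high` when the chosen action is the
#' currently better option and `mean_low` otherwise; the scale is the
#' condition's `reward_sd`.
#'
#' @param cfg A [task_config()].
#' @param action,better_option Integer vectors of option ids (1 or 2),
#'   recycled to a common length.
#' @param seed Optional integer seed.
#' @return Numeric vector of rewards.
#' @export
draw_reward <- function(cfg, action, better_option, seed = NULL) {
  check_option_id(action, "action")
  check_option_id(better_option, "better_option")
  n <- max(length(action), length(better_option))
  mu <- ifelse(rep_len(action, n) == rep_len(better_option, n),
               cfg$mean_high, cfg$mean_low)
  with_seed(seed, rnorm(n, mean = mu, sd = cfg$reward_sd))
}

#' Run one episode of an agent on the task
#'
#' Simulates a full session: on each trial the agent emits choice
#' probabilities from its current state, an action is sampled, a reward is
#' drawn from the task, and the agent's state is updated, in that order.
#' Model-free agents run through a compiled fast path; other agents use their
#' policy callbacks.
#'
#' @param agent An agent created by [agent_spec()] or one of
#'   [agent_random()], [agent_omniscient()].
#' @param cfg A [task_config()].
#' @param seed Integer seed controlling schedule, rewards and choices.
#' @param schedule Optional precomputed schedule from
#'   [draw_reversal_schedule()]; when supplied only choices/rewards are drawn.
#' @param subject,condition Identifiers stamped on the output rows.
#' @return A trial tibble with columns `subject`, `condition`, `trial`,
#'   `block`, `better_option`, `action`, `reward`, `confidence`, `correct`,
#'   with the `task_config` stored in the `"task_config"` attribute.
#' @examples
#' ag <- agent_spec("mf", list(alpha = 0.9, beta = 15))
#' tt <- run_episode(ag, task_config(), seed = 42)
#' mean(tt$correct)
#' @export
run_episode <- function(agent, cfg, seed = NULL, schedule = NULL,
                        subject = "sim1", condition = cfg$condition) {
  validate_task_config(cfg)
  if (!inherits(agent, "metarl_agent")) {
    stop_input("`agent` must be a metarl agent (see `agent_spec()`).")
  }
  with_seed(seed, {
    if (is.null(schedule)) schedule <- draw_reversal_schedule(cfg, seed = NULL)
    better <- schedule$better_option
    n <- length(better)
    sim <- simulate_choices(agent, better, cfg)
    conf <- agent_confidence(agent, sim$p_chosen)
    out <- tibble::tibble(
      subject = subject, condition = condition,
      trial = seq_len(n), block = schedule$block,
      better_option = as.integer(better), action = as.integer(sim$action),
      reward = sim$reward, confidence = conf,
      correct = as.integer(sim$action == better))
    attr(out, "task_config") <- cfg
    out
  })
}

# Dispatch autonomous choice simulation by agent model. Runs inside an
# established RNG context.
simulate_choices <- function(agent, better, cfg) {
  model <- agent$model
  p <- agent$params
  if (model %in% c("mf", "mf4")) {
    pars <- mf_par4(model, p)
    mf_episode_cpp(as.integer(better), pars[["alpha_pos"]], pars[["alpha_neg"]],
                   pars[["alpha_unchosen"]],
                   pars[["beta"]] / agent$reward_scale, agent$q0,
                   cfg$mean_high, cfg$mean_low, cfg$reward_sd)
  } else if (model == "random") {
    n <- length(better)
    action <- sample(1:2, n, replace = TRUE)
    list(action = action,
         reward = draw_reward(cfg, action, better),
         p_chosen = rep(0.5, n))
  } else if (model == "omniscient") {
    list(action = better,
         reward = draw_reward(cfg, better, better),
         p_chosen = rep(1, length(better)))
  } else if (model %in% c("hsmm", "mixture")) {
    simulate_mb_choices(agent, better, cfg)
  } else {
    stop_input("unknown agent model '%s'.", model)
  }
}

# Confidence a generating agent reports: its chosen-option probability mapped
# onto the rating scale, optionally with leaky integration of its own
# previous report.
agent_confidence <- function(agent, p_chosen) {
  b <- agent$conf_bounds
  conf <- scale_confidence(p_chosen, L = b[1], H = b[2])
  if (!is.null(agent$lambda) && agent$lambda < 1) {
    conf <- Reduce(function(prev, cur) agent$lambda * cur +
                     (1 - agent$lambda) * prev,
                   conf, accumulate = TRUE)
  }
  conf
}

#' Performance of a trial table
#'
#' Fraction of trials on which the better option was chosen.
#' @param trials A trial tibble.
#' @return A single number in \[0, 1\].
#' @export
performance <- function(trials) {
  mean(trials$action == trials$better_option)
}
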