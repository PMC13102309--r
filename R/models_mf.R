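#' Model-free Q-learning updates and softmax policy
#'
#' The two-parameter learner updates the chosen option's value toward the
#' received reward by a fraction `alpha` (learning rate) and chooses via a
#' softmax with inverse temperature `beta`. The refined four-parameter learner
#' splits the learning rate by the sign of the prediction error
#' (`alpha_pos` for non-negative, `alpha_neg` for negative) and additionally
#' updates the unchosen option with the same prediction error scaled by a
#' counterfactual rate `alpha_unchosen` (typically negative, since the options
#' are anticorrelated in this task).
#'
#' @param q Numeric length-2 vector of option values.
#' @param action Chosen option id (1 or 2).
#' @param reward Observed reward.
#' @param alpha Learning rate in \[0, 1\].
#' @return `q_update()`/`q_update_refined()`: the updated length-2 value
#'   vector. `softmax_policy()`: length-2 probability vector.
#' @examples
#' q_update(c(50, 50), action = 1, reward = 60, alpha = 0.5)
#' softmax_policy(c(60, 40), beta = 0.5)
#' @export
q_update <- function(q, action, reward, alpha) {
  q_update_refined(q, action, reward, alpha_pos = alpha, alpha_neg = alpha,
                   alpha_unchosen = 0)
}

#' @rdname q_update
#' @param alpha_pos,alpha_neg Learning rates applied when the prediction error
#'   is `>= 0` / `< 0`, both in \[0, 1\].
#' @param alpha_unchosen Counterfactual learning rate for the unchosen option,
#'   in \[-1, 1\].
#' @export
q_update_refined <- function(q, action, reward, alpha_pos, alpha_neg,
                             alpha_unchosen = 0) {
  stopifnot(length(q) == 2, is.finite(q))
  check_option_id(action, "action")
  delta <- reward - q[action]
  al <- if (delta >= 0) alpha_pos else alpha_neg
  q[action] <- q[action] + al * delta
  q[3 - action] <- q[3 - action] + alpha_unchosen * delta
  q
}

#' @rdname q_update
#' @param beta Inverse temperature, `>= 0`. Computed with max-subtraction so
#'   large `beta * q` does not overflow.
#' @export
softmax_policy <- function(q, beta) {
  stopifnot(length(q) == 2, beta >= 0)
  x <- beta * q
  e <- exp(x - max(x))
  e / sum(e)
}

# Canonical four-parameter view of mf / mf4 parameter lists; the simple model
# is the refined model with equal rates and no counterfactual term.
mf_par4 <- function(model, params) {
  if (model == "mf") {
    c(alpha_pos = params$alpha, alpha_neg = params$alpha,
      alpha_unchosen = 0, beta = params$beta)
  } else {
    c(alpha_pos = params$alpha_pos, alpha_neg = params$alpha_neg,
      alpha_unchosen = params$alpha_unchosen, beta = params$beta)
  }
}

#' Replay a model over observed choices and rewards
#'
#' Computes the predictive probability the model assigns to each option on
#' every trial, updating the model with the *observed* action and reward after
#' each trial (the sequential replay used for fitting). The probability at
#' trial t depends only on history up to t - 1.
#'
#' @param trials A trial tibble (needs `action` and `reward`).
#' @param model One of `"mf"`, `"mf4"`, `"hsmm"`, `"mixture"`.
#' @param params Named list of model parameters: `mf` needs `alpha`, `beta`;
#'   `mf4` needs `alpha_pos`, `alpha_neg`, `alpha_unchosen`, `beta`; `hsmm`
#'   needs `n`, `p` (and optionally `D`); `mixture` needs the `mf` and `hsmm`
#'   parameters plus the model-free weight `gamma`.
#' @param cfg Task configuration (required for `hsmm`/`mixture` emissions;
#'   taken from the table's attribute when absent).
#' @param q0 Initial option value (default 50, the midpoint of the two reward
#'   means).
#' @param reward_scale Reward units per softmax unit: the inverse temperature
#'   is expressed per `reward_scale` reward units (default 100, the task's
#'   nominal reward range), so `beta` in \[0, 100\] spans fully stochastic
#'   to near-deterministic choice.
#' @return A tibble with per-trial `p1` (probability of option 1) and
#'   `p_chosen` (probability of the observed action).
#' @export
replay_pchoice <- function(trials, model = c("mf", "mf4", "hsmm", "mixture"),
                           params, cfg = NULL, q0 = 50, reward_scale = 100) {
  model <- match.arg(model)
  if (nrow(trials) == 0) stop_input("`trials` is empty.")
  check_option_id(trials$action, "action")
  if (model %in% c("mf", "mf4")) {
    pars <- mf_par4(model, params)
    out <- mf_replay_cpp(as.integer(trials$action), as.double(trials$reward),
                         pars[["alpha_pos"]], pars[["alpha_neg"]],
                         pars[["alpha_unchosen"]],
                         pars[["beta"]] / reward_scale, q0)
    tibble::tibble(p1 = out$p1, p_chosen = out$p_chosen)
  } else {
    cfg <- cfg %||% attr(trials, "task_config") %||%
      stop_input("`cfg` is required for model '%s'.", model)
    hp <- hsmm_params(n = params$n, p = params$p,
                      D = params$D %||% 70, cfg = cfg)
    post <- hsmm_filter(trials$action, trials$reward, hp)
    p1 <- post$p_state1
    if (model == "mixture") {
      mf <- mf_par4("mf", params)
      pmf <- mf_replay_cpp(as.integer(trials$action),
                           as.double(trials$reward),
                           mf[["alpha_pos"]], mf[["alpha_neg"]],
                           mf[["alpha_unchosen"]],
                           mf[["beta"]] / reward_scale, q0)
      p1 <- params$gamma * pmf$p1 + (1 - params$gamma) * p1
    }
    tibble::tibble(p1 = p1,
                   p_chosen = ifelse(trials$action == 1L, p1, 1 - p1))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default box constraints for fitted parameters.
param_bounds <- function() {
  list(alpha = c(0, 1), beta = c(0, 100),
       alpha_pos = c(0, 1), alpha_neg = c(0, 1), alpha_unchosen = c(-1, 1),
       gamma = c(0, 1), lambda = c(0, 1), L = c(1, 5), H = c(1, 5))
}
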