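#' Hidden semi-Markov model-based learner
#'
#' The model-based learner infers which option is currently better by
#' filtering over a two-state hidden semi-Markov model: latent state i means
#' "option i is better", states alternate strictly (mirroring the task's
#' deterministic reversals), state durations follow a truncated negative
#' binomial distribution on 1..D, and rewards are emitted from a Gaussian
#' with mean 60 when the chosen action matches the state and 40 otherwise,
#' with the task condition's scale.
#'
#' @param n Negative-binomial shape (number of "tails"); `n = 1` gives a
#'   geometric duration distribution.
#' @param p Negative-binomial tail probability, in (0, 1).
#' @param D Maximum state duration in trials (default 70).
#' @param cfg Task configuration supplying the emission means and scale.
#' @param mu_high,mu_low,sigma_c Emission parameters; default from `cfg`.
#' @return `hsmm_params()` returns a parameter object including the implied
#'   mean reversal time `t_bar_rev` of the truncated duration distribution.
#' @export
hsmm_params <- function(n, p, D = 70, cfg = NULL,
                        mu_high = NULL, mu_low = NULL, sigma_c = NULL) {
  if (p <= 0 || p >= 1) stop_input("`p` must lie strictly in (0, 1).")
  if (n < 1) stop_input("`n` must be at least 1.")
  if (D < 1) stop_input("`D` must be at least 1.")
  mu_high <- mu_high %||% (if (!is.null(cfg)) cfg$mean_high else 60)
  mu_low <- mu_low %||% (if (!is.null(cfg)) cfg$mean_low else 40)
  sigma_c <- sigma_c %||% (if (!is.null(cfg)) cfg$reward_sd else 8)
  dur <- duration_pmf(n, p, D)
  structure(list(n = n, p = p, D = as.integer(D), mu_high = mu_high,
                 mu_low = mu_low, sigma_c = sigma_c, dur_pmf = dur$pmf,
                 t_bar_rev = dur$t_bar_rev),
            class = "hsmm_params")
}

#' Truncated negative-binomial duration distribution
#'
#' Probability mass over durations `1..D` proportional to
#' `choose(d + n - 1, d) * p^n * (1 - p)^d`, renormalized over the support.
#' Its mean is the model's expected reversal time.
#'
#' @inheritParams hsmm_params
#' @return A list with `d` (support), `pmf`, and the mean `t_bar_rev`.
#' @examples
#' duration_pmf(n = 1, p = 0.3, D = 70)$t_bar_rev
#' @export
duration_pmf <- function(n, p, D = 70) {
  if (p <= 0 || p >= 1) stop_input("`p` must lie strictly in (0, 1).")
  if (n < 1 || D < 1) stop_input("`n` and `D` must be at least 1.")
  d <- seq_len(D)
  lw <- lchoose(d + n - 1, d) + n * log(p) + d * log1p(-p)
  w <- exp(lw - max(lw))
  pmf <- w / sum(w)
  list(d = d, pmf = pmf, t_bar_rev = sum(d * pmf))
}

#' Gaussian emission log-likelihood of a reward segment
#'
#' Sum of per-trial Gaussian log-densities of rewards under a fixed latent
#' state: mean `mu_high` when the action matches the state, `mu_low`
#' otherwise. An empty segment has log-likelihood 0.
#'
#' @param rewards,actions Equal-length vectors for the segment.
#' @param state Latent state (1 or 2).
#' @param params An [hsmm_params()] object.
#' @return A single log-probability.
#' @export
emission_loglik <- function(rewards, state, actions, params) {
  if (length(rewards) != length(actions)) {
    stop_input("`rewards` and `actions` must have the same length.")
  }
  if (length(rewards) == 0) return(0)
  mu <- ifelse(actions == state, params$mu_high, params$mu_low)
  sum(dnorm(rewards, mean = mu, sd = params$sigma_c, log = TRUE))
}

# Per-trial emission log-lik under each state, as an n x 2 matrix.
emission_ll_matrix <- function(actions, rewards, params) {
  cbind(dnorm(rewards, ifelse(actions == 1L, params$mu_high, params$mu_low),
              params$sigma_c, log = TRUE),
        dnorm(rewards, ifelse(actions == 2L, params$mu_high, params$mu_low),
              params$sigma_c, log = TRUE))
}

# Tail weights W(h) = sum_{d >= h} pmf(d) / d, for the uniform elapsed-time
# prior P(h | d) = 1/d on h <= d.
hsmm_tail_weights <- function(params) {
  rev(cumsum(rev(params$dur_pmf / seq_len(params$D))))
}

#' Filter the HSMM over an observed action/reward sequence
#'
#' Runs the explicit-duration forward recursion in the log domain and returns,
#' for every trial t, the predictive state posterior
#' P(S_t | rewards and actions up to t - 1). The recursion is seeded with a
#' virtual segment boundary at t = 0 and a uniform prior over the first
#' state, so the posterior at t = 1 is (0.5, 0.5).
#'
#' @param actions,rewards Observed sequences.
#' @param params An [hsmm_params()] object.
#' @return A tibble with `trial`, `p_state1`, `p_state2`.
#' @export
hsmm_filter <- function(actions, rewards, params) {
  st <- hsmm_init(params)
  n <- length(actions)
  post <- matrix(NA_real_, n, 2)
  for (t in seq_len(n)) {
    post[t, ] <- hsmm_predict(st)
    st <- hsmm_observe(st, actions[t], rewards[t])
  }
  tibble::tibble(trial = seq_len(n), p_state1 = post[, 1],
                 p_state2 = post[, 2])
}

# Incremental filtering state: log forward variables la[t + 1, j] =
# log P(state j's segment ended exactly at t, r_{1:t}), with la[1, ] the
# virtual boundary at t = 0; cum[t + 1, i] = cumulative emission log-lik of
# trials 1..t under state i.
hsmm_init <- function(params, capacity = 512L) {
  list(params = params, t = 0L,
       la = rbind(c(log(0.5), log(0.5)),
                  matrix(NA_real_, capacity, 2)),
       cum = rbind(c(0, 0), matrix(NA_real_, capacity, 2)),
       logdur = log(params$dur_pmf),
       logw = log(hsmm_tail_weights(params)))
}

# Predictive posterior P(S_{t+1} = i | history through t), before observing
# trial t + 1. Marginalizes the elapsed time h of the ongoing segment:
# sum_h alpha(t + 1 - h, other(i)) * B_i(t + 2 - h .. t) * W(h).
hsmm_predict <- function(st) {
  p <- st$params
  tcur <- st$t + 1L           # trial being predicted
  hmax <- min(tcur, p$D)
  h <- seq_len(hmax)
  num <- vapply(1:2, function(i) {
    j <- 3L - i
    # segment of state i began at tcur - h + 1; emissions cover up to tcur - 1
    logsumexp(st$la[tcur - h + 1L, j] +
                (st$cum[tcur, i] - st$cum[tcur - h + 1L, i]) +
                st$logw[h])
  }, numeric(1))
  e <- exp(num - logsumexp(num))
  e / sum(e)
}

# Advance the filter with the observed trial.
hsmm_observe <- function(st, action, reward) {
  p <- st$params
  t <- st$t + 1L
  if (t + 1L > nrow(st$la)) {
    st$la <- rbind(st$la, matrix(NA_real_, nrow(st$la), 2))
    st$cum <- rbind(st$cum, matrix(NA_real_, nrow(st$cum), 2))
  }
  ll <- c(dnorm(reward, if (action == 1L) p$mu_high else p$mu_low,
                p$sigma_c, log = TRUE),
          dnorm(reward, if (action == 2L) p$mu_high else p$mu_low,
                p$sigma_c, log = TRUE))
  st$cum[t + 1L, ] <- st$cum[t, ] + ll
  dmax <- min(t, p$D)
  d <- seq_len(dmax)
  st$la[t + 1L, ] <- vapply(1:2, function(j) {
    i <- 3L - j
    logsumexp(st$logdur[d] + st$la[t - d + 1L, i] +
                (st$cum[t + 1L, j] - st$cum[t - d + 1L, j]))
  }, numeric(1))
  st$t <- t
  st
}

#' Model-based and mixture choice policies
#'
#' The model-based policy chooses option i with the predictive probability
#' that the latent state favouring option i is active. The mixture policy is
#' a convex combination of model-free (softmax) and model-based
#' probabilities with model-free weight `gamma`.
#'
#' @param posterior Length-2 normalized state posterior.
#' @return Length-2 choice probability vector.
#' @export
mb_policy <- function(posterior) {
  stopifnot(length(posterior) == 2)
  if (abs(sum(posterior) - 1) > 1e-8) {
    stop_input("`posterior` must be normalized.")
  }
  posterior
}

#' @rdname mb_policy
#' @param mf_probs,mb_probs Length-2 normalized choice probabilities.
#' @param gamma Model-free weight in \[0, 1\].
#' @export
mixture_policy <- function(mf_probs, mb_probs, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  gamma * mf_probs + (1 - gamma) * mb_probs
}

# Autonomous simulation of hsmm / mixture agents. Runs inside an established
# RNG context (see run_episode()).
simulate_mb_choices <- function(agent, better, cfg) {
  pars <- agent$params
  hp <- hsmm_params(n = pars$n, p = pars$p, D = pars$D %||% 70, cfg = cfg)
  st <- hsmm_init(hp, capacity = length(better) + 2L)
  mixture <- agent$model == "mixture"
  if (mixture) q <- c(agent$q0, agent$q0)
  n <- length(better)
  action <- integer(n); reward <- numeric(n); pch <- numeric(n)
  for (t in seq_len(n)) {
    p1 <- hsmm_predict(st)[1]
    if (mixture) {
      p1 <- pars$gamma *
        softmax_policy(q, pars$beta / agent$reward_scale)[1] +
        (1 - pars$gamma) * p1
    }
    a <- if (runif(1) < p1) 1L else 2L
    r <- rnorm(1, if (a == better[t]) cfg$mean_high else cfg$mean_low,
               cfg$reward_sd)
    action[t] <- a; reward[t] <- r
    pch[t] <- if (a == 1L) p1 else 1 - p1
    st <- hsmm_observe(st, a, r)
    if (mixture) q <- q_update(q, a, r, pars$alpha)
  }
  list(action = action, reward = reward, p_chosen = pch)
}

#' Default duration-parameter grid for the HSMM fit
#'
#' `p` runs linearly from 0.01 to 0.99 in 17 points (steps of about 0.06) and
#' `n` from 1 to 97 in steps of 6.
#' @return A list with numeric vectors `n` and `p`.
#' @export
hsmm_default_grid <- function() {
  list(n = seq(1, 97, by = 6), p = seq(0.01, 0.99, length.out = 17))
}
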