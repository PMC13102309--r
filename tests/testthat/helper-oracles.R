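# Independent oracles used across the suite. These deliberately avoid the
# package's own recursion/replay code paths.

# Brute-force predictive state posterior of the duration-explicit two-state
# model: enumerates every tiling of the past into complete alternating
# segments (durations 1..D) plus the ongoing segment's (h, d) pair, weighting
# by the duration pmf, the uniform elapsed-time prior 1/d, and Gaussian
# emissions. Feasible for short sequences only.
enum_hsmm_posterior <- function(actions, rewards, hp, t) {
  D <- hp$D
  pmf <- duration_pmf(hp$n, hp$p, D)$pmf
  emis <- function(i, from, to) {
    if (from > to) return(1)
    idx <- from:to
    exp(sum(dnorm(rewards[idx],
                  ifelse(actions[idx] == i, hp$mu_high, hp$mu_low),
                  hp$sigma_c, log = TRUE)))
  }
  # total mass of complete-segment tilings of trials 1..u whose last segment
  # has state j (0.5 prior over the first segment's state)
  tilings <- function(u, j) {
    if (u == 0) return(0.5)
    total <- 0
    recurse <- function(remaining, state, acc) {
      for (d in seq_len(min(remaining, D))) {
        w <- pmf[d] * emis(state, remaining - d + 1, remaining)
        if (remaining - d == 0) {
          total <<- total + acc * w * 0.5
        } else {
          recurse(remaining - d, 3 - state, acc * w)
        }
      }
    }
    recurse(u, j, 1)
    total
  }
  num <- vapply(1:2, function(i) {
    s <- 0
    for (h in seq_len(min(t, D))) {
      u <- t - h
      w_tail <- sum(pmf[h:D] / (h:D))
      s <- s + tilings(u, 3 - i) * w_tail * emis(i, u + 1, t - 1)
    }
    s
  }, numeric(1))
  num / sum(num)
}

# Plain-R sequential replay of the two-parameter Q-learner, built from the
# exported single-step primitives (softmax argument uses the package's
# beta-per-100-reward-units convention).
replay_oracle_mf <- function(actions, rewards, alpha, beta, q0 = 50,
                             reward_scale = 100) {
  n <- length(actions)
  q <- c(q0, q0)
  pch <- numeric(n)
  for (t in seq_len(n)) {
    pr <- softmax_policy(q, beta / reward_scale)
    pch[t] <- pr[actions[t]]
    q <- q_update(q, actions[t], rewards[t], alpha)
  }
  pch
}

# Independent Monte-Carlo episode simulator for the two-parameter learner.
simulate_oracle_mf <- function(better, alpha, beta, q0 = 50, mh = 60,
                               ml = 40, sd = 8, reward_scale = 100) {
  n <- length(better)
  q <- c(q0, q0)
  a <- integer(n)
  for (t in seq_len(n)) {
    p1 <- softmax_policy(q, beta / reward_scale)[1]
    a[t] <- if (runif(1) < p1) 1L else 2L
    r <- rnorm(1, if (a[t] == better[t]) mh else ml, sd)
    q <- q_update(q, a[t], r, alpha)
  }
  mean(a == better)
}

quick_settings <- function(n_restarts = 10, seed = 1L, ...) {
  fit_settings(n_restarts = n_restarts, n_perf_sims = 50, seed = seed, ...)
}

sim_table <- function(alpha = 0.9, beta = 15, seed = 42, cfg = task_config(),
                      conf_bounds = c(1, 5)) {
  run_episode(agent_spec("mf", list(alpha = alpha, beta = beta),
                         conf_bounds = conf_bounds),
              cfg, seed = seed)
}
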