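#' Fitting settings
#'
#' Controls the multi-restart estimation used by [fit_forward()] and
#' [fit_backward()]. Restart initializations are drawn uniformly within the
#' parameter bounds from per-restart child seeds, so the best objective over
#' restarts is reproducible and non-increasing as restarts are added.
#'
#' @param n_restarts Number of random restarts of the bounded local optimizer
#'   (default 120, the point at which estimates stabilize for this task).
#' @param n_perf_sims Number of autonomous task simulations averaged when
#'   estimating a fitted model's performance (default 100).
#' @param n_restarts_grid Restarts of the continuous sub-problem at each
#'   (n, p) grid point for HSMM/mixture fits.
#' @param seed Integer seed governing restart initializations.
#' @param q0 Initial option value for Q-learning models (default 50, the
#'   midpoint of the two reward means).
#' @param prob_floor Floor applied to choice probabilities inside `log()` so
#'   the likelihood stays finite.
#' @param grid Duration-parameter grid for HSMM/mixture fits
#'   (default [hsmm_default_grid()]).
#' @param D Maximum latent-state duration for HSMM/mixture fits.
#' @param optim_control `control` list passed to [stats::optim()].
#' @param reward_scale Reward units per softmax unit (see
#'   [replay_pchoice()]).
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(n_restarts = 120, n_perf_sims = 100,
                         n_restarts_grid = 10, seed = 1L, q0 = 50,
                         prob_floor = 1e-12, grid = hsmm_default_grid(),
                         D = 70, optim_control = list(maxit = 500),
                         reward_scale = 100) {
  stopifnot(n_restarts >= 1, n_perf_sims >= 1)
  structure(list(n_restarts = as.integer(n_restarts),
                 n_perf_sims = as.integer(n_perf_sims),
                 n_restarts_grid = as.integer(n_restarts_grid),
                 seed = as.integer(seed), q0 = q0, prob_floor = prob_floor,
                 grid = grid, D = as.integer(D),
                 optim_control = optim_control, reward_scale = reward_scale),
            class = "fit_settings")
}

#' Negative log-likelihood of observed choices under a model
#'
#' Replays the model over the observed action/reward sequence (the model is
#' updated with the subject's actions and rewards) and sums
#' `-log P(action_t | history)`. Probabilities are floored so the result is
#' finite.
#'
#' @inheritParams replay_pchoice
#' @param prob_floor Probability floor inside the log.
#' @return The negative log-likelihood (a single number).
#' @export
choice_nll <- function(trials, model = "mf", params, cfg = NULL, q0 = 50,
                       prob_floor = 1e-12, reward_scale = 100) {
  rp <- replay_pchoice(trials, model, params, cfg = cfg, q0 = q0,
                       reward_scale = reward_scale)
  -sum(log(pmax(rp$p_chosen, prob_floor)))
}

#' Squared confidence distance of a model
#'
#' Maps the model's probability of the subject's chosen action onto the
#' rating scale with bounds (L, H), optionally applies leaky integration with
#' the previously *reported* confidence, and sums squared deviations from the
#' empirical ratings.
#'
#' @inheritParams replay_pchoice
#' @param L,H Reporting bounds, `L < H`.
#' @param lambda Optional leak weight; `NULL` disables leaky integration.
#' @return The summed squared distance (a single number).
#' @export
confidence_distance <- function(trials, model = "mf", params, L, H,
                                lambda = NULL, cfg = NULL, q0 = 50,
                                reward_scale = 100) {
  rp <- replay_pchoice(trials, model, params, cfg = cfg, q0 = q0,
                       reward_scale = reward_scale)
  conf_from_pchosen(rp$p_chosen, L, H, lambda, trials$confidence) |>
    (\(cm) sum((cm - trials$confidence)^2))()
}

conf_from_pchosen <- function(p_chosen, L, H, lambda = NULL,
                              reported = NULL) {
  cm <- scale_confidence(p_chosen, L, H)
  if (!is.null(lambda)) cm <- leaky_sequence(cm, lambda, reported)
  cm
}

# --- (L, H) reparameterization -------------------------------------------
# L in [1, 5) is fitted directly; H = L + (5 - L) * plogis(v) with v in
# [-12, 12], so L < H <= 5 holds by construction (no rejection at the
# boundary). plogis(12) leaves H short of 5 by < 4e-5.
lh_from_par <- function(L, v) c(L = unname(L), H = unname(L + (5 - L) * stats::plogis(v)))
lh_to_par <- function(L, H) c(L = L, v = stats::qlogis(min(max((H - L) / (5 - L), 1e-5), 1 - 1e-5)))
LH_BOUNDS <- list(L = c(1, 4.999), v = c(-12, 12))

# --- multi-restart bounded optimization ----------------------------------
multistart_optim <- function(fn, lower, upper, n_restarts, seed,
                             control = list(maxit = 500)) {
  k <- length(lower)
  results <- purrr::map(seq_len(n_restarts), function(i) {
    init <- with_seed(child_seed(seed, i),
                      runif(k, min = lower, max = upper))
    ans <- tryCatch(
      optim(init, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = control),
      error = function(e) NULL)
    if (is.null(ans)) {
      # fall back to a derivative-free pass from the same start
      ans <- tryCatch(
        optim(init, fn, method = "Nelder-Mead",
              control = utils::modifyList(control, list(warn.1d.NelderMead = FALSE))),
        error = function(e) NULL)
      if (!is.null(ans)) ans$par <- pmin(pmax(ans$par, lower), upper)
    }
    ans
  })
  ok <- !purrr::map_lgl(results, is.null)
  if (!any(ok)) {
    stop_input("all %d restarts failed to converge.", n_restarts)
  }
  vals <- purrr::map_dbl(results, \(r) if (is.null(r)) Inf else r$value)
  best <- which.min(vals)
  list(par = results[[best]]$par, value = results[[best]]$value,
       per_restart = tibble::tibble(
         restart = seq_len(n_restarts), objective = vals,
         converged = purrr::map_lgl(
           results, \(r) !is.null(r) && isTRUE(r$convergence == 0))))
}

mf_param_names <- function(model) {
  if (model == "mf") c("alpha", "beta")
  else c("alpha_pos", "alpha_neg", "alpha_unchosen", "beta")
}

n_choice_params <- function(model) {
  switch(model, mf = 2L, mf4 = 4L, hsmm = 2L, mixture = 5L)
}

#' Fit the Forward model to a subject's choices
#'
#' Two-stage estimation: (1) the choice parameters are fitted by maximum
#' likelihood of the observed actions; (2) holding those fixed, the reporting
#' bounds (L, H) are fitted by least squares between the scaled chosen-option
#' probability and the empirical confidence ratings. Both stages use
#' multi-restart bounded optimization. For `hsmm` and `mixture` models the
#' duration parameters (n, p) are fitted by grid search, with any continuous
#' choice parameters optimized at each grid point.
#'
#' @param trials A trial tibble for one subject and condition.
#' @param model `"mf"`, `"mf4"`, `"hsmm"`, or `"mixture"`.
#' @param settings A [fit_settings()] object.
#' @param cfg Task configuration; taken from the table attribute when absent.
#' @return A `metarl_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' ag <- agent_spec("mf", list(alpha = 0.5, beta = 15))
#' tt <- run_episode(ag, task_config(), seed = 7)
#' fit <- fit_forward(tt, "mf", fit_settings(n_restarts = 5))
#' tidy(fit)
#' @export
fit_forward <- function(trials, model = c("mf", "mf4", "hsmm", "mixture"),
                        settings = fit_settings(), cfg = NULL) {
  model <- match.arg(model)
  if (nrow(trials) == 0) stop_input("`trials` is empty.")
  cfg <- cfg %||% attr(trials, "task_config")
  if (model %in% c("hsmm", "mixture")) {
    return(grid_fit_hsmm(trials, direction = "forward", model = model,
                         settings = settings, cfg = cfg))
  }
  nms <- mf_param_names(model)
  bounds <- param_bounds()[nms]
  lower <- purrr::map_dbl(bounds, 1); upper <- purrr::map_dbl(bounds, 2)
  act <- as.integer(trials$action); rew <- as.double(trials$reward)
  nll_fn <- function(par) {
    pars <- mf_par4(model, as.list(setNames(par, nms)))
    rp <- mf_replay_cpp(act, rew, pars[["alpha_pos"]], pars[["alpha_neg"]],
                        pars[["alpha_unchosen"]],
                        pars[["beta"]] / settings$reward_scale, settings$q0)
    -sum(log(pmax(rp$p_chosen, settings$prob_floor)))
  }
  stage1 <- multistart_optim(nll_fn, lower, upper, settings$n_restarts,
                             settings$seed, settings$optim_control)
  params <- as.list(setNames(stage1$par, nms))
  # stage 2: reporting bounds on the fixed replayed probabilities
  p4 <- mf_par4(model, params)
  pch <- mf_replay_cpp(act, rew, p4[["alpha_pos"]], p4[["alpha_neg"]],
                       p4[["alpha_unchosen"]],
                       p4[["beta"]] / settings$reward_scale,
                       settings$q0)$p_chosen
  conf <- trials$confidence
  lh_fn <- function(par) {
    lh <- lh_from_par(par[1], par[2])
    sum((conf_from_pchosen(pch, lh["L"], lh["H"]) - conf)^2)
  }
  stage2 <- multistart_optim(lh_fn, c(LH_BOUNDS$L[1], LH_BOUNDS$v[1]),
                             c(LH_BOUNDS$L[2], LH_BOUNDS$v[2]),
                             settings$n_restarts,
                             child_seed(settings$seed, 9991),
                             settings$optim_control)
  lh <- lh_from_par(stage2$par[1], stage2$par[2])
  new_metarl_fit(model = model, direction = "forward",
                 params = c(params, as.list(lh)),
                 objective = stage1$value, choice_nll = stage1$value,
                 conf_objective = stage2$value, n_obs = nrow(trials),
                 per_restart = stage1$per_restart, settings = settings,
                 cfg = cfg)
}

#' Fit the Backward model to a subject's confidence ratings
#'
#' All parameters — the choice parameters and the reporting bounds (L, H),
#' plus the leak weight `lambda` when `leaky = TRUE` — are fitted jointly by
#' minimizing the squared distance between the model's scaled chosen-option
#' probabilities and the empirical confidence ratings. The model is replayed
#' on the subject's observed actions and rewards; with `leaky = TRUE` the
#' predicted confidence on trial t mixes the model's current confidence with
#' the confidence *reported* on trial t - 1.
#'
#' @inheritParams fit_forward
#' @param leaky Add the leak weight `lambda` to the fitted parameters.
#' @return A `metarl_fit` object.
#' @export
fit_backward <- function(trials, model = c("mf", "mf4", "hsmm", "mixture"),
                         settings = fit_settings(), leaky = FALSE,
                         cfg = NULL) {
  model <- match.arg(model)
  if (nrow(trials) == 0) stop_input("`trials` is empty.")
  cfg <- cfg %||% attr(trials, "task_config")
  if (model %in% c("hsmm", "mixture")) {
    return(grid_fit_hsmm(trials, direction = "backward", model = model,
                         settings = settings, leaky = leaky, cfg = cfg))
  }
  nms <- mf_param_names(model)
  bounds <- param_bounds()[nms]
  lower <- c(purrr::map_dbl(bounds, 1), LH_BOUNDS$L[1], LH_BOUNDS$v[1])
  upper <- c(purrr::map_dbl(bounds, 2), LH_BOUNDS$L[2], LH_BOUNDS$v[2])
  if (leaky) { lower <- c(lower, 0); upper <- c(upper, 1) }
  act <- as.integer(trials$action); rew <- as.double(trials$reward)
  conf <- trials$confidence
  k <- length(nms)
  obj_fn <- function(par) {
    pars <- mf_par4(model, as.list(setNames(par[seq_len(k)], nms)))
    pch <- mf_replay_cpp(act, rew, pars[["alpha_pos"]], pars[["alpha_neg"]],
                         pars[["alpha_unchosen"]],
                         pars[["beta"]] / settings$reward_scale,
                         settings$q0)$p_chosen
    lh <- lh_from_par(par[k + 1], par[k + 2])
    lam <- if (leaky) par[k + 3] else NULL
    sum((conf_from_pchosen(pch, lh["L"], lh["H"], lam, conf) - conf)^2)
  }
  ans <- multistart_optim(obj_fn, lower, upper, settings$n_restarts,
                          settings$seed, settings$optim_control)
  params <- as.list(setNames(ans$par[seq_len(k)], nms))
  lh <- lh_from_par(ans$par[k + 1], ans$par[k + 2])
  params <- c(params, as.list(lh))
  if (leaky) params$lambda <- ans$par[k + 3]
  new_metarl_fit(model = model, direction = "backward", params = params,
                 objective = ans$value,
                 choice_nll = choice_nll(trials, model, params, cfg = cfg,
                                         q0 = settings$q0,
                                         prob_floor = settings$prob_floor,
                                         reward_scale = settings$reward_scale),
                 conf_objective = ans$value, n_obs = nrow(trials),
                 per_restart = ans$per_restart, settings = settings,
                 cfg = cfg, leaky = leaky)
}

#' Grid-search fit of the HSMM duration parameters
#'
#' Evaluates the fit objective at every (n, p) point of the duration grid —
#' the choice negative log-likelihood for Forward fits, the squared
#' confidence distance for Backward fits — optimizing any continuous
#' parameters (`alpha`, `beta`, `gamma` for the mixture; `L`, `H`, and
#' optionally `lambda` for Backward fits) at each point, and returns the
#' global best.
#'
#' @inheritParams fit_backward
#' @param direction `"forward"` (choices, maximum likelihood) or `"backward"`
#'   (confidence, least squares).
#' @return A `metarl_fit` object whose parameters include `n`, `p` and the
#'   implied mean reversal time `t_bar_rev`.
#' @export
grid_fit_hsmm <- function(trials, direction = c("forward", "backward"),
                          model = c("hsmm", "mixture"),
                          settings = fit_settings(), leaky = FALSE,
                          cfg = NULL) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  cfg <- cfg %||% attr(trials, "task_config") %||%
    stop_input("`cfg` is required for HSMM fits.")
  act <- as.integer(trials$action); rew <- as.double(trials$reward)
  conf <- trials$confidence
  grid <- expand.grid(n = settings$grid$n, p = settings$grid$p,
                      KEEP.OUT.ATTRS = FALSE)
  eval_point <- function(n, p, idx) {
    hp <- hsmm_params(n = n, p = p, D = settings$D, cfg = cfg)
    post1 <- hsmm_filter(act, rew, hp)$p_state1
    pch_mb <- ifelse(act == 1L, post1, 1 - post1)
    seed_i <- child_seed(settings$seed, idx)
    if (model == "hsmm" && direction == "forward") {
      list(value = -sum(log(pmax(pch_mb, settings$prob_floor))),
           par = NULL, post1 = post1)
    } else if (model == "hsmm") {
      lower <- c(LH_BOUNDS$L[1], LH_BOUNDS$v[1])
      upper <- c(LH_BOUNDS$L[2], LH_BOUNDS$v[2])
      if (leaky) { lower <- c(lower, 0); upper <- c(upper, 1) }
      fn <- function(par) {
        lh <- lh_from_par(par[1], par[2])
        lam <- if (leaky) par[3] else NULL
        sum((conf_from_pchosen(pch_mb, lh["L"], lh["H"], lam, conf) - conf)^2)
      }
      c(multistart_optim(fn, lower, upper, settings$n_restarts_grid, seed_i,
                         settings$optim_control)[c("par", "value")],
        list(post1 = post1))
    } else {
      # mixture: gamma * P_MF + (1 - gamma) * P_MB
      lower <- c(0, 0, 0); upper <- c(1, 100, 1)   # alpha, beta, gamma
      nms <- c("alpha", "beta", "gamma")
      if (direction == "backward") {
        lower <- c(lower, LH_BOUNDS$L[1], LH_BOUNDS$v[1])
        upper <- c(upper, LH_BOUNDS$L[2], LH_BOUNDS$v[2])
        if (leaky) { lower <- c(lower, 0); upper <- c(upper, 1) }
      }
      fn <- function(par) {
        pmf <- mf_replay_cpp(act, rew, par[1], par[1], 0,
                             par[2] / settings$reward_scale,
                             settings$q0)$p1
        p1 <- par[3] * pmf + (1 - par[3]) * post1
        pch <- ifelse(act == 1L, p1, 1 - p1)
        if (direction == "forward") {
          -sum(log(pmax(pch, settings$prob_floor)))
        } else {
          lh <- lh_from_par(par[4], par[5])
          lam <- if (leaky) par[6] else NULL
          sum((conf_from_pchosen(pch, lh["L"], lh["H"], lam, conf) - conf)^2)
        }
      }
      c(multistart_optim(fn, lower, upper, settings$n_restarts_grid, seed_i,
                         settings$optim_control)[c("par", "value")],
        list(post1 = post1))
    }
  }
  res <- purrr::pmap(list(grid$n, grid$p, seq_len(nrow(grid))), eval_point)
  vals <- purrr::map_dbl(res, "value")
  best <- which.min(vals)
  bn <- grid$n[best]; bp <- grid$p[best]
  params <- list(n = bn, p = bp, D = settings$D,
                 t_bar_rev = duration_pmf(bn, bp, settings$D)$t_bar_rev)
  bpar <- res[[best]]$par
  if (model == "mixture") {
    params$alpha <- bpar[1]; params$beta <- bpar[2]; params$gamma <- bpar[3]
    if (direction == "backward") {
      params <- c(params, as.list(lh_from_par(bpar[4], bpar[5])))
      if (leaky) params$lambda <- bpar[6]
    }
  } else if (direction == "backward") {
    params <- c(params, as.list(lh_from_par(bpar[1], bpar[2])))
    if (leaky) params$lambda <- bpar[3]
  }
  nll <- choice_nll(trials, model, params, cfg = cfg, q0 = settings$q0,
                    prob_floor = settings$prob_floor,
                    reward_scale = settings$reward_scale)
  conf_obj <- NA_real_
  if (direction == "forward") {
    # stage 2: reporting bounds on the best grid point's probabilities
    p1 <- res[[best]]$post1
    if (model == "mixture") {
      pmf <- mf_replay_cpp(act, rew, params$alpha, params$alpha, 0,
                           params$beta / settings$reward_scale,
                           settings$q0)$p1
      p1 <- params$gamma * pmf + (1 - params$gamma) * p1
    }
    pch <- ifelse(act == 1L, p1, 1 - p1)
    fn2 <- function(par) {
      lh <- lh_from_par(par[1], par[2])
      sum((conf_from_pchosen(pch, lh["L"], lh["H"]) - conf)^2)
    }
    st2 <- multistart_optim(fn2, c(LH_BOUNDS$L[1], LH_BOUNDS$v[1]),
                            c(LH_BOUNDS$L[2], LH_BOUNDS$v[2]),
                            settings$n_restarts_grid,
                            child_seed(settings$seed, 9992),
                            settings$optim_control)
    params <- c(params, as.list(lh_from_par(st2$par[1], st2$par[2])))
    conf_obj <- st2$value
  } else {
    conf_obj <- vals[best]
  }
  new_metarl_fit(model = model, direction = direction, params = params,
                 objective = if (direction == "forward") nll else vals[best],
                 choice_nll = nll, conf_objective = conf_obj,
                 n_obs = nrow(trials),
                 per_restart = tibble::tibble(
                   restart = seq_len(nrow(grid)), n = grid$n, p = grid$p,
                   objective = vals, converged = is.finite(vals)),
                 settings = settings, cfg = cfg, leaky = leaky)
}

new_metarl_fit <- function(model, direction, params, objective, choice_nll,
                           conf_objective, n_obs, per_restart, settings,
                           cfg = NULL, leaky = FALSE) {
  structure(list(model = model, direction = direction, params = params,
                 objective = objective, choice_nll = choice_nll,
                 conf_objective = conf_objective, n_obs = n_obs,
                 n_choice_params = n_choice_params(model),
                 per_restart = per_restart, settings = settings, cfg = cfg,
                 leaky = leaky),
            class = "metarl_fit")
}

#' @export
print.metarl_fit <- function(x, ...) {
  cat(sprintf("<metarl_fit> %s %s model%s\n", x$direction, x$model,
              if (isTRUE(x$leaky)) " (leaky confidence)" else ""))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  objective: %.4f (%s), n = %d\n", x$objective,
              if (x$direction == "forward") "choice NLL"
              else "confidence distance", x$n_obs))
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x A `metarl_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of `term`/`estimate` pairs. `glance()`: a
#'   one-row tibble with the objectives and information criteria (AIC/BIC
#'   apply only to likelihood-based Forward fits).
#' @method tidy metarl_fit
#' @export
tidy.metarl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(unlist(x$params)))
}

#' @rdname tidy.metarl_fit
#' @method glance metarl_fit
#' @export
glance.metarl_fit <- function(x, ...) {
  ic <- if (x$direction == "forward") {
    information_criteria(x)
  } else {
    tibble::tibble(AIC = NA_real_, BIC = NA_real_)
  }
  tibble::tibble(model = x$model, direction = x$direction,
                 objective = x$objective, choice_nll = x$choice_nll,
                 conf_objective = x$conf_objective, n_obs = x$n_obs,
                 n_params = x$n_choice_params, AIC = ic$AIC, BIC = ic$BIC)
}

#' Information criteria for a likelihood-based fit
#'
#' `AIC = 2k + 2 NLL`, `BIC = k log(n) + 2 NLL`, where k counts the fitted
#' choice parameters. Backward fits minimize a squared confidence distance,
#' not a likelihood, and are rejected.
#'
#' @param fit A Forward `metarl_fit`.
#' @param n_obs Number of observations; defaults to the fitted table's size.
#' @return A one-row tibble with `AIC` and `BIC`.
#' @export
information_criteria <- function(fit, n_obs = fit$n_obs) {
  if (fit$direction != "forward") {
    stop_input(paste0("information criteria require a likelihood-based ",
                      "(Forward) fit; Backward fits minimize a confidence ",
                      "distance."))
  }
  k <- fit$n_choice_params
  tibble::tibble(AIC = 2 * k + 2 * fit$objective,
                 BIC = k * log(n_obs) + 2 * fit$objective)
}
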