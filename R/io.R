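#' Read and write trial tables
#'
#' Trial tables are stored as CSV with the header
#' `subject,condition,trial,block,better_option,action,reward,confidence`
#' (confidence as a float in \[1, 5\], trials 1-based). `read_trials()`
#' validates ranges and per-subject trial contiguity and reports offending
#' row numbers; the derived `correct` column is recomputed on read.
#'
#' @param path File path.
#' @param trials A trial tibble (for `write_trials()`).
#' @return `read_trials()`: a validated trial tibble (all subject-conditions
#'   stacked; split with [dplyr::group_split()] or `split()`).
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject", "condition", "trial", "block", "better_option",
                "action", "reward", "confidence")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_input("missing required columns: %s.", paste(missing, collapse = ", "))
  }
  bad <- which(!(raw$action %in% c(1, 2)))
  if (length(bad) > 0) {
    stop_input("invalid `action` (must be 1 or 2) in rows: %s.",
               paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(!(raw$better_option %in% c(1, 2)))
  if (length(bad) > 0) {
    stop_input("invalid `better_option` in rows: %s.",
               paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(raw$confidence < 1 | raw$confidence > 5)
  if (length(bad) > 0) {
    stop_input("confidence outside [1, 5] in rows: %s.",
               paste(head(bad, 5), collapse = ", "))
  }
  out <- raw |>
    dplyr::mutate(trial = as.integer(.data$trial),
                  block = as.integer(.data$block),
                  better_option = as.integer(.data$better_option),
                  action = as.integer(.data$action),
                  correct = as.integer(.data$action == .data$better_option))
  check <- out |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(contiguous = all(.data$trial == seq_along(.data$trial)),
                     .groups = "drop")
  if (!all(check$contiguous)) {
    bad <- check[!check$contiguous, ]
    stop_input("non-contiguous trial indices for subject(s): %s.",
               paste(unique(bad$subject), collapse = ", "))
  }
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "condition", "trial", "block", "better_option",
            "action", "reward", "confidence")
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' Run the full simulate/fit/report pipeline
#'
#' For each subject-condition in the input: applies the chance-level
#' exclusion filter, fits the Forward and Backward models, estimates their
#' simulated performances, and assembles a [metacog_report()] row. Excluded
#' subject-conditions are flagged (`excluded = TRUE`) and skip the model
#' fits.
#'
#' @param trials A trial tibble (e.g. from [read_trials()]) or a path to a
#'   trial CSV.
#' @param model Choice model id.
#' @param settings [fit_settings()].
#' @param leaky Use the leaky confidence representation in the Backward fit.
#' @param cfg Task configuration; inferred per condition label when `NULL`
#'   (low/high-variance defaults).
#' @param seed Integer seed for performance simulations.
#' @return A tibble with one report row per subject-condition; fitted model
#'   objects are attached in the `"fits"` attribute (a named list with
#'   `forward`/`backward` per group).
#' @export
pipeline_run <- function(trials, model = "mf", settings = fit_settings(),
                         leaky = FALSE, cfg = NULL, seed = 1L) {
  if (is.character(trials)) trials <- read_trials(trials)
  groups <- split(trials, interaction(trials$subject, trials$condition,
                                      drop = TRUE, sep = "|"))
  fits <- list()
  report <- purrr::imap_dfr(groups, function(tt, key) {
    cfg_g <- cfg %||% attr(trials, "task_config") %||%
      task_config(if (grepl("high", tt$condition[1])) "high_variance"
                  else "low_variance")
    attr(tt, "task_config") <- cfg_g
    excl <- exclusion_chi_square(sum(tt$correct), nrow(tt))
    if (excl$excluded) {
      rep <- metacog_report(tt, NULL, NULL, n_sims = settings$n_perf_sims,
                            seed = seed)
      return(rep)
    }
    fwd <- fit_forward(tt, model, settings, cfg = cfg_g)
    bwd <- fit_backward(tt, model, settings, leaky = leaky, cfg = cfg_g)
    fits[[key]] <<- list(forward = fwd, backward = bwd)
    metacog_report(tt, fwd, bwd, n_sims = settings$n_perf_sims,
                   seed = child_seed(seed, match(key, names(groups))))
  })
  attr(report, "fits") <- fits
  report
}
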