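#' Plot a trial table
#'
#' Reward and confidence traces with reversal points marked; choices of the
#' better option are shown along the top rug.
#'
#' @param trials A trial tibble for one subject-condition.
#' @return A ggplot object.
#' @export
plot_trials <- function(trials) {
  rev_pts <- trials$trial[c(FALSE, diff(trials$better_option) != 0)]
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_vline(xintercept = rev_pts, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$reward), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = 10 * .data$confidence),
                       colour = "#2166ac") +
    ggplot2::geom_rug(data = trials[trials$correct == 1L, ], sides = "t",
                      alpha = 0.3) +
    ggplot2::scale_y_continuous(
      "reward",
      sec.axis = ggplot2::sec_axis(~ . / 10, name = "confidence")) +
    ggplot2::labs(x = "trial",
                  title = sprintf("%s (%s)", trials$subject[1],
                                  trials$condition[1]))
}

#' @describeIn autoplot-metarl Restart-objective diagnostics of a fit.
#' @method autoplot metarl_fit
#' @export
autoplot.metarl_fit <- function(object, ...) {
  ggplot2::ggplot(object$per_restart,
                  ggplot2::aes(x = .data$restart, y = .data$objective)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$objective, colour = "#b2182b") +
    ggplot2::labs(x = "restart", y = if (object$direction == "forward")
      "choice NLL" else "confidence distance",
      title = sprintf("%s %s fit: best objective %.3f", object$direction,
                      object$model, object$objective))
}

#' Autoplot methods
#'
#' @name autoplot-metarl
#' @param object A `metarl_fit` or `metarl_report`.
#' @param ... Unused.
#' @return A ggplot object.
NULL

#' @describeIn autoplot-metarl Cohort view of report rows: empirical,
#'   Forward and Backward performance, and the MetaRL.Ratio distribution.
#' @method autoplot metarl_report
#' @export
autoplot.metarl_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("subject", "condition", "perf_empirical",
                                "perf_forward", "perf_backward")],
    dplyr::starts_with("perf"), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5,
                         ggplot2::aes(colour = .data$condition)) +
    ggplot2::labs(x = NULL, y = "fraction of better-option choices")
}
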