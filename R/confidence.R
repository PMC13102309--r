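#' Map choice probabilities to the confidence scale
#'
#' Confidence is modeled as an affine rescaling of the probability assigned to
#' the chosen option: `conf = (H - L) * p + L`, with fitted lower and upper
#' reporting bounds `1 <= L < H <= 5` absorbing individual differences in how
#' the rating scale is used.
#'
#' @param p Probability in \[0, 1\].
#' @param L,H Reporting bounds with `L < H` (strict).
#' @return Confidence values in \[L, H\].
#' @examples
#' scale_confidence(c(0, 0.5, 1), L = 2, H = 4)
#' @export
scale_confidence <- function(p, L, H) {
  if (L >= H) stop_input("`L` (%s) must be strictly below `H` (%s).", L, H)
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    stop_input("`p` must lie in [0, 1].")
  }
  (H - L) * p + L
}

#' Leaky integration of confidence across trials
#'
#' The reported confidence is a convex combination of the current model
#' confidence and the previous trial's confidence:
#' `lambda * current + (1 - lambda) * previous`. With `lambda = 1` only the
#' current confidence counts; with `lambda = 0` the previous value carries
#' over unchanged. On the first trial, where no previous confidence exists,
#' the current value is used as is.
#'
#' @param current,previous Confidence ratings in \[1, 5\].
#' @param lambda Current-trial weight in \[0, 1\].
#' @return Leak-integrated confidence.
#' @export
leaky_confidence <- function(current, previous, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  lambda * current + (1 - lambda) * previous
}

# Apply leaky integration along a sequence. When `previous_reported` is given
# (fitting to data), trial t > 1 mixes with the empirical report at t - 1;
# otherwise (autonomous simulation) with the model's own previous output.
leaky_sequence <- function(current, lambda, previous_reported = NULL) {
  n <- length(current)
  if (n == 0 || lambda == 1) return(current)
  if (!is.null(previous_reported)) {
    out <- lambda * current + (1 - lambda) * c(current[1], previous_reported[-n])
    out[1] <- current[1]
    out
  } else {
    Reduce(function(prev, cur) lambda * cur + (1 - lambda) * prev,
           current, accumulate = TRUE)
  }
}

#' Normalize a confidence rating to the unit interval
#'
#' Maps the \[1, 5\] rating scale onto \[0, 1\] via `(conf - 1) / 4`, the
#' normalization used by the quadratic scoring rule so confidence and
#' trial-level correctness share a scale.
#'
#' @param conf Ratings in \[1, 5\].
#' @return Values in \[0, 1\].
#' @export
normalize_confidence <- function(conf) {
  if (any(conf < 1 - 1e-9 | conf > 5 + 1e-9, na.rm = TRUE)) {
    stop_input("confidence ratings must lie in [1, 5].")
  }
  (conf - 1) / 4
}
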