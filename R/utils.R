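# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed for sub-streams (kept under 2^31 - 1).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 1000003) * 1009 + 7 * as.double(k)) %% 2147483647L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "metarl_input_error")
}

check_option_id <- function(x, name) {
  if (!all(x %in% c(1L, 2L))) {
    stop_input("`%s` must contain only option ids 1 or 2.", name)
  }
}
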