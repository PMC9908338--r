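# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' one so that toggling a stage on or off never perturbs the random stream of
#' the others. The derivation is a small deterministic hash of the stage name
#' folded into the 31-bit signed-integer range R requires of `set.seed()`.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag, e.g. `"kge"`.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

# Stable descending order: ties broken by lower index first.
order_desc_stable <- function(x) order(-x, seq_along(x))

# Consistent condition for configuration problems.
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("syndromeKG_config_error", "error")))
}

log_msg <- function(..., verbose = getOption("syndromeKG.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
}
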