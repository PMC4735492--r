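# Internal helpers: classed errors and deterministic seed derivation.

rn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "raidnet_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

rn_param_error  <- function(msg) rn_stop(msg, "raidnet_parameter_error")
rn_config_error <- function(msg) rn_stop(msg, "raidnet_config_error")
rn_format_error <- function(msg) rn_stop(msg, "raidnet_format_error")
rn_lookup_error <- function(msg) rn_stop(msg, "raidnet_lookup_error")
rn_gen_error    <- function(msg) rn_stop(msg, "raidnet_generation_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

#' Derive a reproducible child seed from a tuple of integers
#'
#' Mixes an arbitrary tuple of integers (base seed, sweep cell index,
#' replicate index, ...) into a single seed in `[1, 2^31 - 2]` with a
#' multiplicative-congruential hash. Used everywhere a replicate or sweep
#' cell needs its own RNG stream that is reproducible in isolation.
#'
#' @param ... integers identifying the stream.
#' @return a single integer seed suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, 3, 17)
derive_seed <- function(...) {
  v <- as.numeric(c(...))
  if (length(v) == 0L || anyNA(v)) {
    rn_param_error("derive_seed() needs at least one non-missing integer")
  }
  h <- 17
  for (x in v) {
    h <- (h * 48271 + (abs(x) %% 2147483647) * 1009 + 12345) %% 2147483563
  }
  as.integer(h %% 2147483562 + 1)
}
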