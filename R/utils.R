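# Internal helpers shared across modules.

# Signal a classed error so callers/tests can distinguish failure modes.
stop_voxtex <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "voxtex_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit mixing of small non-negative integers, used to derive
# per-volume seeds from a master seed without global RNG state.
mix_seed <- function(...) {
  parts <- c(...)
  h <- 0
  for (p in parts) {
    # multiplier kept small so h * 69069 + p stays well below 2^53
    h <- (h * 69069 + as.numeric(p) + 12345) %% 2147483647
  }
  as.integer(h)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
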