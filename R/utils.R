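# RNG hygiene: functions that take a `seed` argument seed the global RNG
# locally and restore whatever state the caller had.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic per-stream seed derived from (seed, index), kept well below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 10007) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
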