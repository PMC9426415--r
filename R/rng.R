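# Deterministic, restorable RNG scope. Public generator entry points
# require an explicit seed; a missing seed is an error, never the clock.

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    stop("a seed is required (set it in the design or pass seed = )",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index)) %% 2147483629)
}
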