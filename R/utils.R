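# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed-scoped RNG: seeds the generator for the calling function's body and
# restores the caller's RNG state when that function exits, so seeded
# generators compose without clobbering global state.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  do.call(base::on.exit, list(bquote((.(restore))()), TRUE, FALSE),
          envir = envir)
  invisible(NULL)
}

# Derive a well-spread child seed from a parent seed and a stream index,
# kept inside the positive 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
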