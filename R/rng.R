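# Named RNG substreams. Each simulation seed is expanded into independent
# substreams (cohort, enrollment, transition, observation, policy) so that
# policies can be compared on identical cohorts under common random numbers.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

STREAM_IDS <- c(cohort = 1, enrollment = 2, transition = 3, observation = 4, policy = 5)

# Deterministic 32-bit-safe substream seed (arithmetic kept exact in doubles).
substream_seed <- function(seed, stream) {
  id <- STREAM_IDS[[stream]]
  as.integer(((as.double(seed) %% 599999) * 3559 + id * 7919) %% 2147483562) + 1L
}

# A set of independently seeded RNG streams. Draws are made by swapping the
# stream's saved .Random.seed in and out of the global environment.
make_streams <- function(seed, names = names(STREAM_IDS)) {
  env <- new.env(parent = emptyenv())
  outer <- get_rng_state()
  for (nm in names) {
    set.seed(substream_seed(seed, nm))
    assign(nm, get_rng_state(), envir = env)
  }
  restore_rng_state(outer)
  env
}

with_stream <- function(streams, name, expr) {
  outer <- get_rng_state()
  restore_rng_state(get(name, envir = streams))
  on.exit({
    assign(name, get_rng_state(), envir = streams)
    restore_rng_state(outer)
  })
  expr
}
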