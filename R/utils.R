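# Internal helpers: seed streams and assertions.

# Derive independent child seeds from one master seed. Each named component
# (trial order, cue-validity draws, stimulus contents, observer noise, ...)
# gets its own stream so it is reproducible in isolation.
child_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

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
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, leaving the
# caller's RNG state untouched.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# sample() that never interprets a length-1 numeric x as 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
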