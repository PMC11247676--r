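`%||%` <- function(a, b) if (is.null(a)) b else a

# configuration-error helpers: every message names the offending field
abort_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    abort_cfg(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    abort_cfg(field, "must be a single number in [0, 1]")
  as.numeric(x)
}

check_positive <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    abort_cfg(field, "must be a single number > 0")
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0)
    abort_cfg(field, "must be a single number >= 0")
  as.numeric(x)
}

# run code under a seeded, isolated RNG stream; restores caller's state,
# so generators are pure functions of (config, seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
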