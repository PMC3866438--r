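# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a == 0] <- 2 * pi
  a - pi
}

# Smallest absolute angular difference between two angles (radians).
ang_diff <- function(a, b) abs(wrap_angle(a - b))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Position sampling interval of all trajectories (50 Hz tracking).
TRACK_DT <- 0.02
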