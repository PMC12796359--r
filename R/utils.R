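# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds derived from one user seed, kept < 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(phantom = 101L, tracks = 211L, cohort = 307L, motion = 401L,
               pipeline = 503L, replicate = 601L)
  if (!stream %in% names(offsets)) stop("unknown RNG substream: ", stream)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stream]]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
}

# Wrap angles (degrees) into [-180, 180).
wrap_degrees <- function(theta) {
  ((theta + 180) %% 360) - 180
}
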