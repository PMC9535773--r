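# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG state
#'
#' Runs `code` with the Mersenne-Twister stream seeded at `seed` and restores
#' the caller's RNG state afterwards, so simulators are reproducible without
#' clobbering the session seed.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
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

# Derive a child seed from a parent seed and a stage label, deterministically
# and below 2^31. Small FNV-style hash; good enough to decorrelate stages.
childSeed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# 0-based half-open window index for a 0-based position.
windowIndex <- function(pos0, windowSize) as.integer(pos0 %/% windowSize)

# Maximal runs of TRUE of length >= minRun; returns list of (start, end) index
# pairs (1-based, inclusive).
runsAtLeast <- function(flag, minRun) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  Map(c, starts[keep], ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
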