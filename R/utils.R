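#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames
NULL

# Run code with a temporary RNG state; the caller's stream is untouched.
# seed must be a finite number; it is folded into the 32-bit integer range.
with_local_seed <- function(seed, code) {
  seed <- as.integer(abs(seed) %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-item substream: maps (seed, index, salt) to a new seed.
# Exact in double precision (products stay far below 2^53).
derive_seed <- function(seed, index, salt = 0) {
  s <- (abs(seed) %% 2147483647) + 1
  (s * 48271 + index * 16807 + salt * 69621) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "attnvgg_error")
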