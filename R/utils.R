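#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores whatever RNG state was in place before the call, so that
#' seeded package functions never disturb the caller's random stream.
#' A `NULL` seed evaluates `code` under the current stream unchanged.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Deterministic Lehmer-style mixing of a root seed with a stream index.
#' All stochastic package functions draw their per-sample / per-network
#' seeds through this helper, so serial and restructured runs agree.
#' Results always lie in `[0, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed.
#' @export
split_seed <- function(seed, index) {
  m <- 2147483647
  s <- as.double(seed) %% m
  if (s <= 0) s <- s + m - 1
  as.integer(((s * 48271) %% m + 7919 * as.double(index)) %% m)
}

# Internal: stop() with a consistent message prefix for shape problems.
stop_structural <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

roman_regions <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
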