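# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG seed, restoring the caller's
## RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## Centered moving average of window length k samples; windows are
## shrunk at the series edges rather than padded, so no NAs appear.
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Population standard deviation (divisor n, not n - 1).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
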