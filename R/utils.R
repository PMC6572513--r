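# internal helpers shared across modules

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("esopcg_invalid_argument", "error")))
}

stop_domain <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "esopcg_error", "error")))
}

# centered moving average, window of n samples (n >= 1); edges use
# shrinking windows so length is preserved
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  N <- length(x)
  half_lo <- (n - 1L) %/% 2L
  half_hi <- n %/% 2L
  lo <- pmax(seq_len(N) - half_lo, 1L)
  hi <- pmin(seq_len(N) + half_hi, N)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
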