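# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
rms <- function(x) sqrt(mean(x^2))

# Sample moments; kurtosis is the Pearson (non-excess) convention, so a
# Gaussian sample sits near 3, not 0.
#' @keywords internal
#' @noRd
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

#' @keywords internal
#' @noRd
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

# Truncated-normal sampler by rejection; bounds are loose relative to sd in
# every preset, so rejection is cheap and exact.
#' @keywords internal
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Deterministic per-recording seed stream: keeps every derived seed a valid
# 32-bit integer regardless of the user's base seed.
#' @keywords internal
#' @noRd
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}
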