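#' @keywords internal
deg2rad <- function(deg) deg * pi / 180

#' @keywords internal
rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles to [0, 2*pi)
#' @keywords internal
wrap_angle <- function(theta) theta %% (2 * pi)

#' Signed angular difference wrapped to (-pi, pi]
#' @keywords internal
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All randomized routines in the package funnel through this so
# that seeded results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
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
  expr
}

#' Sample skewness (method-of-moments g1)
#' @keywords internal
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

#' Sample excess kurtosis (method-of-moments g2)
#' @keywords internal
kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}
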