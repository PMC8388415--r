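#' Von Mises random deviates
#'
#' Best–Fisher rejection sampler.  `kappa = 0` yields uniform angles and
#' `kappa = Inf` the degenerate point mass at `mu` (used by the
#' zero-spread limit of the data generator).
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @return Angles in radians, wrapped to `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- wrap_angle(mu + sign(u3 - 0.5) * acos(f))
  }
  out
}

#' Von Mises concentration from circular variance
#'
#' Inverts the mean-resultant-length relation `A(kappa) =
#' I1(kappa)/I0(kappa) = 1 - v` numerically.  Used to back-solve the
#' concentration a reported sample circular variance implies.
#'
#' @param v Circular variance in `[0, 1)`.
#' @return Concentration `kappa >= 0` (`Inf` for `v = 0`).
#' @export
vm_kappa_from_var <- function(v) {
  stopifnot(v >= 0, v < 1)
  if (v == 0) return(Inf)
  rbar <- 1 - v
  if (rbar < 1e-12) return(0)
  a1 <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  f <- function(k) a1(k) - rbar
  upper <- 10
  while (f(upper) < 0 && upper < 1e8) upper <- upper * 10
  stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}
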