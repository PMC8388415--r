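#' Circular statistics for opening angles
#'
#' Opening angles are directional data: an angle of 359 degrees is close
#' to 1 degree, so ordinary moments mislead.  These routines work in
#' radians internally (angles are wrapped to `[0, 2*pi)`) and report
#' degrees at the interface.
#'
#' @name circular-stats
NULL

#' Angle sample constructor
#'
#' @param angles Numeric vector of angles.
#' @param degrees Logical; if `TRUE` (default) `angles` are degrees and
#'   are converted to radians internally.
#' @param label Optional text label for the sample.
#' @return Object of class `angle_sample` holding radians wrapped to
#'   `[0, 2*pi)`.
#' @export
angle_sample <- function(angles, degrees = TRUE, label = "") {
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  theta <- if (degrees) deg2rad(angles) else angles
  structure(list(theta = wrap_angle(theta), label = label),
            class = "angle_sample")
}

as_angle_sample <- function(x, degrees = TRUE) {
  if (inherits(x, "angle_sample")) x else angle_sample(x, degrees)
}

# Mean direction and mean resultant length of a radian vector.
circ_resultant <- function(theta) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  list(mean = wrap_angle(atan2(S, C)), rbar = sqrt(C^2 + S^2))
}

# Circular median: direction minimising the mean circular distance
# d(theta, phi) = pi - |pi - |theta - phi||.  Candidates are the data
# points and, for even-n configurations, midpoints of adjacent order
# statistics on the circle; ties are broken towards the mean direction.
circ_median_rad <- function(theta) {
  n <- length(theta)
  sorted <- sort(wrap_angle(theta))
  mids <- wrap_angle(sorted + angle_diff(c(sorted[-1], sorted[1]), sorted) / 2)
  cand <- unique(c(sorted, mids))
  objective <- vapply(cand, function(phi) {
    mean(pi - abs(pi - abs(theta - phi) %% (2 * pi)))
  }, numeric(1))
  best <- cand[objective <= min(objective) + 1e-12]
  if (length(best) > 1) {
    mu <- circ_resultant(theta)$mean
    best <- best[which.min(abs(angle_diff(best, mu)))]
  }
  best[1]
}

#' Circular descriptive statistics
#'
#' Mean and median direction, sample circular variance `v = 1 - Rbar`,
#' and the standardised skewness and kurtosis built from the second
#' trigonometric moment about the mean direction:
#' `s_hat = b2 / (1 - Rbar)^{3/2}` and
#' `k_hat = (a2 - Rbar^4) / (1 - Rbar)^2`, where `a2`/`b2` are the
#' cosine/sine components of the second central trigonometric moment.
#'
#' @param sample An [angle_sample()] or numeric vector of angles.
#' @param degrees Interpretation of a bare numeric vector.
#' @return A one-row data frame: `n`, `theta_bar`, `theta_tilde`, `min`
#'   (degrees), `v`, `k_hat`, `s_hat`, `rbar`.
#' @export
circ_descriptives <- function(sample, degrees = TRUE) {
  s <- as_angle_sample(sample, degrees)
  theta <- s$theta
  if (length(theta) < 2) {
    stop("at least two angles are required", call. = FALSE)
  }
  res <- circ_resultant(theta)
  mu <- res$mean; rbar <- res$rbar
  a2 <- mean(cos(2 * (theta - mu)))
  b2 <- mean(sin(2 * (theta - mu)))
  v <- 1 - rbar
  if (v < 1e-12) {
    s_hat <- 0; k_hat <- 0
  } else {
    s_hat <- b2 / v^1.5
    k_hat <- (a2 - rbar^4) / v^2
  }
  data.frame(
    n = length(theta),
    theta_bar = rad2deg(mu),
    theta_tilde = rad2deg(circ_median_rad(theta)),
    min = rad2deg(min(theta)),
    v = v,
    k_hat = k_hat,
    s_hat = s_hat,
    rbar = rbar
  )
}

#' Rayleigh test of circular uniformity
#'
#' Statistic is the mean resultant length `Rbar`; the p-value uses the
#' standard large-sample series correction of `exp(-n Rbar^2)`.
#'
#' @inheritParams circ_descriptives
#' @return A data frame with `statistic` (Rbar), `p` and `method`.
#' @export
rayleigh_test <- function(sample, degrees = TRUE) {
  s <- as_angle_sample(sample, degrees)
  n <- length(s$theta)
  if (n < 5) stop("Rayleigh test requires n >= 5", call. = FALSE)
  rbar <- circ_resultant(s$theta)$rbar
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  data.frame(statistic = rbar, p = p, method = "rayleigh")
}

#' Robust test of reflective symmetry about the circular median
#'
#' Large-sample z-type test based on the standardised second sine moment
#' about the median direction: under reflective symmetry
#' `b2 = mean(sin 2(theta - median))` has expectation zero.  Its
#' variance is estimated from the higher trigonometric moments about the
#' median (Pewsey-type estimator), giving a two-sided normal p-value.
#'
#' @inheritParams circ_descriptives
#' @return A data frame with `statistic` (|z|), `p` and `method`.
#' @export
symmetry_test <- function(sample, degrees = TRUE) {
  s <- as_angle_sample(sample, degrees)
  theta <- s$theta
  n <- length(theta)
  if (n < 10) stop("symmetry test requires n >= 10", call. = FALSE)
  med <- circ_median_rad(theta)
  d <- theta - med
  b2 <- mean(sin(2 * d))
  a1 <- mean(cos(d)); a2 <- mean(cos(2 * d))
  a3 <- mean(cos(3 * d)); a4 <- mean(cos(4 * d))
  var_b2 <- ((1 - a4) / 2 - 2 * a2^2 +
               (2 * a2 / a1) * (a3 + a2 * (1 - a2) / a1)) / n
  if (!is.finite(var_b2) || var_b2 <= 0) {
    # pathologically concentrated sample: no evidence against symmetry
    return(data.frame(statistic = 0, p = 1, method = "reflective_symmetry"))
  }
  z <- b2 / sqrt(var_b2)
  data.frame(statistic = abs(z), p = 2 * stats::pnorm(-abs(z)),
             method = "reflective_symmetry")
}

# ---- two-sample randomization tests ---------------------------------

# Watson-type common-mean statistic Y_g: squared angular difference of
# the sample mean directions over the summed squared circular standard
# errors (Fisher's large-sample form).
watson_ystat <- function(t1, t2) {
  e1 <- circ_stderr2(t1); e2 <- circ_stderr2(t2)
  d <- angle_diff(circ_resultant(t1)$mean, circ_resultant(t2)$mean)
  d^2 / (e1 + e2)
}

# Squared circular standard error of the mean direction.
circ_stderr2 <- function(theta) {
  n <- length(theta)
  res <- circ_resultant(theta)
  mu <- res$mean; rbar <- res$rbar
  a2 <- mean(cos(2 * (theta - mu)))
  v <- (1 - a2) / (2 * n * rbar^2)
  max(v, 1e-12)
}

# Fisher's common-median statistic P_g computed from the pooled median.
# side: logical vector marking observations in the half-circle
# (median, median + pi); grp: 1/2 group index.
fisher_pstat <- function(side, grp, n1, n2) {
  N <- n1 + n2
  M <- sum(side)
  if (M == 0 || M == N) return(0)
  m1 <- sum(side[grp == 1L]); m2 <- sum(side[grp == 2L])
  N^2 / (M * (N - M)) * (m1^2 / n1 + m2^2 / n2) - N * M / (N - M)
}

# Mardia-Watson-Wheeler uniform-scores statistic W_g from circular
# ranks beta (radians).
mww_wstat <- function(beta, grp, n1, n2) {
  c1 <- sum(cos(beta[grp == 1L])); s1 <- sum(sin(beta[grp == 1L]))
  c2 <- sum(cos(beta[grp == 2L])); s2 <- sum(sin(beta[grp == 2L]))
  2 * ((c1^2 + s1^2) / n1 + (c2^2 + s2^2) / n2)
}

#' Two-sample randomization tests for angular data
#'
#' Three complementary comparisons of two angle samples, each with a
#' resampling p-value `(exceedances + 1) / (reps + 1)`:
#'
#' * `watson_mean`: bootstrap test of a common mean direction.  The
#'   statistic `Y_g` contrasts the two mean directions against their
#'   circular standard errors; its null distribution is estimated by
#'   resampling within groups after centring each at its own mean.
#' * `fisher_median`: randomization test of a common median direction
#'   using Fisher's nonparametric statistic `P_g` (counts on either side
#'   of the pooled median), permuting group labels.
#' * `mww_distribution`: randomization Mardia–Watson–Wheeler uniform-
#'   scores test (`W_g`) for any distributional difference, permuting
#'   group labels.
#'
#' @param a,b [angle_sample()] objects or numeric angle vectors.
#' @param method One of `"watson_mean"`, `"fisher_median"`,
#'   `"mww_distribution"`.
#' @param reps Number of bootstrap/permutation replicates (>= 99).
#' @param seed Integer seed; the result is reproducible for a fixed
#'   seed and does not disturb the caller's RNG.
#' @param degrees Interpretation of bare numeric inputs.
#' @return A data frame with `statistic`, `p`, `method`, `reps`.
#' @export
circ_two_sample <- function(a, b,
                            method = c("watson_mean", "fisher_median",
                                       "mww_distribution"),
                            reps = 9999, seed = NULL, degrees = TRUE) {
  method <- match.arg(method)
  t1 <- as_angle_sample(a, degrees)$theta
  t2 <- as_angle_sample(b, degrees)$theta
  n1 <- length(t1); n2 <- length(t2)
  if (n1 < 8 || n2 < 8) {
    stop("both samples must have n >= 8", call. = FALSE)
  }
  if (reps < 99) stop("reps must be >= 99", call. = FALSE)
  with_seed(seed, {
    if (method == "watson_mean") {
      obs <- watson_ystat(t1, t2)
      c1 <- wrap_angle(t1 - circ_resultant(t1)$mean)
      c2 <- wrap_angle(t2 - circ_resultant(t2)$mean)
      exceed <- 0L
      for (r in seq_len(reps)) {
        b1 <- c1[sample.int(n1, n1, replace = TRUE)]
        b2 <- c2[sample.int(n2, n2, replace = TRUE)]
        if (watson_ystat(b1, b2) >= obs) exceed <- exceed + 1L
      }
      stat <- obs
    } else if (method == "fisher_median") {
      pooled <- c(t1, t2)
      med <- circ_median_rad(pooled)
      side <- angle_diff(pooled, med) > 0
      grp <- rep(1:2, c(n1, n2))
      obs <- fisher_pstat(side, grp, n1, n2)
      exceed <- 0L
      for (r in seq_len(reps)) {
        if (fisher_pstat(side, sample(grp), n1, n2) >= obs) {
          exceed <- exceed + 1L
        }
      }
      stat <- obs
    } else {
      pooled <- c(t1, t2)
      N <- n1 + n2
      rk <- rank(pooled, ties.method = "random")
      beta <- 2 * pi * rk / N
      grp <- rep(1:2, c(n1, n2))
      obs <- mww_wstat(beta, grp, n1, n2)
      exceed <- 0L
      for (r in seq_len(reps)) {
        if (mww_wstat(beta, sample(grp), n1, n2) >= obs) {
          exceed <- exceed + 1L
        }
      }
      stat <- obs
    }
    data.frame(statistic = stat, p = (exceed + 1) / (reps + 1),
               method = method, reps = reps)
  })
}
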