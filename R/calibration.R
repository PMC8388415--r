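#' p-value evidence calibration
#'
#' Tools for re-expressing a frequentist p-value on a Bayesian evidence
#' scale: the Bayes Factor Bound (BFB), the False Positive Risk (FPR)
#' under a stated prior, and a calibrated posterior probability of the
#' null hypothesis, `p_h0()`.  Together these replace the usual
#' "p < 0.05" dichotomy: evidence statements are made on the p(H0)
#' scale, with 0.003 (the third standard deviation from the mean of a
#' Gaussian) as the conventional threshold for strong evidence.
#'
#' All three functions are built on the same quantity
#' \deqn{x(p) = -e \, p \, \log p,}
#' which for `p <= 1/e` is the reciprocal of the maximal Bayes factor in
#' favour of the alternative achievable by any reasonable prior
#' (Sellke–Bayarri–Berger bound).  The branch point of the calibration,
#' `p* = 0.3681`, is the point of maximum curvature of the calibration
#' curve and numerically indistinguishable from 1/e.
#'
#' @name calibration
NULL

# Shared kernel: x(p) = -e p log(p).  Increasing on (0, 1/e), equal to 1
# at p = 1/e, decreasing back to 0 as p -> 1.
calibration_x <- function(p) {
  -exp(1) * p * log(p)
}

check_prob <- function(p, name = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  p
}

#' Bayes Factor Bound of a p-value
#'
#' Upper bound on the Bayes factor in favour of the alternative
#' hypothesis implied by an observed p-value: `1 / (-e p log p)`.
#' For `p > 1/e` the bound saturates at 1 (a p-value that large can
#' never favour the alternative).  The kernel value `x(p)` itself,
#' which is at most 1 and quantifies how strongly the saturated branch
#' supports the null (it is the alternative-odds value behind the
#' `p_h0` calibration), is exposed via the `"evidence_h0"` attribute.
#'
#' @param p p-value(s) in (0, 1).
#' @return Numeric vector of odds (>= 1) in favour of the alternative.
#'   The attribute `"evidence_h0"` carries `x(p) <= 1`; small values
#'   are strong evidence against the null below the branch point, and
#'   strong evidence for it above.
#' @examples
#' bfb(0.01)   # ~7.99
#' bfb(0.082)  # ~1.79
#' @export
bfb <- function(p) {
  check_prob(p)
  x <- calibration_x(p)
  out <- ifelse(p <= exp(-1), 1 / x, 1)
  attr(out, "evidence_h0") <- x
  out
}

#' False Positive Risk of a p-value
#'
#' Probability that a result with the observed p-value is a false
#' positive, given a prior probability that a real effect exists.
#' Posterior odds of a real effect are `bfb(p)` times the prior odds
#' `prior_prob_real / (1 - prior_prob_real)`; the FPR is
#' `1 / (1 + posterior_odds)`.
#'
#' @param p p-value(s) in (0, 1).
#' @param prior_prob_real Prior probability in (0, 1) that the effect is
#'   real.  The default 0.5 ("complete randomness") gives prior odds 1.
#' @return Probabilities in (0, 1).
#' @examples
#' fpr(0.01, 0.5)   # ~0.111
#' fpr(0.01, 0.3)   # ~0.226
#' @export
fpr <- function(p, prior_prob_real = 0.5) {
  check_prob(p)
  check_prob(prior_prob_real, "prior_prob_real")
  prior_odds <- prior_prob_real / (1 - prior_prob_real)
  post <- as.numeric(bfb(p)) * prior_odds
  1 / (1 + post)
}

#' Calibrated posterior probability of the null hypothesis
#'
#' Maps a p-value to a posterior probability of the null on a continuous
#' scale running from 0 (as p -> 0) through 0.5 at p = 1/e to 1
#' (as p -> 1).  With `x = -e p log p`:
#' `p_h0 = x / (1 + x)` for `p <= 0.3681` and `1 / (1 + x)` above it.
#' The lower branch is the FPR under prior probability 0.5; the upper
#' branch mirrors it through the branch point so that large p-values
#' yield genuine evidence in favour of the null.
#'
#' @param p p-value(s) in (0, 1).
#' @param limit Branch point of the calibration curve (its point of
#'   maximum curvature); default 0.3681.
#' @return Probabilities in (0, 1).
#' @examples
#' p_h0(0.009)  # ~0.103
#' p_h0(0.25)   # ~0.485
#' p_h0(0.8)    # ~0.673
#' @export
p_h0 <- function(p, limit = 0.3681) {
  check_prob(p)
  x <- calibration_x(p)
  ifelse(p <= limit, x / (1 + x), 1 / (1 + x))
}

#' Complement of [p_h0()]
#' @inheritParams p_h0
#' @return `1 - p_h0(p)`.
#' @export
p_ha <- function(p, limit = 0.3681) 1 - p_h0(p, limit)

#' Full calibration record for a p-value
#'
#' Bundles every calibrated quantity for one or more p-values: BFB,
#' prior and posterior odds, FPR and p(H0)/p(Ha).  Used to decorate all
#' test results produced by the pipeline.
#'
#' @inheritParams fpr
#' @return A data frame with columns `p`, `bfb`, `prior_odds`,
#'   `posterior_odds`, `fpr`, `p_h0`, `p_ha`.
#' @export
calibrate <- function(p, prior_prob_real = 0.5) {
  check_prob(p)
  b <- as.numeric(bfb(p))
  prior_odds <- prior_prob_real / (1 - prior_prob_real)
  data.frame(
    p = p,
    bfb = b,
    prior_odds = prior_odds,
    posterior_odds = b * prior_odds,
    fpr = fpr(p, prior_prob_real),
    p_h0 = p_h0(p),
    p_ha = p_ha(p)
  )
}

# Attach calibration columns (bfb, fpr, p_h0) to a data frame holding a
# p-value column.  p-values of exactly 0/1 (possible only through
# rounding elsewhere) are nudged inside the open interval.
calibrate_columns <- function(df, p_col = "p", prior_prob_real = 0.5) {
  p <- pmin(pmax(df[[p_col]], .Machine$double.xmin), 1 - 1e-16)
  cal <- calibrate(p, prior_prob_real)
  df$bfb <- cal$bfb
  df$fpr <- cal$fpr
  df$p_h0 <- cal$p_h0
  df
}
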