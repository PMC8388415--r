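#' Shapiro-Wilk gate for distributional homogeneity
#'
#' The analysis chooses between parametric and robust branches per
#' variable with a Shapiro-Wilk test evaluated against the
#' third-standard-deviation evidence threshold 0.003 (rather than the
#' conventional 0.05).
#'
#' @param x Numeric vector (3 <= n <= 5000).
#' @return A data frame with `statistic` (W), `p`, `method`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("constant sample: normality is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  data.frame(statistic = unname(sw$statistic), p = sw$p.value,
             method = "shapiro_wilk")
}

#' Biweight midvariance
#'
#' Outlier-resistant variance estimator: deviations are standardised by
#' 9 * MAD (tuning constant 9 on the unscaled median absolute
#' deviation) and observations beyond that band receive zero weight:
#' \deqn{BWMV = n \sum_{|u_i|<1} (x_i-M)^2 (1-u_i^2)^4 \Big/
#'       \Big(\sum_{|u_i|<1} (1-u_i^2)(1-5u_i^2)\Big)^2.}
#' Its square root replaces the standard deviation for non-Gaussian
#' samples.
#'
#' @param x Numeric vector.
#' @return The biweight midvariance (a variance, not an SD).
#' @export
bwmv <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("bwmv requires n >= 2", call. = FALSE)
  M <- stats::median(x)
  mad_raw <- stats::median(abs(x - M))
  if (mad_raw == 0) return(0)
  u <- (x - M) / (9 * mad_raw)
  w <- abs(u) < 1
  num <- n * sum(((x - M)^2 * (1 - u^2)^4)[w])
  den <- sum(((1 - u^2) * (1 - 5 * u^2))[w])^2
  num / den
}

#' Univariate descriptives, classical or robust
#'
#' Classical mode reports mean and standard deviation; robust mode the
#' median and the square root of the biweight midvariance ([bwmv()]).
#'
#' @param x Numeric vector of measurements (mm).
#' @param robust Logical: use the robust branch?
#' @return One-row data frame: `n`, `min`, `central`, `deviation`,
#'   `max`, `robust`.
#' @export
describe <- function(x, robust = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("describe requires n >= 2", call. = FALSE)
  data.frame(
    n = length(x),
    min = min(x),
    central = if (robust) stats::median(x) else mean(x),
    deviation = if (robust) sqrt(bwmv(x)) else stats::sd(x),
    max = max(x),
    robust = robust
  )
}

# Trimmed-sample helpers for Yuen's statistic.
winsorize <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  lo <- xs[g + 1]; hi <- xs[n - g]
  pmin(pmax(x, lo), hi)
}

yuen_parts <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  h <- n - 2 * g
  if (h < 2) stop("sample too small after trimming", call. = FALSE)
  list(tm = mean(x, trim = trim),
       swv = stats::var(winsorize(x, trim)),
       h = h, n = n)
}

#' Equivalence test (TOST) with Welch or Yuen statistics
#'
#' Two one-sided tests of the null hypothesis that the groups *differ*
#' by at least `epsilon` standardised units against the alternative
#' that they are equivalent (`|diff| < epsilon * scale`).  A *small*
#' p-value is therefore evidence of equivalence.  The parametric branch
#' uses Welch's t statistic on means; the robust branch (`"yuen"`) uses
#' Yuen's trimmed t with winsorized variances.  `epsilon` is expressed
#' in Cohen's d units: the margin is `epsilon` times the pooled scale
#' (ordinary pooled SD, or pooled winsorized SD for Yuen).
#'
#' @param x,y Numeric samples (both n >= 5).
#' @param epsilon Equivalence bound in d units (> 0); default 0.2.
#' @param method `"welch"` or `"yuen"`.
#' @param trim Trimming proportion for Yuen (default 0.2).
#' @return One-row data frame: `d` (absolute standardised difference),
#'   `p` (max of the two one-sided p-values), `method`, `epsilon`,
#'   `df`, `diff`, and the component one-sided p-values `p_lower`
#'   (against "difference <= -margin") and `p_upper` (against
#'   "difference >= +margin").
#' @export
tost <- function(x, y, epsilon = 0.2, method = c("welch", "yuen"),
                 trim = 0.2) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 5 || length(y) < 5) {
    stop("both samples must have n >= 5", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  if (method == "welch") {
    nx <- length(x); ny <- length(y)
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx + vy == 0) stop("degenerate variance", call. = FALSE)
    se <- sqrt(vx / nx + vy / ny)
    df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    scale <- sqrt((vx + vy) / 2)
    diff <- mean(x) - mean(y)
  } else {
    px <- yuen_parts(x, trim); py <- yuen_parts(y, trim)
    dx <- (px$n - 1) * px$swv / (px$h * (px$h - 1))
    dy <- (py$n - 1) * py$swv / (py$h * (py$h - 1))
    if (px$swv + py$swv == 0) stop("degenerate variance", call. = FALSE)
    se <- sqrt(dx + dy)
    df <- (dx + dy)^2 / (dx^2 / (px$h - 1) + dy^2 / (py$h - 1))
    scale <- sqrt((px$swv + py$swv) / 2)
    diff <- px$tm - py$tm
  }
  margin <- epsilon * scale
  t_lower <- (diff + margin) / se # H0: diff <= -margin
  t_upper <- (diff - margin) / se # H0: diff >= +margin
  p1 <- stats::pt(t_lower, df, lower.tail = FALSE)
  p2 <- stats::pt(t_upper, df, lower.tail = TRUE)
  data.frame(d = abs(diff) / scale, p = max(p1, p2), method = method,
             epsilon = epsilon, df = df, diff = diff,
             p_lower = p1, p_upper = p2)
}

#' Correlation test, parametric or rank-based
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @param method `"pearson"` or `"kendall"`.
#' @return One-row data frame: `statistic` (the coefficient), `p`,
#'   `method`.
#' @export
correlation <- function(x, y, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 5) stop("n >= 5 required", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  data.frame(statistic = unname(ct$estimate), p = ct$p.value,
             method = method)
}

#' Multivariate equivalence across retained principal components
#'
#' Applies [tost()] per principal component retained to explain up to
#' `var_target` of total variance, and aggregates as the PC-wise
#' maximum p-value and the summed absolute standardised differences.
#' The aggregation rule (max p, summed |d|) is a package convention.
#'
#' @param scores Matrix of PC scores (rows = specimens, ordered
#'   columns).
#' @param var_frac Variance fraction per component.
#' @param groups Two-level factor/character vector over rows.
#' @param var_target Cumulative variance cut-off (default 0.95).
#' @inheritParams tost
#' @return A list with `per_pc` (data frame of PC-wise results), `d`
#'   (summed |d|), `p` (max p), `n_pc`.
#' @export
multivariate_tost <- function(scores, var_frac, groups, var_target = 0.95,
                              epsilon = 0.2, method = "yuen", trim = 0.2) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, nrow(scores) == length(groups))
  keep <- seq_len(max(1, which(cumsum(var_frac) >= var_target)[1]))
  lv <- levels(groups)
  per <- do.call(rbind, lapply(keep, function(j) {
    r <- tost(scores[groups == lv[1], j], scores[groups == lv[2], j],
              epsilon = epsilon, method = method, trim = trim)
    cbind(pc = j, var_frac = var_frac[j], r)
  }))
  list(per_pc = per, d = sum(per$d), p = max(per$p), n_pc = length(keep))
}
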