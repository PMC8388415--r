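#' Permutation test for allometry (shape-size regression)
#'
#' Multivariate regression of tangent-space shape coordinates on a size
#' covariate (typically log centroid size, or a stress proxy), with a
#' Goodall-type F statistic built from sums of squared Procrustes
#' residuals and a residual-randomization permutation p-value.  When
#' `groups` is supplied the statistic tests the covariate x group
#' interaction (different shape-size slopes between groups) on top of
#' the common covariate + group model.
#'
#' Residual diagnostics (Shapiro-Wilk W and p, |skewness| and excess
#' |kurtosis| of the residual Procrustes distances) are reported
#' because heavy-tailed residuals inflate parametric allometry tests.
#'
#' @param aligned An `aligned_set` from [gpa()].
#' @param covariate Numeric covariate, one value per specimen.  If
#'   `NULL`, `log(centroid_sizes)` of the aligned set is used.
#' @param groups Optional group labels (enables the interaction test).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutations.
#' @return List of class `allometry_result`: `F`, `p`, `df`, `slope`
#'   (matrix, one row per covariate column, reshaped k x d per
#'   dimension), `slope_vector`, `r_squared`, `residual_diagnostics`
#'   (list: `W`, `p`, `skew`, `kurtosis`), `n_perm`, `interaction`.
#' @export
allometry_test <- function(aligned, covariate = NULL, groups = NULL,
                           n_perm = 999, seed = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  y <- aligned$tangent
  n <- nrow(y)
  if (is.null(covariate)) covariate <- log(aligned$centroid_sizes)
  if (length(covariate) != n) {
    stop("covariate length must match the number of specimens",
         call. = FALSE)
  }
  if (stats::sd(covariate) < .Machine$double.eps) {
    stop("constant covariate", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)

  yc <- sweep(y, 2, colMeans(y))
  if (is.null(groups)) {
    x_red <- matrix(1, n, 1)
    x_full <- cbind(1, covariate)
    df_eff <- 1
  } else {
    groups <- as.factor(groups)
    x_red <- stats::model.matrix(~ covariate + groups)
    x_full <- stats::model.matrix(~ covariate * groups)
    df_eff <- ncol(x_full) - ncol(x_red)
  }
  df_res <- n - ncol(x_full)

  fit_ss <- function(X, Y) {
    # residual sum of squares over all shape coordinates
    Q <- qr(X)
    res <- stats::lm.fit(X, Y)$residuals
    list(ss = sum(res^2), resid = res, qr = Q)
  }
  red <- fit_ss(x_red, yc)
  full <- fit_ss(x_full, yc)
  ss_eff <- red$ss - full$ss
  f_obs <- (ss_eff / df_eff) / (full$ss / df_res)

  # residual randomization: permute rows of the reduced-model residuals
  fitted_red <- yc - red$resid
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      y_star <- fitted_red + red$resid[sample.int(n), , drop = FALSE]
      ss_red_s <- sum(stats::lm.fit(x_red, y_star)$residuals^2)
      ss_full_s <- sum(stats::lm.fit(x_full, y_star)$residuals^2)
      ((ss_red_s - ss_full_s) / df_eff) / (ss_full_s / df_res)
    }, numeric(1))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)

  coefs <- qr.coef(qr(x_full), yc)
  slope_row <- if (is.null(groups)) 2L else 2L
  slope_vec <- coefs[slope_row, ]

  rd <- sqrt(rowSums(full$resid^2)) # residual Procrustes distances
  sw <- tryCatch(stats::shapiro.test(rd),
                 error = function(e) list(statistic = NA, p.value = NA))
  diagnostics <- list(W = unname(sw$statistic), p = sw$p.value,
                      skew = abs(skewness(rd)), kurtosis = abs(kurtosis(rd)))

  structure(
    list(F = f_obs, p = p, df = c(effect = df_eff, residual = df_res),
         slope = slope_vec, slope_vector = slope_vec,
         r_squared = 1 - full$ss / sum(yc^2),
         residual_diagnostics = diagnostics,
         n_perm = n_perm, interaction = !is.null(groups)),
    class = "allometry_result"
  )
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("<allometry_result> F = %.3f, p = %.4g (%d permutations)%s\n",
              x$F, x$p, x$n_perm,
              if (x$interaction) ", covariate x group interaction" else ""))
  invisible(x)
}

#' Captivity-stress covariate
#'
#' Scalar stress proxy per specimen: the number of individuals kept in
#' an enclosure divided by the enclosure area (individuals per square
#' metre), mapped over a vector of park labels.  Parks without stress
#' information (wild populations) receive 0.
#'
#' @param parks Character vector of park labels.
#' @param table Named numeric vector mapping park to stress; defaults
#'   to the two captive parks of the study conditions: Cabarceno 7
#'   wolves in 2700 m2, Hosquillo 5 wolves in 10000 m2.
#' @return Numeric vector.
#' @export
stress_covariate <- function(parks,
                             table = c(Cabarceno = 7 / 2700,
                                       Hosquillo = 5 / 10000)) {
  out <- unname(table[parks])
  out[is.na(out)] <- 0
  out
}
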