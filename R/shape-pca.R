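#' PCA of Procrustes-aligned shapes
#'
#' Centred principal component decomposition of the flattened
#' tangent-space coordinates of an [gpa()] result.
#'
#' @param aligned An `aligned_set` from [gpa()].
#' @return Object of class `pca_result`: `scores` (n x q),
#'   `var_frac`, `loadings` (columns orthonormal), `center`, `sdev`.
#' @export
pca_shapes <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  x <- aligned$tangent
  if (nrow(x) < 3) stop("PCA requires at least 3 specimens", call. = FALSE)
  pca_matrix(x)
}

pca_matrix <- function(x, center = TRUE, scale. = FALSE) {
  pr <- stats::prcomp(x, center = center, scale. = scale.)
  v <- pr$sdev^2
  total <- sum(v)
  structure(
    list(scores = pr$x, var_frac = if (total > 0) v / total else v * 0,
         loadings = pr$rotation, center = pr$center, scale = pr$scale,
         sdev = pr$sdev, total_var = total),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d x %d; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$var_frac[1],
              100 * ifelse(length(x$var_frac) > 1, x$var_frac[2], 0)))
  invisible(x)
}

#' Linearisation of an opening angle
#'
#' Maps an angle in degrees to `cos(theta) + sin(theta)` (theta in
#' radians), the transformation used to combine the opening angle with
#' the six linear measurements before PCA.
#'
#' @param oa Opening angle(s) in degrees, in (0, 180].
#' @return Numeric vector.
#' @export
oa_to_linear <- function(oa) {
  if (any(!is.finite(oa)) || any(oa <= 0) || any(oa > 180)) {
    stop("opening angles must lie in (0, 180] degrees", call. = FALSE)
  }
  theta <- deg2rad(oa)
  cos(theta) + sin(theta)
}

#' PCA of the seven tooth-score measurements
#'
#' The opening angle column `OA` is first linearised with
#' [oa_to_linear()]; PCA then runs on the covariance of the seven
#' columns (`standardize = TRUE` switches to the correlation matrix).
#'
#' @param metrics Data frame containing columns `WIS`, `WIM`, `WIB`,
#'   `D`, `LDC`, `RDC`, `OA` with no missing values.
#' @param standardize Use unit-variance scaling? Default `FALSE`
#'   (covariance PCA).
#' @return A `pca_result`.
#' @export
metric_pca <- function(metrics, standardize = FALSE) {
  need <- c("WIS", "WIM", "WIB", "D", "LDC", "RDC", "OA")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("metrics table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- metrics[, need]
  if (anyNA(m)) stop("missing values in metrics table", call. = FALSE)
  m$OA <- oa_to_linear(m$OA)
  x <- as.matrix(m)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps)) {
    stop("zero total variance: all rows identical", call. = FALSE)
  }
  pca_matrix(x, scale. = standardize)
}
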