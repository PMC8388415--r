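#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to
#' their centroid; the size measure used in allometric regression.
#'
#' @param x Landmark matrix (k x d).
#' @return Centroid size (mm).
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

# Optimal rotation (no reflection) aligning X onto M in the
# least-squares sense: R = U V' from the SVD of X'M, with the last
# singular direction flipped if det < 0.  Marks have consistent
# handedness from the digitisation protocol, so improper rotations are
# never allowed.
optimal_rotation <- function(x, m) {
  sv <- svd(crossprod(x, m))
  u <- sv$u; v <- sv$v
  if (det(u %*% t(v)) < 0) {
    u[, ncol(u)] <- -u[, ncol(u)]
  }
  u %*% t(v)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a set of landmark configurations:
#' translation to a common centroid, optional scaling to unit centroid
#' size (`scale = TRUE`, shape space; `scale = FALSE` retains size,
#' form space), and rotation of every configuration onto the evolving
#' mean shape until the mean changes by less than `tol`.  Aligned
#' configurations are finally projected orthogonally onto the tangent
#' space at the mean shape; the projected, flattened coordinates (used
#' by [pca_shapes()] and [allometry_test()]) are returned alongside the
#' aligned configurations themselves.
#'
#' @param dataset A [landmark_dataset()], or a k x d x n array.
#' @param scale Scale configurations to unit centroid size?
#' @param tol Convergence tolerance on the change of the mean shape
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `aligned_set`: list with `aligned`
#'   (k x d x n array), `tangent` (n x (k*d) matrix of tangent-space
#'   coordinates), `mean_shape` (k x d), `centroid_sizes`, `scaled`,
#'   `iterations`, `metadata`.
#' @export
gpa <- function(dataset, scale = TRUE, tol = 1e-8, max_iter = 100) {
  if (inherits(dataset, "landmark_dataset")) {
    arr <- as_landmark_array(dataset)
    metadata <- dataset$metadata
  } else {
    arr <- dataset
    metadata <- NULL
  }
  stopifnot(length(dim(arr)) == 3)
  k <- dim(arr)[1]; d <- dim(arr)[2]; n <- dim(arr)[3]
  if (n < 2) stop("GPA requires at least two configurations", call. = FALSE)

  cs <- apply(arr, 3, centroid_size)
  if (any(cs < .Machine$double.eps)) {
    stop("degenerate configuration with zero centroid size", call. = FALSE)
  }

  # centre (and optionally scale) every configuration
  conf <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    x <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    conf[, , i] <- if (scale) x / cs[i] else x
  }

  mean_shape <- conf[, , 1]
  iter <- 0
  repeat {
    iter <- iter + 1
    for (i in seq_len(n)) {
      conf[, , i] <- conf[, , i] %*% optimal_rotation(conf[, , i], mean_shape)
    }
    new_mean <- apply(conf, c(1, 2), mean)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    if (scale) new_mean <- new_mean / centroid_size(new_mean)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iter >= max_iter) break
  }

  # orthogonal projection onto the tangent space at the mean:
  # residuals from the mean are stripped of their component along the
  # normalised mean vector.
  flat <- t(apply(conf, 3, as.vector))     # n x (k*d)
  mvec <- as.vector(mean_shape)
  mhat <- mvec / sqrt(sum(mvec^2))
  resid <- sweep(flat, 2, mvec)
  tangent <- resid - (resid %*% mhat) %*% t(mhat)
  tangent <- sweep(tangent, 2, -mvec)      # add mean back for interpretability

  structure(
    list(aligned = conf, tangent = tangent, mean_shape = mean_shape,
         centroid_sizes = cs, scaled = scale, iterations = iter,
         metadata = metadata),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d configs, %d landmarks, %dD, %s space (%d iters)\n",
              dim(x$aligned)[3], dim(x$aligned)[1], dim(x$aligned)[2],
              if (x$scaled) "shape" else "form", x$iterations))
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size;
#' the full Procrustes distance is `sqrt(1 - s^2)` where `s` is the sum
#' of singular values of the cross-covariance (reflections not
#' allowed).
#'
#' @param x,y Landmark matrices of matching dimension.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(x, y) {
  cx <- sweep(as.matrix(x), 2, colMeans(x)); cx <- cx / sqrt(sum(cx^2))
  cy <- sweep(as.matrix(y), 2, colMeans(y)); cy <- cy / sqrt(sum(cy^2))
  sv <- svd(crossprod(cx, cy))
  s <- sv$d
  if (det(sv$u %*% t(sv$v)) < 0) s[length(s)] <- -s[length(s)]
  sqrt(max(0, 1 - sum(s)^2))
}
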