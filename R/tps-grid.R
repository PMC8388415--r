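#' Thin-plate-spline deformation grid
#'
#' Two-dimensional thin-plate spline interpolant mapping a reference
#' landmark configuration exactly onto a target, evaluated over a
#' regular grid spanning the reference (with a margin), for
#' transformation-grid visualisation.  The kernel is
#' `U(r) = r^2 log(r^2)`; the affine part absorbs translation, rotation
#' and shear, so the reported bending energy is zero exactly when the
#' target is an affine transform of the reference.
#'
#' @param reference k x 2 landmark matrix (typically a mean shape).
#' @param target k x 2 landmark matrix.
#' @param grid Number of grid nodes per axis (default 20).
#' @param margin Fractional margin around the reference bounding box.
#' @return List of class `tps_grid`: `grid` (original node positions),
#'   `warped` (mapped node positions), `bending_energy`, `map`
#'   (function mapping an m x 2 matrix through the spline).
#' @export
tps_grid <- function(reference, target, grid = 20, margin = 0.15) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!all(dim(reference) == dim(target)) || ncol(reference) != 2) {
    stop("reference and target must be matching k x 2 matrices",
         call. = FALSE)
  }
  k <- nrow(reference)
  if (k < 3) stop("at least 3 landmarks required", call. = FALSE)

  U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))
  pd2 <- function(a, b) {
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  }
  K <- U(pmax(pd2(reference, reference), 0))
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  if (qr(L)$rank < k + 3) {
    stop("degenerate (collinear) reference configuration", call. = FALSE)
  }
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[(k + 1):(k + 3), , drop = FALSE]

  map <- function(pts) {
    pts <- as.matrix(pts)
    Up <- U(pmax(pd2(pts, reference), 0))
    cbind(1, pts) %*% A + Up %*% W
  }

  be <- sum(diag(t(W) %*% K %*% W))

  rng <- apply(reference, 2, range)
  pad <- margin * (rng[2, ] - rng[1, ])
  xs <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = grid)
  ys <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = grid)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))

  structure(
    list(grid = nodes, warped = map(nodes), bending_energy = max(0, be),
         map = map),
    class = "tps_grid"
  )
}

#' @export
print.tps_grid <- function(x, ...) {
  cat(sprintf("<tps_grid> %d nodes, bending energy %.4g\n",
              nrow(x$grid), x$bending_energy))
  invisible(x)
}
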