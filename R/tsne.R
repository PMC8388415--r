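#' t-SNE embedding into three dimensions
#'
#' Exact (non-approximate) t-distributed stochastic neighbour embedding
#' of a feature matrix into R^3, trained for 500 iterations with random
#' initialisation, following the original gradient-descent recipe
#' (early exaggeration for the first 100 iterations, momentum switching
#' from 0.5 to 0.8 at iteration 250, adaptive per-parameter gains).
#' The perplexity defaults to the ceiling of the square root of the
#' sample size.
#'
#' @param features Numeric matrix, one row per specimen (n >= 10).
#' @param seed Integer seed for the random initialisation.
#' @param perplexity Perplexity; default `ceiling(sqrt(n))`.
#' @param n_iter Gradient-descent iterations (default 500).
#' @param dims Output dimensionality (default 3).
#' @return n x `dims` matrix of embedding coordinates.
#' @export
tsne_embed <- function(features, seed = NULL, perplexity = NULL,
                       n_iter = 500, dims = 3) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 10) stop("t-SNE requires n >= 10", call. = FALSE)
  if (is.null(perplexity)) perplexity <- ceiling(sqrt(n))
  if (n < 3 * perplexity) {
    stop(sprintf(paste0("n = %d is too small for perplexity %d ",
                        "(need n >= 3 * perplexity); pass a smaller ",
                        "`perplexity` explicitly"), n, perplexity),
         call. = FALSE)
  }

  P <- tsne_affinities(x, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    exaggeration <- 4
    for (iter in seq_len(n_iter)) {
      Pe <- if (iter <= 100) P * exaggeration else P
      d2 <- outer(rowSums(y^2), rowSums(y^2), "+") - 2 * y %*% t(y)
      num <- 1 / (1 + pmax(d2, 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      stiff <- 4 * (Pe - Q) * num
      grad <- (diag(rowSums(stiff)) - stiff) %*% y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      momentum <- if (iter < 250) 0.5 else 0.8
      inc <- momentum * inc - 100 * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    dimnames(y) <- list(rownames(x), paste0("tsne", seq_len(dims)))
    y
  })
}

# Conditional input affinities with per-point precision chosen by
# binary search to match log(perplexity) entropy.
tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
  d2 <- pmax(d2, 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        H <- 0; p <- w
      } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      err <- H - target
      if (abs(err) < tol) break
      if (err > 0) { # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
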