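# Independent oracles used by the unit tests.  These deliberately
# re-derive quantities from first principles (brute force, enumeration,
# closed forms) rather than calling the package's own code paths.

# Arc-length point placement by cumulative segment summation.
oracle_arclength_point <- function(poly, frac) {
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  s <- frac * sum(len)
  cum <- c(0, cumsum(len))
  j <- max(which(cum <= s + 1e-15))
  j <- min(j, nrow(poly) - 1)
  w <- (s - cum[j]) / len[j]
  poly[j, ] + w * seg[j, ]
}

# Coordinate-geometry oracle for the seven score measurements.
oracle_score_metrics <- function(lm) {
  dist <- function(i, j) sqrt(sum((lm[i, ] - lm[j, ])^2))
  u <- lm[1, ] - lm[4, ]; v <- lm[7, ] - lm[4, ]
  # area formula: depth = 2 * triangle area / base
  area <- abs((lm[7, 1] - lm[1, 1]) * (lm[4, 2] - lm[1, 2]) -
                (lm[4, 1] - lm[1, 1]) * (lm[7, 2] - lm[1, 2])) / 2
  c(WIS = dist(1, 7), WIM = dist(2, 6), WIB = dist(3, 5),
    D = 2 * area / dist(1, 7), LDC = dist(1, 4), RDC = dist(7, 4),
    OA = acos(sum(u * v) / (dist(1, 4) * dist(7, 4))) * 180 / pi)
}

# Brute-force biweight midvariance from its defining weighted sums.
oracle_bwmv <- function(x) {
  n <- length(x)
  M <- median(x)
  u <- (x - M) / (9 * median(abs(x - M)))
  a <- as.numeric(abs(u) < 1)
  num <- n * sum(a * (x - M)^2 * (1 - u^2)^4)
  den <- (sum(a * (1 - u^2) * (1 - 5 * u^2)))^2
  num / den
}

# Exact enumeration of the Mardia-Watson-Wheeler permutation null for
# two tiny samples (uses circular ranks of the pooled data).
oracle_mww_exact_p <- function(t1, t2) {
  n1 <- length(t1); n2 <- length(t2); N <- n1 + n2
  beta <- 2 * pi * rank(c(t1, t2)) / N
  wstat <- function(idx1) {
    idx2 <- setdiff(seq_len(N), idx1)
    c1 <- sum(cos(beta[idx1])); s1 <- sum(sin(beta[idx1]))
    c2 <- sum(cos(beta[idx2])); s2 <- sum(sin(beta[idx2]))
    2 * ((c1^2 + s1^2) / n1 + (c2^2 + s2^2) / n2)
  }
  obs <- wstat(seq_len(n1))
  combos <- combn(N, n1)
  stats <- apply(combos, 2, wstat)
  mean(stats >= obs - 1e-12)
}

# Closed-form ordinary Procrustes distance between two centred,
# unit-size configurations via the cross-covariance SVD (no
# reflection).
oracle_opa_distance <- function(x, y) {
  cx <- scale(x, scale = FALSE); cx <- cx / sqrt(sum(cx^2))
  cy <- scale(y, scale = FALSE); cy <- cy / sqrt(sum(cy^2))
  sv <- svd(t(cx) %*% cy)
  s <- sv$d
  if (det(sv$u) * det(sv$v) < 0) s[length(s)] <- -s[length(s)]
  sqrt(max(0, 1 - sum(s)^2))
}

# Mean silhouette width of an embedding with respect to known labels.
oracle_silhouette <- function(y, labels) {
  d <- as.matrix(dist(y))
  n <- nrow(y)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small synthetic morphologika fixture written through plain text (not
# via the package writer), with known counts and valid pit geometry
# (the 30-landmark layout: 5 fixed points then a 5 x 5 patch).
write_fixture_morphologika <- function(path, n_ind = 3, seed = 42) {
  set.seed(seed)
  lines <- c("[individuals]", n_ind, "[landmarks]", 30,
             "[dimensions]", 3, "[names]",
             sprintf("spec%d", seq_len(n_ind)), "[rawpoints]")
  coords <- list()
  for (i in seq_len(n_ind)) {
    lines <- c(lines, sprintf("' spec%d", i))
    fixed <- rbind(c(1.2, 0, 0), c(-0.9, 0, 0), c(0, 0.7, 0),
                   c(0, -0.7, 0), c(0, 0, -0.4))
    patch <- as.matrix(expand.grid(x = seq(-0.6, 0.9, length.out = 5),
                                   y = seq(0.5, -0.5, length.out = 5)))
    m <- rbind(fixed, cbind(patch, -0.2)) +
      matrix(round(rnorm(90, sd = 0.01), 6), 30, 3)
    m <- round(m, 6)
    dimnames(m) <- NULL
    coords[[i]] <- m
    lines <- c(lines, apply(m, 1, paste, collapse = " "))
  }
  writeLines(lines, path)
  coords
}

# A straight-walled V profile with the base at lateral position `a`.
make_v_profile <- function(w = 1, d = 0.5, a = w / 2) {
  toothmarks::compute_wall_landmarks(
    rbind(c(0, 0), c(a, -d), c(w, 0)), c(1, 2, 3)
  )
}
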