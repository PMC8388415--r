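# GPA, shape PCA, allometry, TPS grids and the mixed-metric PCA.

make_random_copies <- function(base, n, scale = TRUE, seed = 1) {
  set.seed(seed)
  k <- nrow(base)
  arr <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s <- if (scale) runif(1, 0.4, 2.5) else 1
    arr[, , i] <- (base * s) %*% R + matrix(runif(2, -5, 5), k, 2,
                                            byrow = TRUE)
  }
  arr
}

test_that("GPA aligns transformed copies of one shape exactly", {
  base <- rbind(c(0, 0), c(1, 0), c(1.2, 0.8), c(0.4, 1.1), c(-0.3, 0.5))
  arr <- make_random_copies(base, 8, scale = TRUE, seed = 41)
  g <- gpa(arr, scale = TRUE)
  dists <- combn(8, 2, function(ij) {
    procrustes_distance(g$aligned[, , ij[1]], g$aligned[, , ij[2]])
  })
  expect_lt(max(dists), 1e-6)

  # form space: rigid copies only (no size change)
  arr2 <- make_random_copies(base, 6, scale = FALSE, seed = 42)
  g2 <- gpa(arr2, scale = FALSE)
  dists2 <- combn(6, 2, function(ij) {
    sqrt(sum((g2$aligned[, , ij[1]] - g2$aligned[, , ij[2]])^2))
  })
  expect_lt(max(dists2), 1e-6)
})

test_that("centroid size of the unit square is sqrt(2)", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
})

test_that("aligned sets satisfy their invariants", {
  set.seed(43)
  sp <- group_spec("t", 20, 140, 30, 0.5, 0.2, 0.08, 0.04, seed = 44)
  g <- gpa(simulate_scores(sp), scale = TRUE)
  # unit centroid size when scaled
  cs <- apply(g$aligned, 3, centroid_size)
  expect_lt(max(abs(cs - 1)), 1e-8)
  # mean shape centred at the origin
  expect_lt(max(abs(colMeans(g$mean_shape))), 1e-10)
})

test_that("GPA result is invariant to pre-transforming the input set", {
  set.seed(45)
  sp <- group_spec("t", 12, 135, 25, 0.5, 0.15, 0.09, 0.04, seed = 46)
  arr <- as_landmark_array(simulate_scores(sp))
  g1 <- gpa(arr, scale = TRUE)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  arr2 <- arr
  for (i in seq_len(dim(arr)[3])) {
    arr2[, , i] <- (arr[, , i] %*% R) * 1.7 + matrix(c(3, -2), 7, 2,
                                                     byrow = TRUE)
  }
  g2 <- gpa(arr2, scale = TRUE)
  for (i in seq_len(dim(arr)[3])) {
    expect_lt(procrustes_distance(g1$aligned[, , i], g2$aligned[, , i]),
              1e-6)
  }
})

test_that("two-configuration distances match the closed-form OPA oracle", {
  t1 <- rbind(c(0, 0), c(2, 0), c(0.6, 1.4))
  t2 <- rbind(c(0, 0), c(1.6, 0.3), c(1.1, 1.8))
  expect_equal(procrustes_distance(t1, t2), oracle_opa_distance(t1, t2),
               tolerance = 1e-10)
  # and against vegan's two-matrix Procrustes (symmetric, no size)
  skip_if_not_installed("vegan")
  pv <- vegan::procrustes(t1, t2, symmetric = TRUE)
  # vegan allows reflection; for these triangles the proper rotation is
  # optimal, so the criteria agree: ss = full Procrustes distance^2
  expect_equal(sqrt(pv$ss), procrustes_distance(t1, t2), tolerance = 1e-6)
})

test_that("shape PCA is lossless and conserves Procrustes variance", {
  set.seed(47)
  sp <- group_spec("t", 25, 140, 30, 0.5, 0.2, 0.08, 0.04, seed = 48)
  g <- gpa(simulate_scores(sp))
  p <- pca_shapes(g)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-9)
  expect_true(all(diff(p$sdev) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # reconstruction
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2, p$center, "+")
  expect_equal(rec, g$tangent, tolerance = 1e-9, ignore_attr = TRUE)
  # conservation: total PCA variance = mean squared deviation from mean
  expect_equal(p$total_var * (nrow(g$tangent) - 1),
               sum(sweep(g$tangent, 2, colMeans(g$tangent))^2),
               tolerance = 1e-9)
})

test_that("variance confined to one coordinate loads one component", {
  set.seed(49)
  base <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  arr <- array(rep(base, 30), c(4, 2, 30))
  arr[2, 1, ] <- arr[2, 1, ] + rnorm(30, sd = 0.1)
  # bypass alignment: feed tangent coordinates directly through PCA of
  # the raw flattened data
  flat <- t(apply(arr, 3, as.vector))
  pr <- prcomp(flat)
  expect_gt(pr$sdev[1]^2 / sum(pr$sdev^2), 0.999)
})

test_that("allometry test recovers a built-in slope and its direction", {
  sp <- group_spec("t", 100, 140, 30, 2.0, 0.6, 0.35, 0.15,
                   allometry_slope = 0.3, seed = 50)
  g <- gpa(simulate_pits(sp), scale = TRUE)
  a <- allometry_test(g, n_perm = 199, seed = 51)
  expect_lte(a$p, 0.01)
  # cosine similarity of the fitted slope with the generating
  # direction; superimposition re-centres every configuration, so the
  # comparable direction is the injected field with its per-coordinate
  # (translation) component removed
  u <- sweep(pit_allometry_direction(), 2,
             colMeans(pit_allometry_direction()))
  u <- as.vector(u) / sqrt(sum(u^2))
  cossim <- abs(sum(a$slope_vector * u)) / sqrt(sum(a$slope_vector^2))
  expect_gt(cossim, 0.9)
})

test_that("allometry test is deterministic under a fixed seed", {
  sp <- group_spec("t", 30, 140, 30, 2.0, 0.6, 0.35, 0.15, seed = 52)
  g <- gpa(simulate_pits(sp), scale = TRUE)
  a1 <- allometry_test(g, n_perm = 199, seed = 53)
  a2 <- allometry_test(g, n_perm = 199, seed = 53)
  expect_identical(a1$F, a2$F)
  expect_identical(a1$p, a2$p)
  expect_error(allometry_test(g, covariate = rep(1, 30)), "constant")
})

test_that("allometry p is well-calibrated under the null", {
  set.seed(54)
  sp <- group_spec("t", 60, 140, 30, 2.0, 0.6, 0.35, 0.15, seed = 55)
  g <- gpa(simulate_pits(sp), scale = TRUE)
  # covariate independent of shape by construction
  ps <- vapply(1:100, function(i) {
    allometry_test(g, covariate = rnorm(60), n_perm = 99,
                   seed = 100 + i)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.3), 0.55) # ~70% expected under uniform p
  expect_lte(mean(ps <= 0.05), 0.12)
})

test_that("TPS grids: identity, affine absorption, exact interpolation", {
  ref <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  t0 <- tps_grid(ref, ref)
  expect_equal(t0$bending_energy, 0, tolerance = 1e-10)
  expect_equal(t0$warped, t0$grid, tolerance = 1e-8, ignore_attr = TRUE)

  A <- matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2)
  taff <- tps_grid(ref, ref %*% A + 0.5)
  expect_equal(taff$bending_energy, 0, tolerance = 1e-8)

  tgt <- ref; tgt[5, ] <- tgt[5, ] + c(0.15, -0.1)
  tw <- tps_grid(ref, tgt)
  expect_equal(tw$map(ref), tgt, tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(tw$bending_energy, 0)
  # deformation is localised: corners move far less than the centre
  moved <- rowSums((tw$map(ref) - ref)^2)
  expect_gt(moved[5], 10 * max(moved[1:4]))

  expect_error(tps_grid(rbind(c(0, 0), c(1, 1), c(2, 2)),
                        rbind(c(0, 0), c(1, 1), c(2, 3))),
               "degenerate")
})

test_that("opening-angle linearisation hits its closed-form values", {
  expect_equal(oa_to_linear(90), 1, tolerance = 1e-12)
  expect_equal(oa_to_linear(45), sqrt(2), tolerance = 1e-12)
  expect_equal(oa_to_linear(180), -1, tolerance = 1e-12)
  expect_error(oa_to_linear(0), "0, 180")
  expect_error(oa_to_linear(190), "0, 180")
})

test_that("mixed-metric PCA recovers a planted factor structure", {
  set.seed(56)
  n <- 300
  width_factor <- rlnorm(n, log(0.5), 0.4)  # shared by the 5 widths
  second <- rnorm(n)
  metrics <- data.frame(
    WIS = width_factor * (1 + rnorm(n, sd = 0.02)),
    WIM = 0.66 * width_factor * (1 + rnorm(n, sd = 0.02)),
    WIB = 0.33 * width_factor * (1 + rnorm(n, sd = 0.02)),
    LDC = 0.7 * width_factor * (1 + rnorm(n, sd = 0.02)),
    RDC = 0.7 * width_factor * (1 + rnorm(n, sd = 0.02)),
    D = 0.08 + 0.012 * second,
    OA = 140 - 6 * second
  )
  p <- metric_pca(metrics)
  # PC1 loads the width variables, PC2 the D/OA axis
  l1 <- abs(p$loadings[, 1]); l2 <- abs(p$loadings[, 2])
  widths <- c("WIS", "WIM", "WIB", "LDC", "RDC")
  expect_gt(sum(l1[widths]^2), 0.9)
  expect_gt(sum(l2[c("D", "OA")]^2), 0.9)
  # raw D and OA are anticorrelated (the pattern PC2 captures)
  expect_lt(cor(metrics$D, metrics$OA), -0.9)

  expect_error(metric_pca(metrics[0, ]), "missing|zero")
  m2 <- metrics; m2$OA[1] <- NA
  expect_error(metric_pca(m2), "missing")
  # standardisation changes loadings but not rank-1 recovery
  p_std <- metric_pca(metrics, standardize = TRUE)
  expect_gt(sum(abs(p_std$loadings[widths, 1])^2), 0.5)
})

test_that("degenerate metric tables are rejected", {
  one <- data.frame(WIS = 1, WIM = 0.6, WIB = 0.3, D = 0.4, LDC = 0.7,
                    RDC = 0.7, OA = 90)
  same <- one[rep(1, 10), ]
  expect_error(metric_pca(same), "zero total variance")
})
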