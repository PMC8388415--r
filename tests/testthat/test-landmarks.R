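# Landmark types, file IO, computed wall landmarks and the derived
# cross-section measurements.

test_that("morphologika round-trip preserves coordinates and labels", {
  set.seed(11)
  configs <- lapply(1:2, function(i) {
    score_profile(make_v_profile(1 + i / 10, 0.4)$landmarks,
                  sprintf("s%d", i),
                  list(park = "Cabarceno", captivity = "captive",
                       prey_size = "large"))
  })
  ds <- landmark_dataset(configs)
  path <- withr::local_tempfile(fileext = ".txt")
  write_morphologika(ds, path)
  back <- read_morphologika(path)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(back$configs[[i]]$landmarks, ds$configs[[i]]$landmarks,
                 tolerance = 1e-12)
  }
  expect_equal(back$metadata$park, c("Cabarceno", "Cabarceno"))
  expect_equal(back$metadata$captivity, c("captive", "captive"))
})

test_that("morphologika reader reports declared counts from a fixture", {
  path <- withr::local_tempfile(fileext = ".txt")
  coords <- write_fixture_morphologika(path, n_ind = 3)
  ds <- read_morphologika(path)
  expect_equal(length(ds), 3)
  expect_equal(ds$n_landmarks, 30)
  expect_equal(ds$dimensionality, 3)
  expect_equal(ds$configs[[2]]$landmarks, coords[[2]], tolerance = 1e-12)
})

test_that("malformed morphologika files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  # declares 7 landmarks but one specimen holds 6 rows
  writeLines(c("[individuals]", "1", "[landmarks]", "7", "[dimensions]",
               "2", "[rawpoints]", "' s1",
               apply(matrix(rnorm(12), 6, 2), 1, paste, collapse = " ")),
             path)
  expect_error(read_morphologika(path), "mismatch")
  writeLines(c("[landmarks]", "7"), path)
  expect_error(read_morphologika(path), "malformed header")
  writeLines(c("[individuals]", "1", "[landmarks]", "2", "[dimensions]",
               "2", "[rawpoints]", "1 2", "3 notanumber"), path)
  expect_error(read_morphologika(path), "parse error")
  expect_error(read_morphologika(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("unknown morphologika blocks are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[individuals]", "1", "[landmarks]", "3", "[dimensions]",
               "2", "[wireframe]", "1 2", "[rawpoints]",
               "0 0", "1 0", "1 1"), path)
  expect_warning(ds <- read_morphologika(path), "wireframe")
  expect_equal(ds$n_landmarks, 3)
})

test_that("TPS records parse with ID and SCALE handling", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=7",
               apply(make_v_profile()$landmarks * 2, 1, paste,
                     collapse = " "),
               "ID=scoreA", "SCALE=0.5",
               "LM=7",
               apply(make_v_profile()$landmarks, 1, paste, collapse = " "),
               "ID=scoreB"), path)
  ds <- read_tps(path)
  expect_equal(length(ds), 2)
  expect_equal(ds$metadata$specimen_id, c("scoreA", "scoreB"))
  # SCALE multiplies the first record back onto the second
  expect_equal(ds$configs[[1]]$landmarks, ds$configs[[2]]$landmarks,
               tolerance = 1e-12)
})

test_that("computed wall landmarks sit at arc-length thirds", {
  # straight V: closed-form positions
  p <- compute_wall_landmarks(rbind(c(0, 0), c(0.5, -0.5), c(1, 0)),
                              c(1, 2, 3))
  expect_equal(p$landmarks[2, ], c(1 / 6, -1 / 6), tolerance = 1e-12)
  expect_equal(p$landmarks[3, ], c(1 / 3, -1 / 3), tolerance = 1e-12)
  expect_equal(p$landmarks[5, ], c(2 / 3, -1 / 3), tolerance = 1e-12)
  expect_equal(p$landmarks[6, ], c(5 / 6, -1 / 6), tolerance = 1e-12)

  # kinked left wall: compare against the cumulative-sum oracle
  poly <- rbind(c(0, 0), c(0.1, -0.35), c(0.45, -0.5), c(1, 0))
  pk <- compute_wall_landmarks(poly, c(1, 3, 4))
  left <- poly[1:3, ]
  expect_equal(pk$landmarks[2, ], oracle_arclength_point(left, 1 / 3),
               tolerance = 1e-12)
  expect_equal(pk$landmarks[3, ], oracle_arclength_point(left, 2 / 3),
               tolerance = 1e-12)
  right <- poly[3:4, ]
  expect_equal(pk$landmarks[5, ], oracle_arclength_point(right, 1 / 3),
               tolerance = 1e-12)

  # degenerate wall and bad ordering
  expect_error(compute_wall_landmarks(rbind(c(0, 0), c(0, 0), c(1, 0)),
                                      c(1, 2, 3)), "zero length")
  expect_error(compute_wall_landmarks(poly, c(3, 1, 4)), "between")
})

test_that("score metrics match closed forms and the geometry oracle", {
  m <- score_metrics(make_v_profile(1, 0.5))
  expect_equal(m$WIS, 1)
  expect_equal(m$WIM, 2 / 3, tolerance = 1e-12)
  expect_equal(m$WIB, 1 / 3, tolerance = 1e-12)
  expect_equal(m$D, 0.5, tolerance = 1e-12)
  expect_equal(m$LDC, sqrt(0.5), tolerance = 1e-12)
  expect_equal(m$RDC, sqrt(0.5), tolerance = 1e-12)
  expect_equal(m$OA, 90, tolerance = 1e-12)

  # flat profile: depth 0, opening angle 180
  flat <- score_profile(cbind(seq(0, 1, length.out = 7), 0))
  mf <- score_metrics(flat)
  expect_equal(mf$D, 0)
  expect_equal(mf$OA, 180)

  # asymmetric profile against the independent oracle
  asym <- make_v_profile(1, 0.4, a = 0.3)
  expect_equal(unlist(score_metrics(asym)),
               oracle_score_metrics(asym$landmarks), tolerance = 1e-12)

  expect_error(score_metrics(matrix(0, 7, 2)), "coincident")
})

test_that("metrics are invariant to rigid motions and scale correctly", {
  set.seed(7)
  for (rep in 1:5) {
    prof <- make_v_profile(runif(1, 0.5, 2), runif(1, 0.1, 0.6),
                           a = runif(1, 0.2, 0.7))
    m0 <- unlist(score_metrics(prof))
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- prof$landmarks %*% R + matrix(rnorm(2), 7, 2, byrow = TRUE)
    expect_equal(unlist(score_metrics(moved)), m0, tolerance = 1e-9)
    # reflection
    refl <- prof$landmarks %*% diag(c(-1, 1))
    expect_equal(unlist(score_metrics(refl)), m0, tolerance = 1e-9)
    # uniform scaling: lengths scale, OA unchanged
    s <- runif(1, 0.5, 3)
    ms <- unlist(score_metrics(prof$landmarks * s))
    expect_equal(ms[1:6], m0[1:6] * s, tolerance = 1e-9)
    expect_equal(ms["OA"], m0["OA"], tolerance = 1e-9)
  }
})

test_that("straight-walled profiles satisfy WIM = 2/3 WIS, WIB = 1/3 WIS", {
  set.seed(8)
  for (rep in 1:10) {
    w <- runif(1, 0.3, 2)
    prof <- make_v_profile(w, runif(1, 0.05, 0.8), a = runif(1, 0.15, 0.85) * w)
    m <- score_metrics(prof)
    expect_equal(m$WIM, (2 / 3) * m$WIS, tolerance = 1e-10)
    expect_equal(m$WIB, (1 / 3) * m$WIS, tolerance = 1e-10)
  }
})

test_that("type constructors enforce their invariants", {
  expect_error(score_profile(matrix(0, 6, 2)), "exactly 7")
  # wall landmark on the wrong side of the chord
  bad <- make_v_profile()$landmarks
  bad[2, 2] <- 0.3
  expect_error(score_profile(bad), "same side")
  # pit: width longer than length
  lm <- matrix(rnorm(90, sd = 0.01), 30, 3)
  lm[1, ] <- c(1, 0, 0); lm[2, ] <- c(-0.9, 0, 0)
  lm[3, ] <- c(0, 3, 0); lm[4, ] <- c(0, -3, 0)
  expect_error(pit_config(lm), "length axis")
  # pit: LM1 nearer the width axis than LM2
  lm[3, ] <- c(0, 0.5, 0); lm[4, ] <- c(0, -0.5, 0)
  lm[1, ] <- c(0.4, 0, 0); lm[2, ] <- c(-0.9, 0, 0)
  expect_error(pit_config(lm), "farther")
  # dataset homogeneity
  p1 <- make_v_profile()
  expect_error(landmark_dataset(list()), "empty")
  expect_error(landmark_dataset(list(p1, p1)), "unique")
})
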