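# The synthetic-data generator: determinism, geometric consistency,
# marginal fidelity and the study-condition defaults.

test_that("zero-spread specs produce the exact symmetric V", {
  sp <- group_spec("v", 5, 90, Inf, 1.0, 0, 0.5, 0, seed = 81)
  ds <- simulate_scores(sp)
  ref <- make_v_profile(1, 0.5)$landmarks
  for (cf in ds$configs) {
    expect_equal(cf$landmarks, ref, tolerance = 1e-9)
  }
  m <- score_metrics_table(ds)
  expect_equal(m$OA, rep(90, 5), tolerance = 1e-9)
  expect_equal(m$WIS, rep(1, 5), tolerance = 1e-9)
  expect_equal(m$D, rep(0.5, 5), tolerance = 1e-9)
})

test_that("the same seed reproduces an identical dataset", {
  sp <- group_spec("r", 20, 145, 30, 0.5, 0.3, 0.08, 0.05, seed = 82)
  d1 <- simulate_scores(sp)
  d2 <- simulate_scores(sp)
  expect_identical(as_landmark_array(d1), as_landmark_array(d2))
  p1 <- simulate_pits(sp)
  p2 <- simulate_pits(sp)
  expect_identical(as_landmark_array(p1), as_landmark_array(p2))
})

test_that("generated score datasets honour their spec marginals", {
  wild <- group_spec("wild", 500, 132.36, vm_kappa_from_var(0.02),
                     0.49, 0.27, 0.11, 0.08, captivity = "wild",
                     seed = 83)
  captive <- group_spec("captive", 500, 151.40, vm_kappa_from_var(0.03),
                        0.50, 0.33, 0.07, 0.06, captivity = "captive",
                        seed = 84)
  mw <- score_metrics_table(simulate_scores(wild))
  mc <- score_metrics_table(simulate_scores(captive))
  expect_lt(abs(median(mw$D) - 0.11) / 0.11, 0.15)
  expect_lt(abs(median(mc$D) - 0.07) / 0.07, 0.15)
  expect_lt(abs(median(mw$WIS) - 0.49) / 0.49, 0.15)
  # built-in depth-width dependence survives the geometry
  expect_gt(cor(mw$D, mw$WIS, method = "kendall"), 0.3)
  # wild marks are deeper than captive ones
  expect_gt(median(mw$D), median(mc$D))
})

test_that("every generated configuration passes the type invariants", {
  sp <- group_spec("inv", 40, 140, 25, 0.5, 0.25, 0.08, 0.05, seed = 85)
  ds <- simulate_scores(sp)
  expect_length(ds$configs, 40)
  # score_profile() constructor re-validates internally; metrics sane
  m <- score_metrics_table(ds)
  expect_true(all(m$OA > 0 & m$OA <= 180))
  expect_true(all(m[, c("WIS", "WIM", "WIB", "D", "LDC", "RDC")] >= 0))
  expect_true(all(m$WIS >= m$WIM & m$WIM >= m$WIB))

  pits <- simulate_pits(sp)
  for (cf in pits$configs) {
    lm <- cf$landmarks
    expect_gte(sqrt(sum((lm[1, ] - lm[2, ])^2)) + 1e-9,
               sqrt(sum((lm[3, ] - lm[4, ])^2)))
  }
})

test_that("circular pits have equal length and width axes", {
  sp <- group_spec("circ", 25, 140, 30, 2.0, 0.4, 0.35, 0.1, seed = 86)
  ds <- simulate_pits(sp, width_ratio = c(1, 1), jitter = 0.002)
  ratios <- vapply(ds$configs, function(cf) {
    lm <- cf$landmarks
    sqrt(sum((lm[3, ] - lm[4, ])^2)) / sqrt(sum((lm[1, ] - lm[2, ])^2))
  }, numeric(1))
  expect_gt(min(ratios), 0.97)
})

test_that("allometry power and null behave as designed", {
  sp1 <- group_spec("slope", 100, 140, 30, 2.0, 0.6, 0.35, 0.15,
                    allometry_slope = 0.3, seed = 87)
  g1 <- gpa(simulate_pits(sp1), scale = TRUE)
  expect_lte(allometry_test(g1, n_perm = 199, seed = 88)$p, 0.01)

  # with no built-in slope the permutation p is uniform across
  # generator seeds
  ps <- vapply(1:40, function(i) {
    sp0 <- group_spec("null", 40, 140, 30, 2.0, 0.6, 0.35, 0.15,
                      allometry_slope = 0, seed = 400 + i)
    g0 <- gpa(simulate_pits(sp0), scale = TRUE)
    allometry_test(g0, n_perm = 99, seed = 90)$p
  }, numeric(1))
  # (permutation p-values sit on a 1/100 grid, so exact-KS ties are
  # expected)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("study-condition default specs carry the published values", {
  specs <- paper_default_specs(1)
  expect_named(specs, c("scores", "pits"))
  expect_length(specs$scores, 4)
  s <- specs$scores
  expect_equal(s$Cabarceno$depth_central, 0.05)
  expect_equal(s$Hosquillo$depth_central, 0.07)
  expect_equal(s$Flechas$depth_central, 0.09)
  expect_equal(s$Villardeciervos$depth_central, 0.12)
  expect_equal(s$Cabarceno$oa_mean, 158.67)
  expect_equal(s$Villardeciervos$oa_mean, 132.19)
  expect_equal(vapply(s, `[[`, integer(1), "n"),
               c(Cabarceno = 56L, Hosquillo = 113L, Flechas = 63L,
                 Villardeciervos = 56L))
  expect_equal(vapply(specs$pits, `[[`, integer(1), "n"),
               c(Cabarceno = 42L, Hosquillo = 113L, Flechas = 49L,
                 Villardeciervos = 79L))
  # captive pooled depth median ~0.07, wild ~0.11 by construction
  expect_true(all(vapply(s[c("Cabarceno", "Hosquillo")], `[[`,
                         character(1), "captivity") == "captive"))
  expect_true(all(vapply(s[c("Flechas", "Villardeciervos")], `[[`,
                         character(1), "captivity") == "wild"))

  # specs round-trip through JSON serialization unchanged
  js <- jsonlite::toJSON(unclass(s$Cabarceno), auto_unbox = TRUE,
                         digits = NA)
  back <- jsonlite::fromJSON(js)
  for (f in c("n", "oa_mean", "wis_central", "depth_central", "tau")) {
    expect_equal(back[[f]], s$Cabarceno[[f]])
  }
})

test_that("pooled multi-group simulation keeps metadata aligned", {
  specs <- paper_default_specs(3)
  small <- lapply(specs$scores[c("Cabarceno", "Flechas")], function(s) {
    s$n <- 15L
    s
  })
  ds <- simulate_groups(small, "scores")
  expect_equal(length(ds), 30)
  expect_equal(sort(unique(ds$metadata$park)), c("Cabarceno", "Flechas"))
  expect_equal(as.vector(table(ds$metadata$captivity)[c("captive", "wild")]),
               c(15L, 15L))
})
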