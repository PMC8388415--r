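# Circular descriptives and tests for opening angles.

test_that("degenerate and uniform samples give the textbook values", {
  d <- circ_descriptives(rep(90, 5))
  expect_equal(d$theta_bar, 90, tolerance = 1e-9)
  expect_equal(d$theta_tilde, 90, tolerance = 1e-9)
  expect_equal(d$v, 0, tolerance = 1e-12)

  u <- circ_descriptives(c(0, 90, 180, 270))
  expect_equal(u$rbar, 0, tolerance = 1e-12)
  expect_equal(u$v, 1, tolerance = 1e-12)

  expect_error(circ_descriptives(90), "at least two")
})

test_that("descriptives recover Von Mises parameters from simulation", {
  kappa <- vm_kappa_from_var(0.03)
  set.seed(101)
  oa <- rvonmises(200, (151 * pi / 180), kappa) * 180 / pi
  desc <- circ_descriptives(oa)
  expect_lt(abs(desc$theta_bar - 151), 3)
  expect_lt(abs(desc$v - 0.03), 0.015)
})

test_that("kappa back-solved from circular variance inverts A(kappa)", {
  for (v in c(0.01, 0.02, 0.03, 0.2)) {
    k <- vm_kappa_from_var(v)
    rbar <- besselI(k, 1, expon.scaled = TRUE) /
      besselI(k, 0, expon.scaled = TRUE)
    expect_equal(rbar, 1 - v, tolerance = 1e-8)
  }
  expect_equal(vm_kappa_from_var(0), Inf)
})

test_that("Rayleigh test separates uniform from concentrated samples", {
  # perfectly uniform 4-point sample duplicated to n = 8
  r0 <- rayleigh_test(rep(c(0, 90, 180, 270), 2))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.98)

  r1 <- rayleigh_test(rep(137, 20))
  expect_equal(r1$statistic, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-6)

  set.seed(5)
  oa <- rvonmises(150, (140 * pi / 180), vm_kappa_from_var(0.02)) * 180 / pi
  r2 <- rayleigh_test(oa)
  expect_gt(r2$statistic, 0.95)
  expect_lt(r2$p, 1e-20)

  expect_error(rayleigh_test(c(1, 2, 3)), "n >= 5")
})

test_that("symmetry test accepts built-in symmetry, rejects skew", {
  # exactly reflective sample about 150 degrees
  base <- c(5, 12, 20, 33, 47, 60)
  sym <- c(150 + base, 150 - base)
  s0 <- symmetry_test(sym)
  expect_lt(s0$statistic, 0.7)
  expect_gt(s0$p, 0.4)

  # wrapped-exponential-type tail on one side
  set.seed(6)
  skewed <- 100 + rexp(200, rate = 1 / 25)
  s1 <- symmetry_test(skewed)
  expect_lt(s1$p, 0.01)

  expect_error(symmetry_test(1:5), "n >= 10")
})

test_that("symmetry test holds its level under Von Mises sampling", {
  set.seed(7)
  kappa <- vm_kappa_from_var(0.03)
  keep <- vapply(1:100, function(i) {
    oa <- rvonmises(150, (140 * pi / 180), kappa) * 180 / pi
    symmetry_test(oa)$p > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.90)
})

test_that("two-sample tests see no signal in exchangeable duplicates", {
  set.seed(8)
  a <- rvonmises(30, (140 * pi / 180), 20) * 180 / pi
  for (m in c("watson_mean", "fisher_median", "mww_distribution")) {
    r <- circ_two_sample(a, a, m, reps = 199, seed = 9)
    expect_gt(r$p, 0.3)
  }
})

test_that("two-sample tests detect the captive/wild angular shift", {
  set.seed(9)
  kappa <- vm_kappa_from_var(0.025)
  a <- rvonmises(150, (132 * pi / 180), kappa) * 180 / pi
  b <- rvonmises(150, (151 * pi / 180), kappa) * 180 / pi
  for (m in c("watson_mean", "fisher_median", "mww_distribution")) {
    r <- circ_two_sample(a, b, m, reps = 999, seed = 10)
    expect_lte(r$p, 0.001)
  }
})

test_that("permutation p agrees with exact enumeration on tiny samples", {
  t1 <- (pi / 180) * c(10, 40, 80, 200, 300, 15, 55, 120)
  t2 <- (pi / 180) * c(150, 170, 190, 210, 230, 250, 135, 165)
  exact <- oracle_mww_exact_p(t1, t2)
  r <- circ_two_sample(t1, t2, "mww_distribution", reps = 9999,
                       seed = 11, degrees = FALSE)
  # add-one estimator vs exact proportion: binomial error margin
  expect_lt(abs(r$p - exact), 3 * sqrt(exact * (1 - exact) / 9999) + 2e-4)
})

test_that("statistics are invariant to a common rotation", {
  set.seed(12)
  a <- rvonmises(40, 2, 8) * 180 / pi
  b <- rvonmises(40, 2.4, 8) * 180 / pi
  for (m in c("watson_mean", "fisher_median", "mww_distribution")) {
    r1 <- circ_two_sample(a, b, m, reps = 199, seed = 13)
    r2 <- circ_two_sample(a + 77, b + 77, m, reps = 199, seed = 13)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
    expect_equal(r1$p, r2$p)
  }
  d1 <- circ_descriptives(a); d2 <- circ_descriptives(a + 90)
  expect_equal(d2$v, d1$v, tolerance = 1e-12)
  expect_equal(d2$k_hat, d1$k_hat, tolerance = 1e-9)
  expect_equal(d2$s_hat, d1$s_hat, tolerance = 1e-9)
})

test_that("seeded randomization tests are bit-reproducible", {
  set.seed(14)
  a <- rvonmises(20, 1, 5) * 180 / pi
  b <- rvonmises(20, 1.5, 5) * 180 / pi
  r1 <- circ_two_sample(a, b, "watson_mean", reps = 199, seed = 21)
  r2 <- circ_two_sample(a, b, "watson_mean", reps = 199, seed = 21)
  expect_identical(r1$p, r2$p)
  expect_error(circ_two_sample(a[1:5], b, "watson_mean"), "n >= 8")
  expect_error(circ_two_sample(a, b, "watson_mean", reps = 50),
               "reps")
})
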