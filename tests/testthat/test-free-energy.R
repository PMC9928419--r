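test_that("BAR solves the self-consistency equation", {
  # identical states
  expect_equal(bar_estimate(rep(0, 10), rep(0, 10))$dF, 0, tolerance = 1e-10)

  # tiny instance vs a dense grid search of the same Bennett equation
  set.seed(5)
  f <- rnorm(5, 1, 0.5)
  r <- rnorm(5, -1, 0.5)
  est <- bar_estimate(f, r)
  rt <- gas_constant_kcal() * 298.15
  g <- function(C) {
    sum(stats::plogis(-((f - C) / rt))) - sum(stats::plogis(-((r + C) / rt)))
  }
  grid <- seq(est$dF - 0.5, est$dF + 0.5, by = 1e-6)
  oracle <- grid[which.min(abs(vapply(grid, g, numeric(1))))]
  expect_equal(est$dF, oracle, tolerance = 2e-6)
})

test_that("BAR recovers a planted Gaussian fluctuation-theorem pair", {
  rt <- gas_constant_kcal() * 298.15
  set.seed(21)
  n <- 5000; sigma <- 0.5; dF <- 1.0
  diss <- sigma^2 / (2 * rt)
  wf <- rnorm(n, dF + diss, sigma)
  wr <- rnorm(n, -dF + diss, sigma)
  est <- bar_estimate(wf, wr)
  expect_lt(abs(est$dF - dF), 2 * est$err)
  expect_true(est$overlap_ok)
})

test_that("BAR is antisymmetric under direction exchange", {
  sim <- sim_bar_windows(seed = 9, n_windows = 1, n_samples = 500,
                         dF_windows = 0.8, sigma = 1)
  fwd <- sim$samples$du_kcal[sim$samples$direction == "fwd"]
  rev <- sim$samples$du_kcal[sim$samples$direction == "rev"]
  expect_equal(bar_estimate(fwd, rev)$dF, -bar_estimate(rev, fwd)$dF,
               tolerance = 1e-7)
})

test_that("non-overlapping windows are flagged, not silently returned", {
  expect_warning(est <- bar_estimate(rnorm(50, 100, 0.1),
                                     rnorm(50, 100, 0.1)),
                 "overlap")
  expect_false(est$overlap_ok)
  expect_true(is.infinite(est$err))
})

test_that("window sums follow independent-error quadrature", {
  expect_equal(sum_windows(tibble::tibble(dF = rep(0, 40),
                                          err = rep(0, 40)))$dG, 0)
  s <- sum_windows(tibble::tibble(dF = c(1, 2), err = c(0.3, 0.4)))
  expect_equal(s$dG, 3)
  expect_equal(s$err, 0.5)
  expect_error(sum_windows(tibble::tibble(dF = numeric(), err = numeric())),
               "no windows")

  # sub-splitting invariance: exact half-windows re-sum to the same total
  full <- tibble::tibble(dF = c(1.2, -0.4), err = c(0, 0))
  split <- tibble::tibble(dF = c(0.6, 0.6, -0.2, -0.2), err = rep(0, 4))
  expect_equal(sum_windows(split)$dG, sum_windows(full)$dG)
})

test_that("restraint correction matches its analytic scaling laws", {
  base <- restraint_correction(0.5, pi / 2, pi / 2)
  rt <- gas_constant_kcal() * 298.15

  # doubling the standard volume adds -RT ln 2
  expect_equal(restraint_correction(0.5, pi / 2, pi / 2, V0 = 2 * 1.6606) -
                 base, -rt * log(2), tolerance = 1e-10)

  # multiplying all six force constants by 4 adds -RT ln(4^3) (six half powers)
  quad <- restraint_correction(0.5, pi / 2, pi / 2, K_r = 4000,
                               K_thetaA = 40, K_thetaB = 40, K_phiA = 40,
                               K_phiB = 40, K_phiC = 40)
  expect_equal(quad - base, -rt * log(4^3), tolerance = 1e-10)

  expect_error(restraint_correction(0.5, 0, pi / 2), "strictly inside")
})

test_that("restraint closed form agrees with numerical quadrature", {
  # frozen-Jacobian integral: the object the formula evaluates exactly
  for (r0 in c(0.3, 0.5, 0.8)) {
    for (kscale in c(0.5, 1, 4)) {
      a <- restraint_correction(r0, pi / 3, pi / 2, K_r = 1000 * kscale,
                                K_thetaA = 10 * kscale,
                                K_thetaB = 10 * kscale,
                                K_phiA = 10 * kscale, K_phiB = 10 * kscale,
                                K_phiC = 10 * kscale)
      q <- restraint_correction_quadrature(r0, pi / 3, pi / 2,
                                           K_r = 1000 * kscale,
                                           K_thetaA = 10 * kscale,
                                           K_thetaB = 10 * kscale,
                                           K_phiA = 10 * kscale,
                                           K_phiB = 10 * kscale,
                                           K_phiC = 10 * kscale)
      expect_lt(abs(a - q), 0.01)
    }
  }

  # full-Jacobian integral: deviation equals the stiff-spring error,
  # approximately RT^2 (1/K_thetaA + 1/K_thetaB) at theta = pi/2
  rt <- gas_constant_kcal() * 298.15
  a <- restraint_correction(0.5, pi / 2, pi / 2)
  qfull <- restraint_correction_quadrature(0.5, pi / 2, pi / 2,
                                           jacobian = "full")
  expect_equal(a - qfull, rt^2 * (1 / 10 + 1 / 10), tolerance = 0.1)
})

test_that("cycle assembly and Kd conversion are exact bookkeeping", {
  expect_equal(assemble_cycle(0, 0, 0)$dG_bind, 0)
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(3)
    expect_equal(assemble_cycle(v[1], v[2], v[3])$dG_bind,
                 -v[1] + v[2] + v[3])
  }
  cyc <- assemble_cycle(1, 2, 3, err_complex = 0.3, err_solv = 0.4)
  expect_equal(cyc$err_bind, 0.5)

  expect_equal(dg_to_kd(0), 1)
  expect_equal(dg_to_kd(-7.14, 298.15) * 1e6, 5.84, tolerance = 0.01)
  expect_equal(dg_to_kd(-5.50, 298.15) * 1e6, 93, tolerance = 0.01)
  # round trip to machine precision
  for (dg in c(-12, -7.24, -0.3, 2)) {
    expect_equal(kd_to_dg(dg_to_kd(dg)), dg, tolerance = 1e-12)
  }
})

test_that("affinity thresholds respect the possible-flag escalation", {
  expect_equal(classify_dg(-5.6, FALSE), "hit")
  expect_equal(classify_dg(-6.0, TRUE), "rejected")
  expect_equal(classify_dg(-10.82, TRUE), "hit")   # high-affinity rescue
  expect_equal(classify_dg(-5.4, FALSE), "rejected")
  expect_equal(classify_dg(c(-5.6, -6.0), c(FALSE, TRUE)),
               c("hit", "rejected"))
})
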