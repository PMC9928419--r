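test_that("csp reproduces both printed variants and basic invariances", {
  a <- peak_table(c("G1", "G2"), c(8.00, 8.50), c(110.0, 120.0), "apo")
  b <- peak_table(c("G1", "G2"), c(8.03, 8.50), c(110.2, 120.0), "bound")
  res <- csp(a, b)
  expect_equal(res$csp[res$residue == "G1"], 0.0290, tolerance = 1e-3)
  expect_equal(res$csp[res$residue == "G2"], 0)

  lit <- csp(a, b, form = "literal")
  expect_equal(lit$csp[lit$residue == "G1"], 0.000842, tolerance = 1e-6)

  # identical tables: all zeros
  expect_true(all(csp(a, a)$csp == 0))

  # magnitude only: swapping ref and bound changes nothing
  expect_equal(csp(b, a)$csp, res$csp)

  # residue order does not matter
  b_shuffled <- b[2:1, ]
  expect_equal(sort(csp(a, b_shuffled)$csp), sort(res$csp))

  # unmatched residues are reported, not dropped
  c_tab <- peak_table(c("G1", "G3"), c(8.0, 7.5), c(110, 115))
  expect_message(res2 <- csp(a, c_tab), "G2")
  expect_setequal(attr(res2, "unmatched"), c("G2", "G3"))
  expect_error(csp(a, peak_table("Z9", 8, 110)), "no shared")
})

test_that("pocket averages and binder calls separate signal from background", {
  ct <- tibble::tibble(residue = c("W65", "F85", "B1", "B2", "B3"),
                       csp = c(0.02, 0.04, 0, 0, 0))
  expect_equal(pocket_average(ct, c("W65", "F85")), 0.03)
  expect_error(pocket_average(ct, c("W65", "K118")), "K118")

  # planted pocket signal 5x the background
  tabs <- shifted_peak_tables(pocket_shift = 0.05, background_shift = 0.01)
  call <- binding_call(csp(tabs$apo, tabs$bound), pocket_residues)
  expect_equal(call$verdict, "binder")

  # an all-zero spectrum cannot be a binder
  tabs0 <- shifted_peak_tables(pocket_shift = 0, background_shift = 0)
  call0 <- binding_call(csp(tabs0$apo, tabs0$bound), pocket_residues)
  expect_equal(call0$verdict, "non-binder")

  tiny <- tibble::tibble(residue = c("W65", "B1", "B2"), csp = c(1, 0, 0))
  expect_error(binding_call(tiny, "W65"), "3 non-pocket")
})

test_that("competition SP matches hand dot products and its symmetries", {
  u <- c(0.05, 0.01); v <- c(-0.03, 0.02)
  mid <- (u + v) / 2
  tr <- tibble::tibble(residue = c("mid", "sum", "same"),
                       uH = u[1], uN = u[2], vH = v[1], vN = v[2],
                       wH = c(mid[1], u[1] + v[1], v[1]),
                       wN = c(mid[2], u[2] + v[2], v[2]))
  res <- competition_sp(tr)
  expect_equal(res$SP[1], -0.001625)   # prints as -0.0016
  expect_equal(res$regime[1], "competition")
  # w = u + v collapses SP to u.v (here negative: these vectors oppose)
  expect_equal(res$SP[2], sum(u * v), tolerance = 1e-12)
  # w = v: ligand has no effect on the complex
  expect_equal(res$SP[3], 0)
  expect_equal(res$regime[3], "indeterminate")

  # additive case needs same-direction binary displacements
  v2 <- c(0.03, 0.02)
  tr_add <- tibble::tibble(residue = "add", uH = u[1], uN = u[2],
                           vH = v2[1], vN = v2[2],
                           wH = u[1] + v2[1], wN = u[2] + v2[2])
  res_add <- competition_sp(tr_add)
  expect_equal(res_add$SP, sum(u * v2))
  expect_equal(res_add$regime, "additive")

  # symmetric under u <-> v exchange; quadratic under common scaling
  tr_sw <- dplyr::rename(tr, uH = vH, uN = vN, vH = uH, vN = uN)
  expect_equal(competition_sp(tr_sw)$SP, res$SP)
  tr_scaled <- dplyr::mutate(tr, dplyr::across(uH:wN, ~ 3 * .x))
  expect_equal(competition_sp(tr_scaled)$SP, 9 * res$SP)
})

test_that("planted competition regimes are classified correctly", {
  g0 <- sim_competition(seed = 2, noise_sd = 0)
  r0 <- competition_sp(g0$triplets)
  expect_equal(mean(r0$regime == g0$truth$regime), 1)

  g5 <- sim_competition(seed = 2, noise_sd = 0.05 * 0.05)
  r5 <- competition_sp(g5$triplets)
  expect_gte(mean(r5$regime == g5$truth$regime), 0.95)

  expect_error(sim_competition(alpha = 1), "strictly inside")
})

test_that("std quantities follow the fractional-transfer definitions", {
  rec <- tibble::tibble(proton = c("H1", "H2", "H3"),
                        I_on = c(0.9, 0.95, 0.98), I_off = 1)
  res <- std_quantities(rec, L_total = 500, E_total = 10)
  expect_equal(res$A_STD, c(0.10, 0.05, 0.02))
  expect_equal(res$STD_AF, c(5.0, 2.5, 1.0))
  expect_equal(res$rel_percent, c(100, 50, 20))
  expect_equal(max(res$rel_percent), 100)

  same <- suppressWarnings(
    std_quantities(tibble::tibble(proton = "H", I_on = 1, I_off = 1),
                   500, 10))
  expect_equal(same$A_STD, 0)
  expect_warning(std_quantities(tibble::tibble(proton = c("a", "b"),
                                               I_on = 1, I_off = 1),
                                500, 10), "undefined")
})

test_that("fast-exchange titrations are linear, two-site ones are not", {
  sim <- sim_titration(seed = 3, noise_sd = 0)
  tl <- titration_linearity(sim$series)
  expect_true(all(tl$verdict == "single-mode"))
  expect_true(all(tl$r_squared > 0.999))

  # two-site path: the 1H axis saturates with a tight site (Kd 10) and
  # the 15N axis with a weak one (Kd 500) -> the trajectory curves
  fb <- function(kd, l, p = 50) {
    s <- p + l + kd
    ((s - sqrt(s^2 - 4 * p * l)) / 2) / p
  }
  conc <- exp(seq(log(10), log(1000), length.out = 16))
  two <- tibble::tibble(conc = conc, residue = "R1",
                        dH_ppm = 8 + 0.1 * fb(10, conc),
                        dN_ppm = 110 + (0.1 / 0.14) * fb(500, conc))
  tl2 <- titration_linearity(two)
  expect_lt(tl2$r_squared, 0.98)
  expect_equal(tl2$verdict, "multi-mode")

  # a stationary residue is reported as not shifting
  flat <- tidyr::expand_grid(conc = c(10, 50, 200, 1000), residue = "R1")
  flat$dH_ppm <- 8; flat$dN_ppm <- 110
  expect_equal(titration_linearity(flat)$verdict, "not-shifting")
})

test_that("titration isotherm fit recovers the planted Kd within 25%", {
  sim <- sim_titration(seed = 6, Kd = 50, noise_sd = 0.001)
  fit <- fit_shift_titration(sim$series, protein_conc = 50)
  expect_lt(abs(fit$Kd - 50) / 50, 0.25)
})
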