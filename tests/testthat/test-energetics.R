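test_that("delta_delta_H reproduces hand arithmetic and trivial cases", {
  # identical channels: no preference either way
  tr0 <- energy_trace(c(0, 1, 2), c(-5, -6, -7), c(-5, -6, -7))
  d0 <- delta_delta_H(tr0)
  expect_equal(d0$ddH_mean, 0)
  expect_equal(d0$ddH_sd, 0)

  tr <- energy_trace(c(0, 1), c(-10, -12), c(-4, -6))
  d <- delta_delta_H(tr)
  expect_equal(d$ddH_mean, -6)
  expect_equal(d$ddH_sd, 0)

  expect_error(energy_trace(0, -1, -1), "two frames")
  expect_error(energy_trace(c(0, 0), c(-1, -1), c(-1, -1)), "increasing")
})

test_that("kJ/mol traces convert on read and averaging commutes with units", {
  tr_kcal <- energy_trace(c(0, 1, 2), c(-10, -12, -11), c(-4, -5, -6))
  tr_kj <- energy_trace(c(0, 1, 2), c(-10, -12, -11) * 4.184,
                        c(-4, -5, -6) * 4.184, unit = "kJ/mol")
  expect_equal(delta_delta_H(tr_kj)$ddH_mean, delta_delta_H(tr_kcal)$ddH_mean)
  expect_equal(delta_delta_H(tr_kj)$ddH_sd, delta_delta_H(tr_kcal)$ddH_sd)

  # uniform time reindexing leaves the summary untouched
  tr_re <- energy_trace(c(10, 20, 30), c(-10, -12, -11), c(-4, -5, -6))
  expect_equal(delta_delta_H(tr_re)[-1], delta_delta_H(tr_kcal)[-1])
})

test_that("OU-noise traces recover the planted mean within 3 SE", {
  sim <- sim_energy_trace(seed = 11, n_frames = 5000, ddH_mean = -5,
                          ddH_sd = 3)
  d <- delta_delta_H(sim$trace)
  phi <- sim$truth$phi
  se <- 3 / sqrt(5000) * sqrt((1 + phi) / (1 - phi))
  expect_lt(abs(d$ddH_mean - (-5)), 3 * se)
  expect_lt(abs(d$ddH_sd - 3), 0.3)
})

test_that("contact_ratio counts unique pairs per interacting atom", {
  # one contact per atom
  cs1 <- contact_set(c("a", "b", "c", "d"), c("p1", "p2", "p3", "p4"))
  expect_equal(contact_ratio(cs1)$c, 1)

  # 2 + 1 + 3 contacts on 3 atoms
  cs2 <- contact_set(c("a", "a", "b", "c", "c", "c"),
                     c("p1", "p2", "p1", "p3", "p4", "p5"))
  expect_equal(contact_ratio(cs2)$c, 2)

  # duplicated rows collapse; brute-force recount oracle on random tables
  set.seed(7)
  for (i in 1:10) {
    la <- sample(letters[1:6], 30, replace = TRUE)
    pa <- sample(paste0("p", 1:10), 30, replace = TRUE)
    cs <- contact_set(la, pa)
    uni <- unique(paste(la, pa))
    expect_equal(contact_ratio(cs)$n_contacts, length(uni))
    expect_equal(contact_ratio(cs)$c,
                 length(uni) / length(unique(sub(" .*", "", uni))))
  }

  expect_warning(res <- contact_ratio(contact_set(character(), character())),
                 "unbound")
  expect_equal(res$c, 0)
})

test_that("score and classification follow the weighted rule", {
  sc <- score_and_classify(tibble::tibble(
    ddH_mean = c(-3, 6, 10), ddH_sd = c(0, 7, 2), c = c(2, 1, 1)
  ))
  expect_equal(sc$S, c(11, -2, -6))
  expect_equal(sc$classification, c("hit", "possible", "rejected"))

  # a ligand that left the pocket is out regardless of S
  out <- score_and_classify(tibble::tibble(
    ddH_mean = -3, ddH_sd = 0, c = 2, stayed_in_pocket = FALSE))
  expect_equal(out$classification, "left_pocket")

  # recorded screen reference: a low positive score is still a hit
  f3 <- score_and_classify(tibble::tibble(ddH_mean = 0, ddH_sd = 0,
                                          c = 6.15 / 4))
  expect_equal(f3$S, 6.15)
  expect_equal(f3$classification, "hit")

  # alternative "possible" policy: sd must exceed |mean|
  alt <- score_and_classify(tibble::tibble(ddH_mean = 6, ddH_sd = 7, c = 1),
                            possible_policy = "sd_exceeds_mean")
  expect_equal(alt$classification, "possible")
  alt2 <- score_and_classify(tibble::tibble(ddH_mean = 6, ddH_sd = 5, c = 1),
                             possible_policy = "sd_exceeds_mean")
  expect_equal(alt2$classification, "rejected")
})

test_that("score is monotone in c and ddH_mean and partition is exhaustive", {
  set.seed(1)
  base <- tibble::tibble(ddH_mean = rnorm(50, 0, 5),
                         ddH_sd = abs(rnorm(50, 3, 2)),
                         c = runif(50, 1, 4))
  sc <- score_and_classify(base)
  up_c <- score_and_classify(dplyr::mutate(base, c = c + 0.5))
  up_d <- score_and_classify(dplyr::mutate(base, ddH_mean = ddH_mean + 1))
  expect_true(all(up_c$S > sc$S))
  expect_true(all(up_d$S < sc$S))
  expect_true(all(sc$classification %in% c("hit", "possible", "rejected")))
  # exactly one class per row by construction of case_when; spot-check
  expect_false(any(sc$S > 0 & sc$classification != "hit"))
})

test_that("traces and contacts round-trip through their file formats", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time = c(0, 1), H_LP = c(-10, -12),
                                  H_LW = c(-4, -6)), tmp)
  tr <- read_energy_trace(tmp)
  expect_equal(delta_delta_H(tr)$ddH_mean, -6)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(ligand_atom = c("a", "a", "b"),
                                  protein_atom = c("p1", "p2", "p1")), tmp2)
  expect_equal(contact_ratio(read_contacts(tmp2))$c, 1.5)
})
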