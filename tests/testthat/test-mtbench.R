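test_that("spot filtering applies the strict elongation boundary", {
  s <- tibble::tibble(width = c(0.10, 0.21, 0.22, 0.30, 0.15),
                      length = 1)
  kept <- filter_spots(s)
  expect_equal(nrow(kept), 3)
  expect_false(0.22 %in% kept$width)     # boundary ratio is excluded

  # subset and idempotence properties
  expect_true(all(kept$width %in% s$width))
  expect_equal(filter_spots(kept), kept)

  # bait-enrichment cutoff: spot must be > 2x the cytoplasm bait level
  s2 <- tibble::tibble(width = 1, length = 10, gfp_mean = c(50, 15),
                       gfp_cyto_mean = 20)
  expect_equal(nrow(filter_spots(s2)), 1)
  expect_error(filter_spots(tibble::tibble(width = 2, length = 1)),
               "length >= width")
})

test_that("enrichment is the spot-to-cytoplasm ratio with zero-signal drops", {
  s <- tibble::tibble(mrna_spot_mean = c(150, 100), mrna_cyto_mean = 100)
  e <- enrichment(s)
  expect_equal(e$enrichment, c(1.5, 1.0))
  s0 <- tibble::tibble(mrna_spot_mean = c(150, 80),
                       mrna_cyto_mean = c(100, 0))
  expect_message(e0 <- enrichment(s0), "dropped")
  expect_equal(nrow(e0), 1)
})

test_that("well slopes match hand OLS and scale equivariance", {
  s <- tibble::tibble(well_id = "w1", gfp_mean = c(1, 2, 3),
                      enrichment = c(1.0, 1.2, 1.4))
  fit <- suppressWarnings(well_slope(s, min_spots = 3))
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 0.8)

  # constant enrichment: slope 0
  sc <- tibble::tibble(well_id = "w1", gfp_mean = 1:40,
                       enrichment = rep(2, 40))
  expect_equal(suppressWarnings(well_slope(sc))$slope, 0)

  # scaling bait intensities by a > 0 scales the slope by 1/a
  sim <- sim_plate(seed = 13, layout = plate_layout()[1, ], n_cells = 10)
  sp <- enrichment(sim$spots)
  f1 <- well_slope(sp)
  sp2 <- dplyr::mutate(sp, gfp_mean = 5 * gfp_mean)
  expect_equal(well_slope(sp2)$slope, f1$slope / 5, tolerance = 1e-10)

  # under-populated or zero-variance wells are flagged unusable
  few <- tibble::tibble(well_id = "w", gfp_mean = 1:5, enrichment = 1:5)
  expect_false(well_slope(few)$usable)
  novar <- tibble::tibble(well_id = "w", gfp_mean = rep(1, 40),
                          enrichment = rnorm(40))
  expect_false(well_slope(novar)$usable)
})

test_that("plate normalisation anchors the control means at 0 and 1", {
  sl <- tibble::tibble(
    well_id = paste0("w", 1:6),
    slope = c(0.001, 0.003, 0.011, 0.009, 0.0055, 0.008),
    role = c("gfp", "gfp", "dmso", "dmso", "treated", "treated"))
  ns <- normalize_plate(sl)
  expect_equal(mean(ns$normalized_slope[ns$role == "dmso"]), 1)
  expect_equal(mean(ns$normalized_slope[ns$role == "gfp"]), 0)
  # a well halfway between the control means lands at 0.5
  expect_equal(ns$normalized_slope[5], 0.4375)
  # normalising an already normalised plate is the identity
  ns2 <- normalize_plate(dplyr::mutate(ns, slope = normalized_slope))
  expect_equal(ns2$normalized_slope, ns$normalized_slope)
  expect_error(normalize_plate(sl[sl$role != "gfp", ]), "control")
})

test_that("ssmd follows its definition, antisymmetry and affine invariance", {
  expect_equal(ssmd(c(1, 1.1, 0.9), c(1, 1.1, 0.9)), 0)
  pos <- c(1.0, 1.2, 0.8, 1.1); neg <- c(0.1, -0.1, 0.05, -0.05)
  expect_equal(ssmd(pos, neg),
               (mean(pos) - mean(neg)) / sqrt(var(pos) + var(neg)))
  expect_equal(ssmd(neg, pos), -ssmd(pos, neg))
  # common affine transform leaves the sumvar variant unchanged
  expect_equal(ssmd(3 * pos + 2, 3 * neg + 2), ssmd(pos, neg))
  # pooled variant differs by sqrt(2) for equal group sizes and SDs
  set.seed(1)
  a <- rnorm(48); b <- rnorm(48) + 2
  expect_equal(ssmd(b, a, "pooled") / ssmd(b, a, "sumvar"), sqrt(2),
               tolerance = 0.05)
  expect_warning(ssmd(c(1, 1), c(0, 0)), "undefined")
})

test_that("hit calls require a significant decrease relative to DMSO", {
  sl <- dplyr::bind_rows(
    tibble::tibble(well_id = paste0("d", 1:4), role = "dmso",
                   compound = "DMSO", replicate = 1:4,
                   normalized_slope = c(1.00, 1.02, 0.98, 1.01)),
    tibble::tibble(well_id = paste0("t", 1:4), role = "treated",
                   compound = "X", replicate = 1:4,
                   normalized_slope = c(0.80, 0.82, 0.78, 0.81)),
    tibble::tibble(well_id = paste0("u", 1:4), role = "treated",
                   compound = "UP", replicate = 1:4,
                   normalized_slope = c(1.20, 1.22, 1.18, 1.21)))
  hits <- suppressWarnings(call_hits(sl))
  expect_true(hits$significant[hits$compound == "X"])
  expect_equal(hits$mean_effect[hits$compound == "X"], -0.2)
  # an equally significant increase is never a hit
  expect_false(hits$significant[hits$compound == "UP"])

  # treated wells indistinguishable from DMSO stay non-significant
  set.seed(2)
  jig <- dplyr::bind_rows(
    tibble::tibble(well_id = paste0("d", 1:4), role = "dmso",
                   compound = "DMSO", replicate = 1:4,
                   normalized_slope = 1 + rnorm(4, 0, 0.02)),
    tibble::tibble(well_id = paste0("t", 1:4), role = "treated",
                   compound = "Y", replicate = 1:4,
                   normalized_slope = 1 + rnorm(4, 0, 0.02)))
  expect_false(call_hits(jig)$significant)
})

test_that("planted-effect plates come back with the right hit set", {
  lay <- plate_layout(compounds = c("A", "B", "C"))
  sim <- sim_plate(seed = 7, layout = lay,
                   compound_effects = c(A = 0.5, B = 0.3, C = 0))
  res <- score_plate(sim$spots, sim$layout)
  hits <- res$hits$compound[res$hits$significant]
  expect_setequal(hits, c("A", "B"))
  expect_gt(res$ssmd, 3)
})

test_that("spot detection recovers constructed geometry and intensities", {
  # blank image
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_spots(blank, blank)), 0)

  # 5 bars (20 x 3) + 3 disks (r = 5) on a flat background
  img <- constructed_bar_disk_image()
  mrna <- matrix(50, 200, 200)
  sp <- detect_spots(img, mrna)
  expect_equal(nrow(sp), 8)
  ratios <- sort(sp$width / sp$length)
  expect_equal(ratios[1:5], rep(0.1414, 5), tolerance = 0.02)
  expect_equal(ratios[6:8], rep(1, 3), tolerance = 0.05)

  # planted per-bar mRNA intensities are recovered
  sim <- sim_well_image(seed = 5, n_bars = 6, dim = 160, noise_sd = 0)
  det <- detect_spots(sim$gfp, sim$mrna)
  det <- filter_spots(det)
  expect_equal(nrow(det), 6)
  truth_enr <- sort(sim$truth$enrichment)
  got_enr <- sort(det$mrna_spot_mean / det$mrna_cyto_mean)
  expect_equal(got_enr, truth_enr, tolerance = 0.05)
})

test_that("an image plate pipeline recovers the planted hit set", {
  lay <- plate_layout(compounds = c("A", "B"))
  sim <- sim_image_plate(seed = 3, layout = lay, n_bars = 40,
                         compound_effects = c(A = 0.6, B = 0.45))
  spots <- purrr::map_dfr(names(sim$images), function(w) {
    detect_spots(sim$images[[w]]$gfp, sim$images[[w]]$mrna, well_id = w)
  })
  res <- score_plate(spots, sim$layout, min_spots = 10)
  expect_setequal(res$hits$compound[res$hits$significant], c("A", "B"))
  # planted slope inside each bait well's CI
  bait <- res$wells[tolower(res$wells$role) == "dmso", ]
  expect_true(all(bait$ci95_low <= 0.003 & 0.003 <= bait$ci95_high))
})
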