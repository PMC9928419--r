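#' Seeded synthetic-data generators
#'
#' Every `sim_*()` generator is deterministic given its `seed`, draws from
#' a stage-specific random stream (so adding one generator call never
#' perturbs another stage's fixtures), and returns its planted ground
#' truth alongside the data. The generators emulate the statistical
#' structure each estimator assumes - Ornstein-Uhlenbeck energy noise,
#' Gaussian fluctuation-theorem work pairs, 1:1 fast-exchange titration
#' shifts, planted-slope spot fields - not the underlying physics.
#'
#' @name synthetic
#' @keywords internal
NULL

# stage-specific stream splitting: mix the user seed with the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 7919L + h %% 7919L
}

#' Simulate an interaction-energy trace with OU noise
#'
#' Per-frame ligand-water enthalpy follows an Ornstein-Uhlenbeck process
#' around `H_LW_mean`; the pocket-vs-water difference follows an
#' independent OU process with planted mean `ddH_mean` and stationary SD
#' `ddH_sd` (the paper-typical fluctuation scale is 2-7 kcal/mol);
#' H_LP = H_LW + ddH by construction.
#'
#' @param seed integer seed
#' @param n_frames number of frames (>= 2)
#' @param ddH_mean,ddH_sd planted mean and stationary SD of the
#'   pocket-vs-water enthalpy difference, kcal/mol
#' @param H_LW_mean,H_LW_sd ligand-water baseline, kcal/mol
#' @param tau correlation time in ns (> 0)
#' @param t_total trajectory length in ns
#' @param ligand_id label
#' @return A list: `trace` (an [energy_trace()]) and `truth`
#'   (`ddH_mean`, `ddH_sd`, `tau`, `phi`).
#' @export
sim_energy_trace <- function(seed = 1L, n_frames = 5000, ddH_mean = -5,
                             ddH_sd = 3, H_LW_mean = -40, H_LW_sd = 4,
                             tau = 0.05, t_total = 10,
                             ligand_id = "synthetic") {
  stopifnot(n_frames >= 2)
  if (tau <= 0) stop("correlation time must be positive", call. = FALSE)
  dt <- t_total / (n_frames - 1)
  phi <- exp(-dt / tau)
  ou <- function(mu, sdev) {
    x <- numeric(n_frames)
    x[1] <- stats::rnorm(1, mu, sdev)
    innov <- stats::rnorm(n_frames - 1, 0, sdev * sqrt(1 - phi^2))
    for (i in 2:n_frames) x[i] <- mu + phi * (x[i - 1] - mu) + innov[i - 1]
    x
  }
  with_local_seed(stage_seed(seed, "energy"), {
    hlw <- ou(H_LW_mean, H_LW_sd)
    ddh <- ou(ddH_mean, ddH_sd)
    list(
      trace = energy_trace(seq(0, t_total, length.out = n_frames),
                           H_LP = hlw + ddh, H_LW = hlw,
                           ligand_id = ligand_id),
      truth = list(ddH_mean = ddH_mean, ddH_sd = ddH_sd, tau = tau,
                   phi = phi)
    )
  })
}

#' Simulate fluctuation-theorem-consistent lambda-window work samples
#'
#' Per window i, forward work samples are N(dF_i + sigma^2/(2RT),
#' sigma^2) and reverse samples N(-dF_i + sigma^2/(2RT), sigma^2) - the
#' Gaussian pair satisfying the Crooks fluctuation theorem, so BAR must
#' recover dF_i without bias. Defaults: 40 equally loaded windows.
#'
#' @param seed integer seed
#' @param n_windows number of lambda windows
#' @param n_samples samples per direction per window
#' @param dG_total planted total free-energy change, split evenly across
#'   windows (or give `dF_windows` directly)
#' @param dF_windows optional vector of per-window free energies
#' @param sigma Gaussian work SD per window, kcal/mol
#' @param temperature K
#' @return A list: `samples` (tibble `window,direction,du_kcal`) and
#'   `truth` (`dF_windows`, `dG_total`, `sigma`, `temperature`).
#' @export
sim_bar_windows <- function(seed = 1L, n_windows = 40, n_samples = 5000,
                            dG_total = 10, dF_windows = NULL, sigma = 2.5,
                            temperature = default_temperature()) {
  stopifnot(sigma > 0, n_windows >= 1, n_samples >= 1)
  if (is.null(dF_windows)) {
    dF_windows <- rep(dG_total / n_windows, n_windows)
  }
  stopifnot(length(dF_windows) == n_windows)
  rt <- gas_constant_kcal() * temperature
  diss <- sigma^2 / (2 * rt)
  with_local_seed(stage_seed(seed, "bar"), {
    samples <- purrr::map_dfr(seq_len(n_windows), function(i) {
      tibble::tibble(
        window = i,
        direction = rep(c("fwd", "rev"), each = n_samples),
        du_kcal = c(stats::rnorm(n_samples, dF_windows[i] + diss, sigma),
                    stats::rnorm(n_samples, -dF_windows[i] + diss, sigma))
      )
    })
    list(samples = samples,
         truth = list(dF_windows = dF_windows, dG_total = sum(dF_windows),
                      sigma = sigma, temperature = temperature))
  })
}

#' Simulate a ligand-by-residue CSP matrix with planted structure
#'
#' Builds cluster prototype rows (each cluster raises a disjoint
#' signature set of residues), adds Gaussian noise, and appends outlier
#' rows with a much larger, matrix-wide perturbation. Default dimensions
#' follow the 15-ligand by 20-residue screening matrix.
#'
#' @param seed integer seed
#' @param n_ligands,n_residues matrix dimensions (outlier rows included
#'   in `n_ligands`)
#' @param n_clusters planted ligand clusters
#' @param n_outliers planted outlier rows
#' @param baseline background CSP level, ppm
#' @param signal signature-residue CSP amplitude, ppm
#' @param outlier_signal outlier amplitude, ppm
#' @param noise_sd Gaussian noise SD, ppm
#' @return A list: `matrix` (ligands x residues, non-negative) and
#'   `truth` (`cluster` integer labels with outliers as their own
#'   cluster(s), `outliers` row names).
#' @export
sim_csp_matrix <- function(seed = 1L, n_ligands = 15, n_residues = 20,
                           n_clusters = 4, n_outliers = 1,
                           baseline = 0.005, signal = 0.05,
                           outlier_signal = 0.15, noise_sd = 0.003) {
  n_regular <- n_ligands - n_outliers
  if (n_clusters > n_regular) {
    stop("more clusters than non-outlier ligands", call. = FALSE)
  }
  with_local_seed(stage_seed(seed, "csp"), {
    sig_sets <- split(sample(n_residues),
                      rep_len(seq_len(n_clusters), n_residues))
    proto <- matrix(baseline, n_clusters, n_residues)
    for (k in seq_len(n_clusters)) proto[k, sig_sets[[k]]] <- signal
    labels <- sort(rep_len(seq_len(n_clusters), n_regular))
    m <- proto[labels, , drop = FALSE]
    if (n_outliers > 0) {
      out_rows <- matrix(outlier_signal * stats::runif(n_outliers * n_residues,
                                                       0.6, 1),
                         n_outliers, n_residues)
      m <- rbind(m, out_rows)
      labels <- c(labels, n_clusters + seq_len(n_outliers))
    }
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    m <- pmax(m, 0)
    rownames(m) <- paste0("L", seq_len(n_ligands))
    colnames(m) <- paste0("R", seq_len(n_residues))
    list(matrix = m,
         truth = list(cluster = stats::setNames(labels, rownames(m)),
                      outliers = rownames(m)[labels > n_clusters]))
  })
}

#' Simulate displacement-vector triplets with planted regimes
#'
#' Competitive residues receive w = a u + (1 - a) v (the ternary peak
#' sits between the two binary peaks, so ligand- and RNA-induced shifts
#' oppose each other); additive residues receive w = u + v with u and v
#' drawn at an acute angle (so their scalar product is positive by
#' construction). Gaussian noise is added to w.
#'
#' @param seed integer seed
#' @param n_residues number of residues
#' @param prop_competitive fraction of competitive residues
#' @param alpha interior mixing coefficient, strictly in (0, 1)
#' @param effect_size typical displacement magnitude, scaled ppm
#' @param noise_sd Gaussian noise SD on each w component, scaled ppm
#' @return A list: `triplets` (tibble accepted by [competition_sp()]) and
#'   `truth` (`regime` per residue).
#' @export
sim_competition <- function(seed = 1L, n_residues = 40,
                            prop_competitive = 0.5, alpha = 0.5,
                            effect_size = 0.05, noise_sd = 0) {
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  with_local_seed(stage_seed(seed, "competition"), {
    n_comp <- round(n_residues * prop_competitive)
    regime <- sample(c(rep("competition", n_comp),
                       rep("additive", n_residues - n_comp)))
    ang_u <- stats::runif(n_residues, 0, 2 * pi)
    mag_u <- effect_size * stats::runif(n_residues, 0.7, 1.3)
    mag_v <- effect_size * stats::runif(n_residues, 0.7, 1.3)
    # additive pairs at an acute angle; competitive pairs wide apart
    dang <- ifelse(regime == "additive",
                   stats::runif(n_residues, -pi / 3, pi / 3),
                   stats::runif(n_residues, 2 * pi / 3, 4 * pi / 3))
    ang_v <- ang_u + dang
    u <- cbind(mag_u * cos(ang_u), mag_u * sin(ang_u))
    v <- cbind(mag_v * cos(ang_v), mag_v * sin(ang_v))
    w <- matrix(0, n_residues, 2)
    comp <- regime == "competition"
    w[comp, ] <- alpha * u[comp, , drop = FALSE] +
      (1 - alpha) * v[comp, , drop = FALSE]
    w[!comp, ] <- u[!comp, , drop = FALSE] + v[!comp, , drop = FALSE]
    w <- w + matrix(stats::rnorm(2 * n_residues, 0, noise_sd), n_residues)
    triplets <- tibble::tibble(
      residue = paste0("R", seq_len(n_residues)),
      uH = u[, 1], uN = u[, 2], vH = v[, 1], vN = v[, 2],
      wH = w[, 1], wN = w[, 2]
    )
    list(triplets = triplets,
         truth = list(regime = stats::setNames(regime, triplets$residue)))
  })
}

#' Simulate a 1:1 fast-exchange NMR titration
#'
#' Observed shifts interpolate linearly between free and bound positions
#' with the fraction bound from the exact (quadratic) 1:1 binding mass
#' balance, so every residue's titration path is a straight line in the
#' shift plane. Defaults follow a 16-point titration of a 50 uM protein
#' with ligand from 10 to 1000 uM.
#'
#' @param seed integer seed
#' @param Kd planted dissociation constant, uM (> 0)
#' @param protein_conc protein concentration, uM
#' @param ligand_concs titration ligand concentrations, uM
#' @param n_residues number of shifting residues
#' @param max_dH,max_dN largest bound-state displacements, ppm
#' @param noise_sd measurement noise on each shift, ppm
#' @return A list: `series` (long tibble `conc,residue,dH_ppm,dN_ppm`
#'   accepted by [titration_linearity()]) and `truth` (`Kd`,
#'   `bound_dH`, `bound_dN`, `fraction_bound`).
#' @export
sim_titration <- function(seed = 1L, Kd = 50, protein_conc = 50,
                          ligand_concs = exp(seq(log(10), log(1000),
                                                 length.out = 16)),
                          n_residues = 10, max_dH = 0.12, max_dN = 0.8,
                          noise_sd = 0) {
  if (Kd <= 0) stop("`Kd` must be positive", call. = FALSE)
  with_local_seed(stage_seed(seed, "titration"), {
    free_H <- stats::runif(n_residues, 7, 9.5)
    free_N <- stats::runif(n_residues, 105, 130)
    bound_dH <- stats::runif(n_residues, 0.3, 1) * max_dH *
      sample(c(-1, 1), n_residues, TRUE)
    bound_dN <- stats::runif(n_residues, 0.3, 1) * max_dN *
      sample(c(-1, 1), n_residues, TRUE)
    fb <- vapply(ligand_concs, function(l) {
      s <- protein_conc + l + Kd
      c_complex <- (s - sqrt(s^2 - 4 * protein_conc * l)) / 2
      c_complex / protein_conc
    }, numeric(1))
    series <- purrr::map_dfr(seq_along(ligand_concs), function(i) {
      tibble::tibble(
        conc = ligand_concs[i],
        residue = paste0("R", seq_len(n_residues)),
        dH_ppm = free_H + fb[i] * bound_dH +
          stats::rnorm(n_residues, 0, noise_sd),
        dN_ppm = free_N + fb[i] * bound_dN +
          stats::rnorm(n_residues, 0, noise_sd)
      )
    })
    list(series = series,
         truth = list(Kd = Kd, bound_dH = bound_dH, bound_dN = bound_dN,
                      fraction_bound = fb))
  })
}

#' Simulate a one-site ITC titration
#'
#' Heats follow the single-site Wiseman isotherm under the default
#' small-molecule design (0.2 mL cell at 14 uM protein, 26 injections of
#' 1.5 uL titrant at 200 uM) with proportional Gaussian noise.
#'
#' @param seed integer seed
#' @param Kd,dH,n_sites planted binding parameters (uM, kcal/mol, -)
#' @param noise_frac noise SD as a fraction of the largest heat magnitude
#' @inheritParams itc_experiment
#' @return A list: `experiment` (an [itc_experiment()]) and `truth`.
#' @export
sim_itc <- function(seed = 1L, Kd = 6, dH = -10, n_sites = 1,
                    noise_frac = 0.01, cell_conc = 14, syringe_conc = 200,
                    injection_volumes = rep(1.5, 26), cell_volume = 0.2,
                    temperature = default_temperature()) {
  with_local_seed(stage_seed(seed, "itc"), {
    design <- itc_experiment(numeric(length(injection_volumes)),
                             cell_conc = cell_conc,
                             syringe_conc = syringe_conc,
                             injection_volumes = injection_volumes,
                             cell_volume = cell_volume,
                             temperature = temperature)
    q <- itc_model_heats(design, Kd = Kd, dH = dH, n_sites = n_sites)
    q <- q + stats::rnorm(length(q), 0, noise_frac * max(abs(q)))
    design$heats <- q
    list(experiment = design,
         truth = list(Kd = Kd, dH = dH, n_sites = n_sites))
  })
}

#' Default microtiter layout for simulated plates
#'
#' @param compounds character vector of treated compounds (quadruplicate
#'   wells each by default)
#' @param n_replicates replicate wells per compound and per DMSO control
#' @param n_gfp bait-free control wells
#' @return A layout tibble: `well_id`, `role`, `compound`,
#'   `concentration`, `replicate`.
#' @export
plate_layout <- function(compounds = character(), n_replicates = 4,
                         n_gfp = 4) {
  rows <- list(
    tibble::tibble(role = "dmso", compound = "DMSO", concentration = 0,
                   replicate = seq_len(n_replicates)),
    tibble::tibble(role = "gfp", compound = "GFP", concentration = 0,
                   replicate = seq_len(n_gfp))
  )
  if (length(compounds) > 0) {
    rows <- c(rows, list(
      tidyr::expand_grid(compound = compounds,
                         replicate = seq_len(n_replicates)) |>
        dplyr::mutate(role = "treated", concentration = 10)
    ))
  }
  layout <- dplyr::bind_rows(rows)
  layout$well_id <- sprintf("W%02d", seq_len(nrow(layout)))
  layout[, c("well_id", "role", "compound", "concentration", "replicate")]
}

#' Simulate a plate of spot tables with planted enrichment slopes
#'
#' Each well receives `n_cells` cells with 10-50 elongated spots each;
#' spot mRNA enrichment is `intercept + slope * gfp + noise`, with the
#' well slope set by its role: bait wells (dmso/positive) carry
#' `slope_bait`, bait-free wells (gfp/negative) slope 0, and treated
#' wells `slope_bait * (1 - effect)` where `effect` comes from
#' `compound_effects`. A fraction of round, low-elongation spots is
#' mixed in to exercise the shape filter.
#'
#' @param seed integer seed
#' @param layout a [plate_layout()] tibble
#' @param n_cells cells per well
#' @param slope_bait planted enrichment-vs-bait slope of untreated bait
#'   wells (per bait-intensity unit)
#' @param compound_effects named numeric vector: fractional slope
#'   decrease per treated compound (0 = inert, 0.5 = halves the slope)
#' @param intercept enrichment at zero bait
#' @param noise_sd enrichment noise SD
#' @param round_fraction fraction of non-elongated contaminant spots
#' @return A list: `spots` (spot tibble), `layout`, and `truth`
#'   (`slope` per well, `effect` per compound, `significant` compounds
#'   with effect > 0).
#' @export
sim_plate <- function(seed = 1L, layout = plate_layout(), n_cells = 40,
                      slope_bait = 0.003, compound_effects = NULL,
                      intercept = 1, noise_sd = 0.15,
                      round_fraction = 0.15) {
  stopifnot(all(c("well_id", "role") %in% names(layout)))
  if (is.null(compound_effects)) {
    trt <- unique(layout$compound[tolower(layout$role) == "treated"])
    compound_effects <- stats::setNames(rep(0, length(trt)), trt)
  }
  with_local_seed(stage_seed(seed, "plate"), {
    spots <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      role <- tolower(layout$role[i])
      slope <- switch(role,
        dmso = , positive = slope_bait,
        gfp = , negative = 0,
        treated = slope_bait *
          (1 - compound_effects[[layout$compound[i]]]),
        0)
      n_spots <- sum(sample(10:50, n_cells, replace = TRUE))
      gfp <- stats::runif(n_spots, 100, 1000)
      enr <- pmax(intercept + slope * gfp +
                    stats::rnorm(n_spots, 0, noise_sd), 0.05)
      round_spot <- stats::runif(n_spots) < round_fraction
      len <- stats::runif(n_spots, 15, 30)
      wid <- ifelse(round_spot,
                    len * stats::runif(n_spots, 0.5, 1),
                    len * stats::runif(n_spots, 0.05, 0.18))
      cyto <- 100
      tibble::tibble(
        well_id = layout$well_id[i],
        cell_id = paste0(layout$well_id[i], "_c",
                         sample(n_cells, n_spots, replace = TRUE)),
        spot_id = seq_len(n_spots),
        gfp_mean = gfp, mrna_spot_mean = enr * cyto,
        mrna_cyto_mean = cyto, gfp_cyto_mean = 20,
        width = wid, length = len
      )
    })
    slopes <- vapply(seq_len(nrow(layout)), function(i) {
      role <- tolower(layout$role[i])
      switch(role,
        dmso = , positive = slope_bait,
        gfp = , negative = 0,
        treated = slope_bait * (1 - compound_effects[[layout$compound[i]]]),
        0)
    }, numeric(1))
    list(spots = spots, layout = layout,
         truth = list(slope = stats::setNames(slopes, layout$well_id),
                      effect = compound_effects,
                      significant = names(compound_effects)[compound_effects > 0]))
  })
}

#' Simulate well-level control scores at a planted SSMD
#'
#' Draws positive and negative control well scores from Gaussians whose
#' standardised mean difference equals `ssmd_target` (equal group SDs),
#' mirroring a 96-well plate with 48 controls of each kind.
#'
#' @param seed integer seed
#' @param n_pos,n_neg wells per group
#' @param ssmd_target planted strictly standardised mean difference
#' @param mean_neg,mean_pos group means
#' @return A list: `pos`, `neg` (numeric vectors), `truth`.
#' @export
sim_control_wells <- function(seed = 1L, n_pos = 48, n_neg = 48,
                              ssmd_target = 8, mean_neg = 0, mean_pos = 1) {
  sdev <- (mean_pos - mean_neg) / (ssmd_target * sqrt(2))
  with_local_seed(stage_seed(seed, "wells"), {
    list(pos = stats::rnorm(n_pos, mean_pos, sdev),
         neg = stats::rnorm(n_neg, mean_neg, sdev),
         truth = list(ssmd = ssmd_target, sd = sdev))
  })
}

# rasterise a rotated bar (or a disk when half_len == half_wid) onto img
draw_blob <- function(img, cx, cy, half_len, half_wid, angle, value,
                      disk = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(max(half_len, half_wid)) + 1L
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  gy <- (rows - 0.5) - cy
  gx <- (cols - 0.5) - cx
  gx_m <- matrix(gx, length(rows), length(cols), byrow = TRUE)
  gy_m <- matrix(gy, length(rows), length(cols))
  if (disk) {
    inside <- gx_m^2 + gy_m^2 <= half_len^2
  } else {
    alo <- gx_m * cos(angle) + gy_m * sin(angle)
    ape <- -gx_m * sin(angle) + gy_m * cos(angle)
    inside <- abs(alo) <= half_len & abs(ape) <= half_wid
  }
  sub <- img[rows, cols]
  sub[inside] <- sub[inside] + value
  img[rows, cols] <- sub
  img
}

#' Simulate a two-channel well image with planted spot statistics
#'
#' Renders elongated bait-rich bars (and optionally round contaminant
#' disks) on a noisy background in the bait channel, and an mRNA channel
#' whose per-bar intensity follows
#' `cyto * (intercept + slope * bait_intensity)` - the planted
#' enrichment-vs-bait line that [detect_spots()] + [well_slope()] should
#' recover.
#'
#' @param seed integer seed
#' @param n_bars number of elongated spots
#' @param n_disks number of round contaminant spots
#' @param dim image dimension (square), pixels
#' @param slope,intercept planted enrichment line
#' @param bait_range range of bait intensities above background
#' @param bg_mean,bg_sd bait-channel background
#' @param cyto_mean mRNA cytoplasm level
#' @param bar_len,bar_halfwidth bar geometry, pixels
#' @param noise_sd pixel noise in both channels
#' @return A list: `gfp`, `mrna` (matrices) and `truth` (per-bar bait
#'   intensity and enrichment, plus `slope`, `intercept`).
#' @export
sim_well_image <- function(seed = 1L, n_bars = 30, n_disks = 0, dim = 256,
                           slope = 0.003, intercept = 1,
                           bait_range = c(200, 900), bg_mean = 30,
                           bg_sd = 5, cyto_mean = 100,
                           bar_len = 20, bar_halfwidth = 1.2,
                           noise_sd = 2) {
  with_local_seed(stage_seed(seed, "image"), {
    gfp <- matrix(stats::rnorm(dim * dim, bg_mean, bg_sd), dim, dim)
    mrna <- matrix(stats::rnorm(dim * dim, cyto_mean, noise_sd), dim, dim)
    margin <- bar_len + 4
    bait <- stats::runif(n_bars, bait_range[1], bait_range[2])
    enr <- intercept + slope * bait
    # minimum-separation placement so spots stay distinct components
    n_place <- n_bars + n_disks
    min_d2 <- (bar_len + 2)^2
    px <- numeric(n_place); py <- numeric(n_place)
    placed <- 0L
    tries <- 0L
    while (placed < n_place && tries < 20000L) {
      cand_x <- stats::runif(1, margin, dim - margin)
      cand_y <- stats::runif(1, margin, dim - margin)
      tries <- tries + 1L
      if (placed == 0L ||
          min((px[seq_len(placed)] - cand_x)^2 +
                (py[seq_len(placed)] - cand_y)^2) >= min_d2) {
        placed <- placed + 1L
        px[placed] <- cand_x; py[placed] <- cand_y
      }
    }
    if (placed < n_place) {
      # dense field: fall back to random placement for the remainder
      px[(placed + 1L):n_place] <- stats::runif(n_place - placed, margin,
                                                dim - margin)
      py[(placed + 1L):n_place] <- stats::runif(n_place - placed, margin,
                                                dim - margin)
    }
    cx <- px[seq_len(n_bars)]
    cy <- py[seq_len(n_bars)]
    ang <- stats::runif(n_bars, 0, pi)
    for (i in seq_len(n_bars)) {
      gfp <- draw_blob(gfp, cx[i], cy[i], bar_len / 2, bar_halfwidth,
                       ang[i], bait[i])
      mrna <- draw_blob(mrna, cx[i], cy[i], bar_len / 2, bar_halfwidth,
                        ang[i], cyto_mean * (enr[i] - 1))
    }
    if (n_disks > 0) {
      dx <- px[n_bars + seq_len(n_disks)]
      dy <- py[n_bars + seq_len(n_disks)]
      db <- stats::runif(n_disks, bait_range[1], bait_range[2])
      for (i in seq_len(n_disks)) {
        gfp <- draw_blob(gfp, dx[i], dy[i], 5, 5, 0, db[i], disk = TRUE)
      }
    }
    gfp <- pmax(gfp, 0)
    mrna <- pmax(mrna, 0)
    list(gfp = gfp, mrna = mrna,
         truth = list(bait = bait, enrichment = enr, slope = slope,
                      intercept = intercept, n_bars = n_bars,
                      n_disks = n_disks))
  })
}

#' Simulate a whole image plate with planted compound effects
#'
#' One [sim_well_image()] per layout row; bait wells carry
#' `slope_bait`, bait-free wells slope 0, treated wells
#' `slope_bait * (1 - effect)`.
#'
#' @inheritParams sim_plate
#' @param n_bars bars per well image
#' @param dim image size, pixels
#' @param ... forwarded to [sim_well_image()]
#' @return A list: `images` (named list of gfp/mrna pairs per well),
#'   `layout`, `truth` (as in [sim_plate()]).
#' @export
sim_image_plate <- function(seed = 1L, layout = plate_layout(),
                            slope_bait = 0.003, compound_effects = NULL,
                            n_bars = 40, dim = 192, ...) {
  if (is.null(compound_effects)) {
    trt <- unique(layout$compound[tolower(layout$role) == "treated"])
    compound_effects <- stats::setNames(rep(0, length(trt)), trt)
  }
  slopes <- vapply(seq_len(nrow(layout)), function(i) {
    role <- tolower(layout$role[i])
    switch(role,
      dmso = , positive = slope_bait,
      gfp = , negative = 0,
      treated = slope_bait * (1 - compound_effects[[layout$compound[i]]]),
      0)
  }, numeric(1))
  images <- lapply(seq_len(nrow(layout)), function(i) {
    sim_well_image(seed = seed + 131L * i, n_bars = n_bars, dim = dim,
                   slope = slopes[i], ...)[c("gfp", "mrna")]
  })
  names(images) <- layout$well_id
  list(images = images, layout = layout,
       truth = list(slope = stats::setNames(slopes, layout$well_id),
                    effect = compound_effects,
                    significant = names(compound_effects)[compound_effects > 0]))
}
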