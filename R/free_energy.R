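#' Bennett acceptance ratio estimate for one lambda window
#'
#' Solves the Bennett self-consistency equation for the free-energy
#' difference between two adjacent alchemical states from bidirectional
#' work samples. `du_forward` holds energy differences U(next) - U(current)
#' sampled in the current state; `du_reverse` holds U(current) - U(next)
#' sampled in the next state (each set is the "work" in its own sampling
#' direction, so a fluctuation-theorem-consistent pair has means
#' +dF + dissipation and -dF + dissipation respectively).
#'
#' The root is found by monotone bracketed root finding to 1e-8 kcal/mol;
#' the error is Bennett's asymptotic variance computed from the pooled
#' Fermi-weight form. Poor phase-space overlap is diagnosed via the
#' effective sample size of the Fermi weights; a degenerate window is
#' returned with `overlap_ok = FALSE`, an infinite error sentinel and a
#' warning rather than an error.
#'
#' @param du_forward,du_reverse energy-difference samples, kcal/mol
#' @param temperature temperature in K
#' @return A one-row tibble: `dF`, `err` (kcal/mol), `n_forward`,
#'   `n_reverse`, `overlap_ok`.
#' @examples
#' bar_estimate(rep(0, 10), rep(0, 10))   # identical states: dF = 0
#' @export
bar_estimate <- function(du_forward, du_reverse,
                         temperature = default_temperature()) {
  if (length(du_forward) == 0L || length(du_reverse) == 0L) {
    stop("both sample sets must be non-empty", call. = FALSE)
  }
  stopifnot(temperature > 0)
  if (any(!is.finite(du_forward)) || any(!is.finite(du_reverse))) {
    stop("work samples must be finite", call. = FALSE)
  }
  rt <- gas_constant_kcal() * temperature
  wf <- du_forward / rt
  wr <- du_reverse / rt
  nf <- length(wf)
  nr <- length(wr)
  m <- log(nf / nr)
  fermi <- function(x) stats::plogis(-x)

  # g(C) is strictly increasing in C; its root is the reduced dF
  g <- function(C) sum(fermi(m + wf - C)) - sum(fermi(-m + wr + C))
  guess <- (mean(wf) - mean(wr)) / 2
  span <- max(1, stats::sd(c(wf, -wr)), abs(guess))
  root <- stats::uniroot(g, interval = c(guess - 2 * span, guess + 2 * span),
                         extendInt = "upX", tol = 1e-8 / rt)$root

  # Bennett asymptotic variance, pooled-sample Fermi form
  t_all <- c(m + wf - root, -(-m + wr + root))
  w_pool <- fermi(t_all) * fermi(-t_all)       # 1 / (2 + 2 cosh t)
  var_red <- 1 / sum(w_pool) - (1 / nf + 1 / nr)
  var_red <- max(var_red, 0)

  # overlap diagnostic: with disjoint work distributions the Fermi
  # weights on at least one side collapse to numerical zero
  wbar_f <- mean(fermi(m + wf - root))
  wbar_r <- mean(fermi(-m + wr + root))
  overlap_ok <- is.finite(var_red) && min(wbar_f, wbar_r) > 1e-8 &&
    var_red < 1e6
  err <- sqrt(var_red) * rt
  if (!overlap_ok) {
    warning("poor phase-space overlap in BAR window; error set to Inf",
            call. = FALSE)
    err <- Inf
  }
  tibble::tibble(dF = root * rt, err = err, n_forward = nf, n_reverse = nr,
                 overlap_ok = overlap_ok)
}

#' BAR over a table of lambda windows
#'
#' @param samples a tibble with columns `window`, `direction`
#'   (`"fwd"`/`"rev"`) and `du_kcal`, e.g. from [read_window_samples()] or
#'   [sim_bar_windows()]
#' @inheritParams bar_estimate
#' @return A tibble with one row per window (ordered by `window`):
#'   `window`, `dF`, `err`, `n_forward`, `n_reverse`, `overlap_ok`.
#' @export
bar_windows <- function(samples, temperature = default_temperature()) {
  need <- c("window", "direction", "du_kcal")
  if (!all(need %in% names(samples))) {
    stop("`samples` must have columns window, direction, du_kcal", call. = FALSE)
  }
  if (!all(samples$direction %in% c("fwd", "rev"))) {
    stop("`direction` must be 'fwd' or 'rev'", call. = FALSE)
  }
  samples |>
    dplyr::group_by(.data$window) |>
    dplyr::group_modify(function(d, key) {
      bar_estimate(d$du_kcal[d$direction == "fwd"],
                   d$du_kcal[d$direction == "rev"],
                   temperature = temperature)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$window)
}

#' Read lambda-window samples from CSV
#'
#' @param path CSV with columns `window,direction,du_kcal`
#' @return A tibble suitable for [bar_windows()].
#' @export
read_window_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("window", "direction", "du_kcal")
  if (!all(need %in% names(df))) {
    stop("window CSV must have columns window, direction, du_kcal", call. = FALSE)
  }
  df
}

#' Sum per-window free energies
#'
#' Adds window free-energy differences along a leg of the alchemical
#' transformation; errors combine in quadrature under the
#' independent-window assumption.
#'
#' @param windows tibble with columns `dF` and `err` (e.g. from
#'   [bar_windows()])
#' @return One-row tibble: `dG`, `err`, `n_windows`.
#' @examples
#' sum_windows(tibble::tibble(dF = c(1, 2), err = c(0.3, 0.4)))  # 3 +/- 0.5
#' @export
sum_windows <- function(windows) {
  if (nrow(windows) == 0L) stop("no windows to sum", call. = FALSE)
  if (!all(c("dF", "err") %in% names(windows))) {
    stop("`windows` must have columns dF and err", call. = FALSE)
  }
  tibble::tibble(dG = sum(windows$dF),
                 err = sqrt(sum(windows$err^2)),
                 n_windows = nrow(windows))
}

#' Analytical free-energy cost of ligand restraints
#'
#' Free-energy correction for imposing one distance, two angle and three
#' dihedral harmonic restraints (potentials K/2 (x - x0)^2) on a decoupled
#' ligand, referred to the standard-state volume V0:
#'
#'   dG_r = -RT ln\[ 8 pi^2 V0 / (r0^2 sin(thetaA0) sin(thetaB0))
#'                  * sqrt(K_r K_thetaA K_thetaB K_phiA K_phiB K_phiC)
#'                  / (2 pi RT)^3 \]
#'
#' This closed form evaluates the harmonic configurational integral with
#' the geometric Jacobian r^2 sin(thetaA) sin(thetaB) frozen at the
#' restraint minimum (the stiff-spring limit);
#' [restraint_correction_quadrature()] evaluates the same integral
#' numerically, optionally with the full Jacobian.
#'
#' @param r0 reference distance, nm
#' @param thetaA0,thetaB0 reference angles, rad (strictly inside (0, pi))
#' @param K_r distance force constant, kcal mol^-1 nm^-2
#' @param K_thetaA,K_thetaB,K_phiA,K_phiB,K_phiC angle/dihedral force
#'   constants, kcal mol^-1 rad^-2
#' @param temperature K
#' @param V0 standard-state volume in nm^3 (1.6606 nm^3 for 1 M)
#' @return dG_r in kcal/mol (a numeric scalar).
#' @examples
#' restraint_correction(r0 = 0.5, thetaA0 = pi / 2, thetaB0 = pi / 2)
#' @export
restraint_correction <- function(r0, thetaA0, thetaB0,
                                 K_r = 1000,
                                 K_thetaA = 10, K_thetaB = 10,
                                 K_phiA = 10, K_phiB = 10, K_phiC = 10,
                                 temperature = default_temperature(),
                                 V0 = 1.6606) {
  ks <- c(K_r, K_thetaA, K_thetaB, K_phiA, K_phiB, K_phiC)
  stopifnot(r0 > 0, all(ks > 0), temperature > 0, V0 > 0)
  if (thetaA0 <= 0 || thetaA0 >= pi || thetaB0 <= 0 || thetaB0 >= pi) {
    stop("reference angles must lie strictly inside (0, pi)", call. = FALSE)
  }
  rt <- gas_constant_kcal() * temperature
  arg <- 8 * pi^2 * V0 / (r0^2 * sin(thetaA0) * sin(thetaB0)) *
    sqrt(prod(ks)) / (2 * pi * rt)^3
  -rt * log(arg)
}

#' @rdname restraint_correction
#' @param jacobian `"frozen"` integrates the six harmonic factors with the
#'   geometric Jacobian fixed at the minimum (the object the closed form
#'   evaluates exactly); `"full"` carries the r^2 and sin(theta) weights
#'   through the integrals, quantifying the stiff-spring approximation
#'   error of the closed form.
#' @export
restraint_correction_quadrature <- function(r0, thetaA0, thetaB0,
                                            K_r = 1000,
                                            K_thetaA = 10, K_thetaB = 10,
                                            K_phiA = 10, K_phiB = 10,
                                            K_phiC = 10,
                                            temperature = default_temperature(),
                                            V0 = 1.6606,
                                            jacobian = c("frozen", "full")) {
  jacobian <- match.arg(jacobian)
  stopifnot(r0 > 0, temperature > 0)
  rt <- gas_constant_kcal() * temperature
  beta <- 1 / rt
  gau <- function(k, x0, x) exp(-beta * k / 2 * (x - x0)^2)
  int <- function(f, lower, upper) {
    stats::integrate(f, lower, upper, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }
  # the 6-D integral is separable, so the product of 1-D quadratures is exact
  if (jacobian == "frozen") {
    I_r <- r0^2 * int(function(r) gau(K_r, r0, r), 0, Inf)
    I_tA <- sin(thetaA0) * int(function(t) gau(K_thetaA, thetaA0, t), 0, pi)
    I_tB <- sin(thetaB0) * int(function(t) gau(K_thetaB, thetaB0, t), 0, pi)
  } else {
    I_r <- int(function(r) r^2 * gau(K_r, r0, r), 0, Inf)
    I_tA <- int(function(t) sin(t) * gau(K_thetaA, thetaA0, t), 0, pi)
    I_tB <- int(function(t) sin(t) * gau(K_thetaB, thetaB0, t), 0, pi)
  }
  I_phi <- vapply(c(K_phiA, K_phiB, K_phiC), function(k) {
    int(function(p) gau(k, 0, p), -pi, pi)
  }, numeric(1))
  z <- I_r * I_tA * I_tB * prod(I_phi)
  -rt * log(8 * pi^2 * V0 / z)
}

#' Assemble the absolute-binding thermodynamic cycle
#'
#' Combines the decoupling free energy in the complex, the ligand
#' (de)solvation leg and the analytical restraint correction into the
#' binding free energy. Sign convention (fixed here, once): both
#' `dG_complex` and `dG_solv` are decoupling free energies (fully coupled
#' to fully decoupled, in complex and in solvent respectively) and
#'
#'   dG_bind = -dG_complex + dG_solv + dG_restraint
#'
#' @param dG_complex,dG_solv,dG_restraint leg free energies, kcal/mol
#' @param err_complex,err_solv,err_restraint leg errors, combined in
#'   quadrature
#' @return One-row tibble: `dG_complex`, `dG_solv`, `dG_restraint`,
#'   `dG_bind`, `err_bind`.
#' @export
assemble_cycle <- function(dG_complex, dG_solv, dG_restraint,
                           err_complex = 0, err_solv = 0, err_restraint = 0) {
  vals <- c(dG_complex, dG_solv, dG_restraint)
  if (any(!is.finite(vals))) {
    stop("all three cycle terms must be finite", call. = FALSE)
  }
  tibble::tibble(
    dG_complex = dG_complex, dG_solv = dG_solv, dG_restraint = dG_restraint,
    dG_bind = -dG_complex + dG_solv + dG_restraint,
    err_bind = sqrt(err_complex^2 + err_solv^2 + err_restraint^2)
  )
}

#' Convert a binding free energy to a dissociation constant (and back)
#'
#' Kd = exp(dG / RT) * 1 M, with dG the (negative, for favourable binding)
#' binding free energy; `kd_to_dg()` is the exact inverse.
#'
#' @param dG binding free energy, kcal/mol
#' @param temperature K
#' @return `dg_to_kd()`: Kd in mol/L; `kd_to_dg()`: dG in kcal/mol.
#' @examples
#' dg_to_kd(-7.14) * 1e6   # ~6 micromolar
#' @export
dg_to_kd <- function(dG, temperature = default_temperature()) {
  stopifnot(temperature > 0)
  exp(dG / (gas_constant_kcal() * temperature))
}

#' @rdname dg_to_kd
#' @param Kd dissociation constant in mol/L
#' @export
kd_to_dg <- function(Kd, temperature = default_temperature()) {
  stopifnot(temperature > 0, all(Kd > 0))
  gas_constant_kcal() * temperature * log(Kd)
}

#' Apply the binding-affinity hit thresholds
#'
#' Ligands that passed the trajectory filter outright are hits when their
#' binding free energy magnitude reaches 5.5 kcal/mol; ligands that only
#' passed as "possible" are held to a stricter 6.5 kcal/mol.
#'
#' @param dG binding free energies, kcal/mol (vectorised)
#' @param possible_flag logical: was the ligand only a "possible" in the
#'   trajectory filter?
#' @param hit_threshold,possible_threshold magnitude cutoffs, kcal/mol
#' @return Character vector, `"hit"` or `"rejected"`.
#' @examples
#' classify_dg(c(-5.6, -6.0), possible_flag = c(FALSE, TRUE))
#' @export
classify_dg <- function(dG, possible_flag = FALSE,
                        hit_threshold = 5.5, possible_threshold = 6.5) {
  stopifnot(all(is.finite(dG)))
  n <- max(length(dG), length(possible_flag))
  dG <- rep_len(dG, n)
  possible_flag <- rep_len(possible_flag, n)
  cut <- ifelse(possible_flag, possible_threshold, hit_threshold)
  ifelse(abs(dG) >= cut, "hit", "rejected")
}
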