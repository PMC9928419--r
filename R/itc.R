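#' Describe an isothermal titration calorimetry experiment
#'
#' Bundles the titration design (cell/syringe concentrations, injection
#' schedule, cell volume) with the observed injection heats. The default
#' design mirrors a typical small-molecule titration: a 0.2 mL cell at
#' 14 uM protein receiving 26 injections of 1.5 uL titrant at 200 uM.
#'
#' @param heats injection heats, ucal (one per injection)
#' @param cell_conc protein concentration in the cell, uM
#' @param syringe_conc titrant concentration in the syringe, uM
#' @param injection_volumes injection volumes, uL
#' @param cell_volume cell volume, mL
#' @param temperature K
#' @return A list of class `itc_experiment`.
#' @export
itc_experiment <- function(heats,
                           cell_conc = 14, syringe_conc = 200,
                           injection_volumes = rep(1.5, length(heats)),
                           cell_volume = 0.2,
                           temperature = default_temperature()) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0,
            all(injection_volumes > 0), temperature > 0)
  if (length(heats) != length(injection_volumes)) {
    stop("`heats` and `injection_volumes` must have equal length", call. = FALSE)
  }
  structure(list(heats = heats, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 cell_volume = cell_volume, temperature = temperature),
            class = "itc_experiment")
}

# Per-injection cell concentrations under the constant-volume overflow
# model: each injection displaces (and expels) a well-mixed fraction
# v/V0 of the cell content before the new titrant is accounted for.
itc_concentrations <- function(exp) {
  v0 <- exp$cell_volume * 1000   # uL
  m <- exp$cell_conc
  x <- 0
  out <- matrix(0, nrow = length(exp$injection_volumes), ncol = 3,
                dimnames = list(NULL, c("M", "X", "dilution")))
  for (i in seq_along(exp$injection_volumes)) {
    d <- exp$injection_volumes[i] / v0
    m <- m * (1 - d)
    x <- x * (1 - d) + exp$syringe_conc * d
    out[i, ] <- c(m, x, d)
  }
  out
}

#' Predicted one-site injection heats (Wiseman isotherm)
#'
#' Computes the heat of each injection under a single-site binding model
#' with dissociation constant `Kd`, molar enthalpy `dH` and stoichiometry
#' `n_sites`, using dilution-corrected cell concentrations. The bound
#' ligand after each injection comes from the quadratic (exact mass
#' balance) solution; the heat is the enthalpy of newly formed complex in
#' the cell, net of complex expelled by the injection.
#'
#' @param exp an [itc_experiment()]
#' @param Kd dissociation constant, uM
#' @param dH binding enthalpy, kcal/mol
#' @param n_sites binding stoichiometry
#' @return Numeric vector of heats, ucal.
#' @export
itc_model_heats <- function(exp, Kd, dH, n_sites = 1) {
  stopifnot(inherits(exp, "itc_experiment"), Kd > 0)
  conc <- itc_concentrations(exp)
  bound_prev <- 0
  v0_l <- exp$cell_volume / 1000  # L
  q <- numeric(nrow(conc))
  for (i in seq_len(nrow(conc))) {
    s <- n_sites * conc[i, "M"] + conc[i, "X"] + Kd
    b <- (s - sqrt(s^2 - 4 * n_sites * conc[i, "M"] * conc[i, "X"])) / 2
    # ucal = kcal/mol * 1e3 cal/kcal * (uM -> mol/L: 1e-6) * L * 1e6 ucal/cal
    q[i] <- dH * 1000 * v0_l * (b - bound_prev * (1 - conc[i, "dilution"]))
    bound_prev <- b
  }
  q
}

#' Fit a one-site binding isotherm to ITC heats
#'
#' Least-squares fit of the single-site isotherm (Kd, dH, stoichiometry)
#' to dilution-corrected injection heats. A flat heat curve is flagged
#' non-identifiable (`fit_ok = FALSE`); a negative fitted stoichiometry
#' triggers a warning.
#'
#' @param exp an [itc_experiment()]
#' @return An object of class `itc_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods; `$estimates`
#'   is a one-row tibble (`Kd_uM`, `dH_kcal`, `n_sites`, `rss`, `fit_ok`).
#' @export
fit_one_site <- function(exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  q <- exp$heats
  if (length(q) < 6L) stop("at least 6 injections are required", call. = FALSE)
  flat <- diff(range(q)) < max(1e-9, 1e-6 * max(abs(q), 1e-12))
  if (flat) {
    warning("flat heat curve: one-site model is non-identifiable", call. = FALSE)
    est <- tibble::tibble(Kd_uM = NA_real_, dH_kcal = NA_real_,
                          n_sites = NA_real_, rss = 0, fit_ok = FALSE)
    return(structure(list(estimates = est, fit = NULL, experiment = exp),
                     class = "itc_fit"))
  }
  df <- data.frame(q = q)
  dh0 <- sum(q) / (1000 * exp$cell_volume / 1000 *
                     min(exp$cell_conc,
                         sum(exp$injection_volumes) * exp$syringe_conc /
                           (exp$cell_volume * 1000)))
  start <- list(lKd = log(exp$cell_conc / 2),
                dH = if (is.finite(dh0) && dh0 != 0) dh0 else -5,
                n = 1)
  fit <- try(minpack.lm::nlsLM(
    q ~ itc_model_heats(exp, exp(lKd), dH, n),
    data = df, start = start,
    lower = c(lKd = log(1e-4), dH = -1e3, n = 1e-3),
    upper = c(lKd = log(1e5), dH = 1e3, n = 50),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("one-site fit failed to converge", call. = FALSE)
    est <- tibble::tibble(Kd_uM = NA_real_, dH_kcal = NA_real_,
                          n_sites = NA_real_, rss = NA_real_, fit_ok = FALSE)
    return(structure(list(estimates = est, fit = NULL, experiment = exp),
                     class = "itc_fit"))
  }
  cf <- stats::coef(fit)
  if (cf[["n"]] <= 0.01) {
    warning("fitted stoichiometry is not positive", call. = FALSE)
  }
  est <- tibble::tibble(Kd_uM = exp(cf[["lKd"]]), dH_kcal = cf[["dH"]],
                        n_sites = cf[["n"]],
                        rss = sum(stats::resid(fit)^2), fit_ok = TRUE)
  structure(list(estimates = est, fit = fit, experiment = exp),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  print(x$estimates)
  invisible(x)
}
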