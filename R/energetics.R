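#' Build an interaction-energy trace
#'
#' An energy trace holds per-frame ligand-protein (`H_LP`) and ligand-water
#' (`H_LW`) interaction enthalpies along a short molecular-dynamics
#' trajectory. Traces tagged `"kJ/mol"` are converted to kcal/mol on
#' construction so that all downstream scoring works in kcal/mol.
#'
#' @param time frame times in ns, strictly increasing
#' @param H_LP ligand-protein interaction enthalpy per frame
#' @param H_LW ligand-water interaction enthalpy per frame
#' @param ligand_id ligand label
#' @param unit `"kcal/mol"` (default) or `"kJ/mol"`
#' @return A tibble with columns `ligand_id`, `time`, `H_LP`, `H_LW`
#'   (kcal/mol), of class `energy_trace`.
#' @examples
#' energy_trace(c(0, 0.1), c(-10, -12), c(-4, -6))
#' @export
energy_trace <- function(time, H_LP, H_LW, ligand_id = "ligand",
                         unit = c("kcal/mol", "kJ/mol")) {
  unit <- match.arg(unit)
  if (length(time) < 2L) {
    stop("an energy trace needs at least two frames", call. = FALSE)
  }
  if (length(H_LP) != length(time) || length(H_LW) != length(time)) {
    stop("`time`, `H_LP` and `H_LW` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("frame times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(H_LP)) || any(!is.finite(H_LW))) {
    stop("energies must be finite", call. = FALSE)
  }
  if (unit == "kJ/mol") {
    H_LP <- kj_to_kcal(H_LP)
    H_LW <- kj_to_kcal(H_LW)
  }
  out <- tibble::tibble(ligand_id = ligand_id, time = time,
                        H_LP = H_LP, H_LW = H_LW)
  class(out) <- c("energy_trace", class(out))
  out
}

#' Read an energy trace from disk
#'
#' Accepts either a single CSV with columns `time,H_LP,H_LW` (and optional
#' `unit` column) or a pair of two-column whitespace files (time, energy),
#' one per interaction term.
#'
#' @param path CSV path, or the ligand-protein term when `path_lw` is given
#' @param path_lw optional path of the ligand-water two-column file
#' @param ligand_id ligand label
#' @param unit energy unit of the files
#' @return An [energy_trace()] tibble in kcal/mol.
#' @export
read_energy_trace <- function(path, path_lw = NULL, ligand_id = "ligand",
                              unit = c("kcal/mol", "kJ/mol")) {
  unit <- match.arg(unit)
  if (is.null(path_lw)) {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("time", "H_LP", "H_LW")
    if (!all(need %in% names(df))) {
      stop("energy CSV must have columns time, H_LP, H_LW", call. = FALSE)
    }
    if ("unit" %in% names(df)) {
      u <- unique(df$unit)
      if (length(u) != 1L) stop("mixed energy units in one trace", call. = FALSE)
      unit <- match.arg(u, c("kcal/mol", "kJ/mol"))
    }
    energy_trace(df$time, df$H_LP, df$H_LW, ligand_id = ligand_id, unit = unit)
  } else {
    lp <- readr::read_table(path, col_names = c("time", "H_LP"),
                            show_col_types = FALSE, comment = "#")
    lw <- readr::read_table(path_lw, col_names = c("time", "H_LW"),
                            show_col_types = FALSE, comment = "#")
    if (nrow(lp) != nrow(lw) || any(abs(lp$time - lw$time) > 1e-9)) {
      stop("the two energy files must share the same time base", call. = FALSE)
    }
    energy_trace(lp$time, lp$H_LP, lw$H_LW, ligand_id = ligand_id, unit = unit)
  }
}

#' Enthalpic preference of a ligand for the pocket over water
#'
#' Computes the per-frame difference between ligand-protein and ligand-water
#' interaction enthalpies, ddH = H_LP - H_LW, and summarises it over the
#' trajectory. A negative mean says the ligand prefers the pocket; the
#' standard deviation quantifies the fluctuation of that preference (for
#' drug-sized ligands it typically falls between 2 and 7 kcal/mol).
#'
#' @param trace an [energy_trace()] (or any data frame with `H_LP`, `H_LW`)
#' @return A one-row tibble with `ligand_id`, `ddH_mean`, `ddH_sd`
#'   (sample SD, n-1 denominator) and `n_frames`, in kcal/mol.
#' @examples
#' tr <- energy_trace(c(0, 1), c(-10, -12), c(-4, -6))
#' delta_delta_H(tr)   # mean -6, sd 0
#' @export
delta_delta_H <- function(trace) {
  if (!all(c("H_LP", "H_LW") %in% names(trace))) {
    stop("`trace` must have columns H_LP and H_LW", call. = FALSE)
  }
  if (nrow(trace) < 2L) {
    stop("at least two frames are required", call. = FALSE)
  }
  ddh <- trace$H_LP - trace$H_LW
  tibble::tibble(
    ligand_id = if ("ligand_id" %in% names(trace)) trace$ligand_id[1] else "ligand",
    ddH_mean = mean(ddh),
    ddH_sd = stats::sd(ddh),
    n_frames = length(ddh)
  )
}

#' Build a ligand-protein contact set
#'
#' @param ligand_atom,protein_atom parallel vectors of atom identifiers; each
#'   row is one interatomic contact (duplicated pairs are collapsed).
#' @param ligand_id ligand label
#' @return A tibble of unique contacts with class `contact_set`.
#' @export
contact_set <- function(ligand_atom, protein_atom, ligand_id = "ligand") {
  out <- tibble::tibble(ligand_id = ligand_id,
                        ligand_atom = as.character(ligand_atom),
                        protein_atom = as.character(protein_atom))
  out <- dplyr::distinct(out)
  class(out) <- c("contact_set", class(out))
  out
}

#' @rdname contact_set
#' @param path CSV with columns `ligand_atom,protein_atom`
#' @export
read_contacts <- function(path, ligand_id = "ligand") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("ligand_atom", "protein_atom") %in% names(df))) {
    stop("contact CSV must have columns ligand_atom, protein_atom", call. = FALSE)
  }
  contact_set(df$ligand_atom, df$protein_atom, ligand_id = ligand_id)
}

#' Contacts per interacting ligand atom
#'
#' The contact ratio c is the number of unique ligand-protein interatomic
#' contacts divided by the number of distinct ligand atoms involved; c >= 1
#' whenever the set is non-empty, and larger values flag ligand atoms that
#' each engage several pocket atoms.
#'
#' @param contacts a [contact_set()] (or data frame with `ligand_atom`,
#'   `protein_atom`)
#' @return A one-row tibble with `ligand_id`, `n_contacts`,
#'   `n_ligand_atoms`, `c`. An empty set returns `c = 0` with a warning
#'   (the ligand is effectively unbound).
#' @examples
#' cs <- contact_set(c("a", "a", "b", "c", "c", "c"), 1:6)
#' contact_ratio(cs)$c   # 6 contacts / 3 atoms = 2
#' @export
contact_ratio <- function(contacts) {
  if (!all(c("ligand_atom", "protein_atom") %in% names(contacts))) {
    stop("`contacts` must have columns ligand_atom and protein_atom", call. = FALSE)
  }
  uni <- dplyr::distinct(tibble::as_tibble(contacts)[c("ligand_atom", "protein_atom")])
  n_contacts <- nrow(uni)
  n_atoms <- dplyr::n_distinct(uni$ligand_atom)
  if (n_contacts == 0L) {
    warning("empty contact set: ligand is effectively unbound (c = 0)",
            call. = FALSE)
    cr <- 0
  } else {
    cr <- n_contacts / n_atoms
  }
  tibble::tibble(
    ligand_id = if ("ligand_id" %in% names(contacts) && nrow(contacts) > 0)
      contacts$ligand_id[1] else "ligand",
    n_contacts = n_contacts,
    n_ligand_atoms = n_atoms,
    c = cr
  )
}

#' Default weights of the trajectory filter score
#'
#' The filter score is S = w_c * c + w_ddH * ddH_mean with default weights
#' w_c = 4 and w_ddH = -1, so a high contact ratio and a pocket-favouring
#' (negative) enthalpy difference both push S upward.
#'
#' @param w_c weight of the contact ratio
#' @param w_ddH weight of the mean enthalpy difference
#' @return A named list of class `score_weights`.
#' @export
score_weights <- function(w_c = 4, w_ddH = -1) {
  stopifnot(is.finite(w_c), is.finite(w_ddH))
  structure(list(w_c = w_c, w_ddH = w_ddH), class = "score_weights")
}

#' Score ligands and classify them as hits
#'
#' Combines the enthalpic observable and the contact ratio into the weighted
#' score S and applies the hit rules: a ligand that left the pocket during
#' the short refinement run is `left_pocket`; otherwise S > 0 is a `hit`;
#' S <= 0 is `possible` when the statistical error rescues it, and
#' `rejected` otherwise. Two error policies are available: the default
#' declares `possible` when S + sd(ddH) > 0 (the error-adjusted score turns
#' positive); `"sd_exceeds_mean"` instead requires sd(ddH) > |mean(ddH)|.
#'
#' @param scores a data frame with columns `ddH_mean`, `ddH_sd`, `c`, and
#'   optionally `ligand_id` and `stayed_in_pocket` (default `TRUE`)
#' @param weights a [score_weights()] object
#' @param possible_policy `"error_adjusted"` (default) or `"sd_exceeds_mean"`
#' @return The input tibble with columns `S` and `classification`
#'   (`hit`, `possible`, `rejected`, `left_pocket`) appended.
#' @examples
#' score_and_classify(tibble::tibble(ddH_mean = -3, ddH_sd = 2, c = 2))
#' @export
score_and_classify <- function(scores, weights = score_weights(),
                               possible_policy = c("error_adjusted",
                                                   "sd_exceeds_mean")) {
  possible_policy <- match.arg(possible_policy)
  stopifnot(inherits(weights, "score_weights"))
  need <- c("ddH_mean", "ddH_sd", "c")
  if (!all(need %in% names(scores))) {
    stop("`scores` must have columns ddH_mean, ddH_sd, c", call. = FALSE)
  }
  df <- tibble::as_tibble(scores)
  if (!"stayed_in_pocket" %in% names(df)) df$stayed_in_pocket <- TRUE
  if (!"ligand_id" %in% names(df)) {
    df <- tibble::add_column(df, ligand_id = paste0("L", seq_len(nrow(df))),
                             .before = 1)
  }
  if (any(!is.finite(df$ddH_mean)) || any(!is.finite(df$ddH_sd)) ||
      any(!is.finite(df$c))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (any(df$ddH_sd < 0)) stop("ddH_sd must be non-negative", call. = FALSE)
  S <- weights$w_c * df$c + weights$w_ddH * df$ddH_mean
  rescued <- if (possible_policy == "error_adjusted") {
    S + df$ddH_sd > 0
  } else {
    df$ddH_sd > abs(df$ddH_mean)
  }
  df$S <- S
  df$classification <- dplyr::case_when(
    !df$stayed_in_pocket ~ "left_pocket",
    S > 0 ~ "hit",
    rescued ~ "possible",
    TRUE ~ "rejected"
  )
  df
}

#' One-call trajectory filter for a single ligand
#'
#' Convenience wrapper: computes [delta_delta_H()] from the trace,
#' [contact_ratio()] from the contact set, and classifies with
#' [score_and_classify()].
#'
#' @inheritParams delta_delta_H
#' @inheritParams contact_ratio
#' @inheritParams score_and_classify
#' @param stayed_in_pocket did the ligand remain bound during the short MD?
#' @return A one-row classified score tibble.
#' @export
filter_score <- function(trace, contacts, stayed_in_pocket = TRUE,
                         weights = score_weights(), ...) {
  dd <- delta_delta_H(trace)
  cr <- contact_ratio(contacts)
  score_and_classify(
    tibble::tibble(ligand_id = dd$ligand_id, ddH_mean = dd$ddH_mean,
                   ddH_sd = dd$ddH_sd, c = cr$c,
                   stayed_in_pocket = stayed_in_pocket),
    weights = weights, ...
  )
}
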