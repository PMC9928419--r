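#' Estimate a dissociation constant from titration shift trajectories
#'
#' Under 1:1 fast exchange each residue's displacement from the first
#' titration point grows proportionally to the change in fraction bound,
#' d_r(L) = A_r * (fb(Kd, L) - fb(Kd, L1)). For a candidate Kd the
#' per-residue amplitudes A_r have a closed-form least-squares solution,
#' leaving a one-dimensional profile objective in Kd that is minimised
#' by golden-section search over a wide log range.
#'
#' @param series long tibble `conc,residue,dH_ppm,dN_ppm` (>= 4 points)
#' @param protein_conc protein concentration, same unit as `conc`
#' @param nscale 15N weight for the shift plane
#' @param kd_range search interval for Kd (same unit as `conc`)
#' @return A one-row tibble: `Kd`, `rss`, `n_residues`.
#' @export
fit_shift_titration <- function(series, protein_conc,
                                nscale = default_nitrogen_scale(),
                                kd_range = c(0.1, 1e5)) {
  need <- c("conc", "residue", "dH_ppm", "dN_ppm")
  stopifnot(all(need %in% names(series)), protein_conc > 0)
  concs <- sort(unique(series$conc))
  if (length(concs) < 4L) {
    stop("at least 4 titration points are required", call. = FALSE)
  }
  wide <- series |>
    dplyr::arrange(.data$residue, .data$conc) |>
    dplyr::group_by(.data$residue) |>
    dplyr::mutate(disp = sqrt((.data$dH_ppm - dplyr::first(.data$dH_ppm))^2 +
                                (nscale * (.data$dN_ppm -
                                             dplyr::first(.data$dN_ppm)))^2)) |>
    dplyr::ungroup()
  fb <- function(kd, l) {
    s <- protein_conc + l + kd
    ((s - sqrt(s^2 - 4 * protein_conc * l)) / 2) / protein_conc
  }
  rss_of <- function(log_kd) {
    kd <- exp(log_kd)
    g <- fb(kd, wide$conc) - fb(kd, min(concs))
    sum(unlist(lapply(split(seq_len(nrow(wide)), wide$residue), function(i) {
      gi <- g[i]; di <- wide$disp[i]
      if (sum(gi^2) == 0) return(sum(di^2))
      a <- sum(di * gi) / sum(gi^2)
      sum((di - a * gi)^2)
    })))
  }
  opt <- stats::optimize(rss_of, log(kd_range))
  tibble::tibble(Kd = exp(opt$minimum), rss = opt$objective,
                 n_residues = dplyr::n_distinct(series$residue))
}
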