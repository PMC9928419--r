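#' Build or read an NMR peak table
#'
#' A peak table holds assigned amide crosspeak positions for one condition
#' (apo protein, protein + ligand, ...): one row per residue with its 1H
#' and 15N chemical shifts in ppm. Side-chain entries (e.g. "W65sc") are
#' ordinary rows with their own identifiers.
#'
#' @param residue residue identifiers, unique within the table
#' @param dH_ppm,dN_ppm 1H and 15N shifts, ppm
#' @param condition_id condition label
#' @return A tibble with class `peak_table`.
#' @export
peak_table <- function(residue, dH_ppm, dN_ppm, condition_id = "condition") {
  residue <- as.character(residue)
  if (anyDuplicated(residue)) {
    stop("residue identifiers must be unique within a condition", call. = FALSE)
  }
  if (any(!is.finite(dH_ppm)) || any(!is.finite(dN_ppm))) {
    stop("chemical shifts must be finite", call. = FALSE)
  }
  out <- tibble::tibble(condition_id = condition_id, residue = residue,
                        dH_ppm = dH_ppm, dN_ppm = dN_ppm)
  class(out) <- c("peak_table", class(out))
  out
}

#' @rdname peak_table
#' @param path CSV with columns `residue,dH_ppm,dN_ppm`
#' @export
read_peak_table <- function(path, condition_id = "condition") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "dH_ppm", "dN_ppm") %in% names(df))) {
    stop("peak CSV must have columns residue, dH_ppm, dN_ppm", call. = FALSE)
  }
  peak_table(df$residue, df$dH_ppm, df$dN_ppm, condition_id = condition_id)
}

#' Weighted-average chemical shift perturbation per residue
#'
#' Combines the 1H and 15N displacements between a reference and a bound
#' condition into a single per-residue perturbation. The default form is
#' the root-mean-square convention
#' sqrt(0.5 * (dH^2 + (0.14 dN)^2)); `form = "literal"` returns the
#' squared variant 0.5 * (dH^2 + (0.14 dN)^2) instead (same ranking,
#' squared-ppm units).
#'
#' Residues present in only one of the two tables are reported in the
#' `unmatched` attribute (and via a message), never silently dropped.
#'
#' @param ref,bound [peak_table()]s for the two conditions
#' @param nscale 15N weight (default 0.14)
#' @param form `"sqrt"` (default) or `"literal"`
#' @return A tibble `residue`, `csp` (ppm for `"sqrt"`), with attribute
#'   `unmatched`.
#' @examples
#' a <- peak_table("G1", 8.00, 110.0)
#' b <- peak_table("G1", 8.03, 110.2)
#' csp(a, b)$csp   # sqrt(0.5 * (0.03^2 + 0.028^2)) = 0.029
#' @export
csp <- function(ref, bound, nscale = default_nitrogen_scale(),
                form = c("sqrt", "literal")) {
  form <- match.arg(form)
  shared <- intersect(ref$residue, bound$residue)
  if (length(shared) == 0L) {
    stop("no shared residues between the two conditions", call. = FALSE)
  }
  unmatched <- union(setdiff(ref$residue, bound$residue),
                     setdiff(bound$residue, ref$residue))
  if (length(unmatched) > 0L) {
    message("residues present in only one condition: ",
            paste(unmatched, collapse = ", "))
  }
  r <- ref[match(shared, ref$residue), ]
  b <- bound[match(shared, bound$residue), ]
  sq <- 0.5 * ((b$dH_ppm - r$dH_ppm)^2 + (nscale * (b$dN_ppm - r$dN_ppm))^2)
  out <- tibble::tibble(residue = shared,
                        csp = if (form == "sqrt") sqrt(sq) else sq)
  attr(out, "unmatched") <- unmatched
  out
}

#' Mean perturbation over a binding-pocket residue set
#'
#' @param csp_tbl a tibble with columns `residue` and `csp` (from [csp()])
#' @param pocket character vector of pocket residue identifiers
#' @return Arithmetic mean CSP over the pocket residues (scalar).
#' @export
pocket_average <- function(csp_tbl, pocket) {
  stopifnot(length(pocket) > 0)
  missing <- setdiff(pocket, csp_tbl$residue)
  if (length(missing) > 0L) {
    stop("pocket residues missing from the CSP table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mean(csp_tbl$csp[csp_tbl$residue %in% pocket])
}

#' Call a ligand a binder from its CSP profile
#'
#' Default policy: a ligand is a binder when its mean pocket CSP exceeds
#' the mean plus `n_sd` standard deviations of the non-pocket residues'
#' CSPs (the within-spectrum background). The policy needs at least three
#' non-pocket residues to estimate that background.
#'
#' @inheritParams pocket_average
#' @param n_sd background multiplier (default 1)
#' @return A one-row tibble: `pocket_mean`, `background_mean`,
#'   `background_sd`, `threshold`, `verdict` (`"binder"`/`"non-binder"`).
#' @export
binding_call <- function(csp_tbl, pocket, n_sd = 1) {
  pm <- pocket_average(csp_tbl, pocket)
  bg <- csp_tbl$csp[!csp_tbl$residue %in% pocket]
  if (length(bg) < 3L) {
    stop("need at least 3 non-pocket residues to estimate the background",
         call. = FALSE)
  }
  thr <- mean(bg) + n_sd * stats::sd(bg)
  tibble::tibble(pocket_mean = pm, background_mean = mean(bg),
                 background_sd = stats::sd(bg), threshold = thr,
                 verdict = ifelse(pm > thr, "binder", "non-binder"))
}

#' Displacement-vector triplets for RNA-competition analysis
#'
#' From four peak tables (apo, +ligand, +RNA, +RNA+ligand) builds, per
#' residue, the three displacement vectors from the apo position in the
#' scaled (1H, 0.14 x 15N) plane: u (ligand only), v (RNA only) and
#' w (RNA + ligand).
#'
#' @param apo,ligand,rna,both [peak_table()]s for the four conditions
#' @param nscale 15N weight
#' @return A tibble with columns `residue`, `uH,uN,vH,vN,wH,wN`
#'   (scaled ppm). Residues missing any condition are skipped and listed
#'   in the `skipped` attribute.
#' @export
shift_triplets <- function(apo, ligand, rna, both,
                           nscale = default_nitrogen_scale()) {
  shared <- Reduce(intersect, list(apo$residue, ligand$residue,
                                   rna$residue, both$residue))
  all_res <- Reduce(union, list(apo$residue, ligand$residue,
                                rna$residue, both$residue))
  skipped <- setdiff(all_res, shared)
  if (length(skipped) > 0L) {
    message("residues missing a condition, skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(shared) == 0L) stop("no residue has all four conditions", call. = FALSE)
  disp <- function(tab) {
    i <- match(shared, tab$residue)
    j <- match(shared, apo$residue)
    cbind(H = tab$dH_ppm[i] - apo$dH_ppm[j],
          N = nscale * (tab$dN_ppm[i] - apo$dN_ppm[j]))
  }
  u <- disp(ligand); v <- disp(rna); w <- disp(both)
  out <- tibble::tibble(residue = shared,
                        uH = u[, "H"], uN = u[, "N"],
                        vH = v[, "H"], vN = v[, "N"],
                        wH = w[, "H"], wN = w[, "N"])
  attr(out, "skipped") <- skipped
  out
}

#' Scalar-product competition statistic per residue
#'
#' For each residue, SP = (v - w) . (u - w) built from the ligand-only
#' (u), RNA-only (v) and RNA-plus-ligand (w) displacement vectors.
#' Residues whose ligand- and RNA-induced shifts move in opposite
#' directions relative to the ternary condition give SP < 0
#' ("competition"); same-direction shifts give SP > 0 ("additive");
#' values within `epsilon` of zero are "indeterminate".
#'
#' @param triplets a tibble as returned by [shift_triplets()] (columns
#'   `uH,uN,vH,vN,wH,wN`)
#' @param epsilon dead-band half-width in scaled ppm^2
#' @return The input with columns `SP` and `regime` appended.
#' @examples
#' tr <- tibble::tibble(residue = "V84", uH = 0.05, uN = 0.01,
#'                      vH = -0.03, vN = 0.02, wH = 0.01, wN = 0.015)
#' competition_sp(tr)
#' @export
competition_sp <- function(triplets, epsilon = 1e-6) {
  need <- c("uH", "uN", "vH", "vN", "wH", "wN")
  if (!all(need %in% names(triplets))) {
    stop("`triplets` must have columns uH,uN,vH,vN,wH,wN", call. = FALSE)
  }
  sp <- (triplets$vH - triplets$wH) * (triplets$uH - triplets$wH) +
    (triplets$vN - triplets$wN) * (triplets$uN - triplets$wN)
  out <- tibble::as_tibble(triplets)
  out$SP <- sp
  out$regime <- dplyr::case_when(
    sp < -epsilon ~ "competition",
    sp > epsilon ~ "additive",
    TRUE ~ "indeterminate"
  )
  out
}

#' Saturation transfer difference quantities
#'
#' For each ligand proton computes the fractional STD
#' A_STD = (I_off - I_on) / I_off, the amplification factor
#' STD_AF = A_STD * \[L\]/\[E\], and the relative STD percentage obtained
#' by normalising against the largest A_STD (assigned 100%). Typical
#' epitope-mapping conditions use a large ligand excess (e.g. 500 uM
#' ligand over 10 uM protein).
#'
#' @param records a tibble with columns `proton`, `I_on`, `I_off`
#' @param L_total,E_total total ligand and protein concentrations (same
#'   unit, e.g. uM)
#' @return The input with `A_STD`, `STD_AF` and `rel_percent` appended;
#'   if every A_STD is zero `rel_percent` is `NA` and a warning is given.
#' @export
std_quantities <- function(records, L_total, E_total) {
  stopifnot(L_total > 0, E_total > 0)
  if (!all(c("proton", "I_on", "I_off") %in% names(records))) {
    stop("`records` must have columns proton, I_on, I_off", call. = FALSE)
  }
  if (any(records$I_off <= 0)) stop("I_off must be positive", call. = FALSE)
  out <- tibble::as_tibble(records)
  out$A_STD <- (out$I_off - out$I_on) / out$I_off
  out$STD_AF <- out$A_STD * L_total / E_total
  mx <- max(out$A_STD)
  if (mx <= 0) {
    warning("all A_STD are zero: relative percentages undefined", call. = FALSE)
    out$rel_percent <- NA_real_
  } else {
    out$rel_percent <- 100 * out$A_STD / mx
  }
  out
}

#' Linearity of titration trajectories in the shift plane
#'
#' In 1:1 fast exchange, increasing ligand concentration moves each
#' residue's crosspeak along a straight line between the free and bound
#' positions; curvature betrays a second binding mode. For each residue
#' the titration path in the scaled (1H, 0.14 x 15N) plane is fitted by
#' total least squares (first principal axis); R^2 is the share of
#' variance captured by that axis.
#'
#' @param series a long tibble with columns `conc`, `residue`, `dH_ppm`,
#'   `dN_ppm` covering at least 4 titration points
#' @param nscale 15N weight
#' @param r2_threshold linearity cutoff for the `single-mode` verdict
#' @param min_move minimum total displacement (scaled ppm) below which a
#'   residue is called `not-shifting`
#' @return A tibble per residue: `residue`, `movement`, `r_squared`,
#'   `verdict` (`single-mode` / `multi-mode` / `not-shifting`).
#' @export
titration_linearity <- function(series, nscale = default_nitrogen_scale(),
                                r2_threshold = 0.98, min_move = 0.005) {
  need <- c("conc", "residue", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns conc, residue, dH_ppm, dN_ppm",
         call. = FALSE)
  }
  if (dplyr::n_distinct(series$conc) < 4L) {
    stop("at least 4 titration points are required", call. = FALSE)
  }
  series |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_modify(function(d, key) {
      xy <- cbind(d$dH_ppm, nscale * d$dN_ppm)
      move <- sqrt(sum((xy[which.max(d$conc), ] - xy[which.min(d$conc), ])^2))
      if (move < min_move) {
        return(tibble::tibble(movement = move, r_squared = NA_real_,
                              verdict = "not-shifting"))
      }
      ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
      r2 <- ev[1] / sum(ev)
      tibble::tibble(movement = move, r_squared = r2,
                     verdict = ifelse(r2 >= r2_threshold,
                                      "single-mode", "multi-mode"))
    }) |>
    dplyr::ungroup()
}
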