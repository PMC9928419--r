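#' Detect elongated bait-rich spots in a two-channel field
#'
#' Re-implements a "find spots" scheme for microtubule-bench images: the
#' bait (GFP) channel is thresholded at background mean + `k_sigma` SDs,
#' connected components are extracted, and each component's length and
#' width are derived from its second-moment (inertia) matrix as
#' 4 sqrt(eigenvalue) - the axes of the ellipse with equal moments. Per
#' spot, the mean bait and mRNA intensities are recorded together with
#' the cytoplasmic mRNA mean taken over the non-spot, non-nucleus region.
#'
#' @param gfp,mrna numeric matrices of identical dimension (single plane,
#'   non-negative): bait and mRNA channels
#' @param nucleus_mask optional logical matrix; `TRUE` pixels are
#'   excluded from the cytoplasm estimate
#' @param k_sigma threshold in background SDs above the background mean
#' @param min_pixels discard components smaller than this
#' @param well_id,cell_id labels stamped on the output rows
#' @return A tibble of spots: `well_id`, `cell_id`, `spot_id`,
#'   `gfp_mean`, `mrna_spot_mean`, `mrna_cyto_mean`, `gfp_cyto_mean`,
#'   `width`, `length`, `n_pixels`. Blank images give zero rows.
#' @export
detect_spots <- function(gfp, mrna, nucleus_mask = NULL, k_sigma = 3,
                         min_pixels = 4, well_id = "well", cell_id = "cell") {
  stopifnot(is.matrix(gfp), is.matrix(mrna), all(dim(gfp) == dim(mrna)))
  if (any(gfp < 0) || any(mrna < 0)) {
    stop("images must be non-negative", call. = FALSE)
  }
  if (is.null(nucleus_mask)) {
    nucleus_mask <- matrix(FALSE, nrow(gfp), ncol(gfp))
  }
  if (max(gfp) > 0 && mean(gfp >= max(gfp) * 0.999) > 0.25) {
    warning("bait channel looks saturated", call. = FALSE)
  }
  # robust background statistics: spots are sparse, so the median and MAD
  # of the whole field estimate the background mean and SD
  thr <- stats::median(gfp) + k_sigma * stats::mad(gfp)
  mask <- gfp > thr & !nucleus_mask
  empty <- tibble::tibble(
    well_id = character(), cell_id = character(), spot_id = integer(),
    gfp_mean = double(), mrna_spot_mean = double(),
    mrna_cyto_mean = double(), gfp_cyto_mean = double(),
    width = double(), length = double(), n_pixels = integer()
  )
  if (!any(mask) || !is.finite(thr)) return(empty)

  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels@.Data)
  keep <- lab > 0L
  idx <- which(keep)
  rows <- (idx - 1L) %% nrow(gfp) + 1L
  cols <- (idx - 1L) %/% nrow(gfp) + 1L
  comp <- lab[idx]

  cyto <- !mask & !nucleus_mask
  mrna_cyto <- mean(mrna[cyto])
  gfp_cyto <- mean(gfp[cyto])

  per <- split(seq_along(comp), comp)
  spots <- purrr::map_dfr(seq_along(per), function(i) {
    sel <- per[[i]]
    if (length(sel) < min_pixels) return(NULL)
    x <- cols[sel] - 0.5   # pixel-centred coordinates
    y <- rows[sel] - 0.5
    mu <- cbind(x - mean(x), y - mean(y))
    mom <- crossprod(mu) / length(sel)
    evs <- eigen(mom, symmetric = TRUE, only.values = TRUE)$values
    evs <- pmax(evs, 1 / 12)  # a 1-px-wide line still has pixel extent
    pix <- idx[sel]
    tibble::tibble(
      spot_id = i,
      gfp_mean = mean(gfp[pix]),
      mrna_spot_mean = mean(mrna[pix]),
      width = 4 * sqrt(evs[2]), length = 4 * sqrt(evs[1]),
      n_pixels = length(sel)
    )
  })
  if (nrow(spots) == 0L) return(empty)
  spots$well_id <- well_id
  spots$cell_id <- cell_id
  spots$mrna_cyto_mean <- mrna_cyto
  spots$gfp_cyto_mean <- gfp_cyto
  spots[, names(empty)]
}

#' Keep microtubule-shaped, bait-enriched spots
#'
#' Retains spots whose width-to-length ratio is strictly below
#' `ratio_max` (elongated, filament-like shapes; a spot exactly at the
#' boundary is excluded) and, when the bait cytoplasm level is available,
#' whose bait intensity exceeds `bait_enrichment_min` times it.
#'
#' @param spots a spot tibble (from [detect_spots()], [read_spots()] or
#'   [sim_plate()])
#' @param ratio_max width/length cutoff (strict `<`)
#' @param bait_enrichment_min minimum spot/cytoplasm bait ratio; ignored
#'   when the table has no `gfp_cyto_mean` column
#' @return The surviving subset of `spots` (same columns).
#' @examples
#' s <- tibble::tibble(width = c(1, 2.2), length = c(10, 10))
#' nrow(filter_spots(s))   # 1: 0.22 is excluded by the strict inequality
#' @export
filter_spots <- function(spots, ratio_max = 0.22, bait_enrichment_min = 2) {
  stopifnot(all(c("width", "length") %in% names(spots)))
  if (nrow(spots) == 0L) return(spots)
  if (any(spots$width > spots$length) || any(spots$width <= 0)) {
    stop("spots must satisfy length >= width > 0", call. = FALSE)
  }
  keep <- spots$width / spots$length < ratio_max
  if ("gfp_cyto_mean" %in% names(spots) && !is.null(bait_enrichment_min)) {
    keep <- keep & spots$gfp_mean > bait_enrichment_min * spots$gfp_cyto_mean
  }
  spots[keep, , drop = FALSE]
}

#' Read a spot table from CSV
#'
#' @param path CSV with columns
#'   `well,cell,spot,gfp_mean,mrna_spot,mrna_cyto,width,length`
#' @return A spot tibble with the package's canonical column names.
#' @export
read_spots <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well", "cell", "spot", "gfp_mean", "mrna_spot", "mrna_cyto",
            "width", "length")
  if (!all(need %in% names(df))) {
    stop("spot CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::tibble(well_id = as.character(df$well),
                 cell_id = as.character(df$cell),
                 spot_id = df$spot, gfp_mean = df$gfp_mean,
                 mrna_spot_mean = df$mrna_spot,
                 mrna_cyto_mean = df$mrna_cyto,
                 width = df$width, length = df$length)
}

#' mRNA enrichment of a spot over the cytoplasm
#'
#' @param spots spot tibble with `mrna_spot_mean` and `mrna_cyto_mean`
#' @return The input with an `enrichment` column
#'   (`mrna_spot_mean / mrna_cyto_mean`); spots with no cytoplasmic
#'   signal are dropped with a message.
#' @export
enrichment <- function(spots) {
  stopifnot(all(c("mrna_spot_mean", "mrna_cyto_mean") %in% names(spots)))
  bad <- spots$mrna_cyto_mean <= 0
  if (any(bad)) {
    message(sum(bad), " spot(s) dropped: zero cytoplasmic mRNA signal")
    spots <- spots[!bad, , drop = FALSE]
  }
  spots$enrichment <- spots$mrna_spot_mean / spots$mrna_cyto_mean
  spots
}

#' Per-well regression of mRNA enrichment on bait intensity
#'
#' Ordinary least squares of spot mRNA enrichment on spot bait (GFP)
#' intensity over all spots of a well; the slope is the well's
#' RNA-binding score and carries a t-distribution 95% confidence
#' interval. Wells with fewer than `min_spots` spots, or with no bait
#' variance, are flagged unusable.
#'
#' @param spots spot tibble for one or more wells (needs `well_id`,
#'   `gfp_mean` and `enrichment`; run [enrichment()] first if needed)
#' @param min_spots minimum spots per well
#' @return A tibble per well: `well_id`, `slope`, `intercept`,
#'   `ci95_low`, `ci95_high`, `n_spots`, `n_cells`, `usable`.
#' @export
well_slope <- function(spots, min_spots = 30) {
  if (!"enrichment" %in% names(spots)) spots <- enrichment(spots)
  stopifnot(all(c("well_id", "gfp_mean") %in% names(spots)))
  spots |>
    dplyr::group_by(.data$well_id) |>
    dplyr::group_modify(function(d, key) {
      n_cells <- if ("cell_id" %in% names(d)) dplyr::n_distinct(d$cell_id) else NA_integer_
      if (nrow(d) < min_spots) {
        return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                              ci95_low = NA_real_, ci95_high = NA_real_,
                              n_spots = nrow(d), n_cells = n_cells,
                              usable = FALSE))
      }
      if (stats::sd(d$gfp_mean) == 0) {
        return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                              ci95_low = NA_real_, ci95_high = NA_real_,
                              n_spots = nrow(d), n_cells = n_cells,
                              usable = FALSE))
      }
      fit <- stats::lm(enrichment ~ gfp_mean, data = d)
      cf <- stats::coef(fit)
      se <- summary(fit)$coefficients["gfp_mean", "Std. Error"]
      tq <- stats::qt(0.975, df = nrow(d) - 2)
      tibble::tibble(slope = cf[["gfp_mean"]], intercept = cf[["(Intercept)"]],
                     ci95_low = cf[["gfp_mean"]] - tq * se,
                     ci95_high = cf[["gfp_mean"]] + tq * se,
                     n_spots = nrow(d), n_cells = n_cells, usable = TRUE)
    }) |>
    dplyr::ungroup()
}

#' Normalise well slopes to the plate's control anchors
#'
#' Per-plate affine rescaling that sends the mean slope of the bait-free
#' (GFP-only) control wells to 0 and the mean slope of the DMSO-treated
#' bait wells to 1, so treated wells read directly as a fraction of the
#' untreated RNA-binding score.
#'
#' @param slopes a tibble from [well_slope()] joined with a plate layout:
#'   needs columns `slope` and `role` (`"gfp"`, `"dmso"`, `"treated"`,
#'   optionally `"positive"`/`"negative"` aliases for dmso/gfp)
#' @return The input with a `normalized_slope` column.
#' @export
normalize_plate <- function(slopes) {
  stopifnot(all(c("slope", "role") %in% names(slopes)))
  role <- tolower(slopes$role)
  lo_set <- role %in% c("gfp", "negative")
  hi_set <- role %in% c("dmso", "positive")
  usable <- if ("usable" %in% names(slopes)) slopes$usable else TRUE
  if (!any(lo_set & usable) || !any(hi_set & usable)) {
    stop("plate needs usable bait-free (gfp/negative) and DMSO-bait ",
         "(dmso/positive) control wells", call. = FALSE)
  }
  lo <- mean(slopes$slope[lo_set & usable])
  hi <- mean(slopes$slope[hi_set & usable])
  if (hi == lo) stop("control means coincide; cannot normalise", call. = FALSE)
  out <- tibble::as_tibble(slopes)
  out$normalized_slope <- (out$slope - lo) / (hi - lo)
  out
}

#' Strictly standardised mean difference between control groups
#'
#' SSMD = (mean+ - mean-) / sqrt(sd+^2 + sd-^2) (default `"sumvar"`
#' variant); the `"pooled"` variant divides by the pooled SD instead
#' (with equal group SDs the two differ by sqrt(2)). Large SSMD means
#' the assay separates positive from negative controls well; compounds
#' must shift the readout by more than 1/SSMD of the control difference
#' to be detectable.
#'
#' @param pos,neg numeric vectors of well scores (>= 2 each)
#' @param variant `"sumvar"` (default) or `"pooled"`
#' @return SSMD (numeric scalar); `NaN` with a warning when both groups
#'   are degenerate.
#' @export
ssmd <- function(pos, neg, variant = c("sumvar", "pooled")) {
  variant <- match.arg(variant)
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 wells per group", call. = FALSE)
  }
  vp <- stats::var(pos); vn <- stats::var(neg)
  denom <- if (variant == "sumvar") {
    sqrt(vp + vn)
  } else {
    sqrt(((length(pos) - 1) * vp + (length(neg) - 1) * vn) /
           (length(pos) + length(neg) - 2))
  }
  if (denom == 0) {
    warning("zero variance in both control groups: SSMD undefined",
            call. = FALSE)
    return(NaN)
  }
  (mean(pos) - mean(neg)) / denom
}

#' Call compound hits against DMSO controls
#'
#' For each compound, pairs its replicate wells with the DMSO control
#' wells by replicate index and applies a two-tailed paired t-test on the
#' normalised slopes. A compound is a significant hit only when p <
#' `alpha` AND its mean normalised slope lies below the DMSO mean (only
#' decreases in RNA binding count). Optional Benjamini-Hochberg
#' correction across compounds.
#'
#' @param slopes normalised plate tibble (from [normalize_plate()]):
#'   needs `normalized_slope`, `role`, `compound`, `replicate`
#' @param alpha significance level
#' @param p_adjust `"none"` (default) or `"BH"`
#' @return A tibble per compound: `compound`, `mean_effect` (treated
#'   minus DMSO mean), `p_value`, `significant`.
#' @export
call_hits <- function(slopes, alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("normalized_slope", "role", "compound", "replicate")
  if (!all(need %in% names(slopes))) {
    stop("`slopes` must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  dmso <- slopes[tolower(slopes$role) == "dmso", ]
  if (nrow(dmso) == 0L) stop("no DMSO control wells", call. = FALSE)
  dmso <- dmso[order(dmso$replicate), ]
  treated <- slopes[tolower(slopes$role) == "treated", ]
  out <- treated |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$replicate), ]
      m <- match(d$replicate, dmso$replicate)
      if (any(is.na(m))) {
        stop("replicate pairing incomplete for a compound", call. = FALSE)
      }
      diffs <- d$normalized_slope - dmso$normalized_slope[m]
      if (any(is.na(diffs))) {
        warning("unusable wells dropped from a compound's replicate pairs",
                call. = FALSE)
        diffs <- diffs[!is.na(diffs)]
      }
      if (length(diffs) < 2L) {
        return(tibble::tibble(mean_effect = NA_real_, p_value = NA_real_))
      }
      if (stats::sd(diffs) < 1e-10 * max(1, abs(mean(diffs)))) {
        warning("zero-variance paired differences: degenerate test",
                call. = FALSE)
        p <- if (abs(mean(diffs)) < 1e-8) 1 else 0
      } else {
        p <- stats::t.test(diffs)$p.value
      }
      tibble::tibble(mean_effect = mean(diffs), p_value = p)
    }) |>
    dplyr::ungroup()
  p <- if (p_adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- !is.na(p) & p < alpha &
    !is.na(out$mean_effect) & out$mean_effect < 0
  out
}

#' Score a plate of spots end to end
#'
#' Convenience pipeline: shape-filter spots, compute enrichments,
#' regress per well, join the layout, normalise to the plate controls,
#' and call hits; also reports the plate SSMD from its control wells.
#'
#' @param spots spot tibble
#' @param layout tibble with `well_id`, `role`, `compound`,
#'   `concentration`, `replicate`
#' @param ratio_max,bait_enrichment_min passed to [filter_spots()]
#' @param min_spots passed to [well_slope()]
#' @param alpha passed to [call_hits()]
#' @return A list: `wells` (normalised slope tibble), `hits`, `ssmd`.
#' @export
score_plate <- function(spots, layout, ratio_max = 0.22,
                        bait_enrichment_min = 2, min_spots = 30,
                        alpha = 0.05) {
  stopifnot(all(c("well_id", "role") %in% names(layout)))
  wells <- spots |>
    filter_spots(ratio_max = ratio_max,
                 bait_enrichment_min = bait_enrichment_min) |>
    enrichment() |>
    well_slope(min_spots = min_spots) |>
    dplyr::inner_join(layout, by = "well_id") |>
    normalize_plate()
  role <- tolower(wells$role)
  s <- if (sum(role %in% c("dmso", "positive")) >= 2 &&
           sum(role %in% c("gfp", "negative")) >= 2) {
    ssmd(wells$normalized_slope[role %in% c("dmso", "positive")],
         wells$normalized_slope[role %in% c("gfp", "negative")])
  } else {
    NA_real_
  }
  hits <- if (any(role == "treated")) call_hits(wells, alpha = alpha) else NULL
  list(wells = wells, hits = hits, ssmd = s)
}
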