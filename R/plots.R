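#' Per-residue CSP bar chart
#'
#' @param csp_tbl tibble from [csp()]
#' @param pocket optional pocket residue set to highlight
#' @return A ggplot object.
#' @export
plot_csp <- function(csp_tbl, pocket = NULL) {
  d <- tibble::as_tibble(csp_tbl)
  d$pocket <- if (is.null(pocket)) FALSE else d$residue %in% pocket
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$csp,
                                  fill = .data$pocket)) +
    ggplot2::geom_col(show.legend = !is.null(pocket)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "weighted CSP (ppm)", fill = "pocket") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scalar-product competition histogram
#'
#' @param sp_tbl tibble from [competition_sp()]
#' @return A ggplot object: per-residue SP bars coloured by regime.
#' @export
plot_competition <- function(sp_tbl) {
  ggplot2::ggplot(sp_tbl, ggplot2::aes(x = .data$residue, y = .data$SP,
                                       fill = .data$regime)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(competition = "steelblue",
                                          additive = "orange2",
                                          indeterminate = "grey70")) +
    ggplot2::labs(x = NULL, y = "SP (scaled ppm²)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Normalised plate-slope overview
#'
#' @param wells normalised tibble from [normalize_plate()]
#' @return A ggplot object: normalised slope per well, grouped by role.
#' @export
plot_plate <- function(wells) {
  ggplot2::ggplot(wells, ggplot2::aes(x = .data$role,
                                      y = .data$normalized_slope,
                                      colour = .data$role)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "normalised mRNA enrichment slope") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- tibble::tibble(injection = seq_along(object$experiment$heats),
                      heat = object$experiment$heats)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$injection,
                                       y = .data$heat)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injection", y = "heat (µcal)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    e <- object$estimates
    d$fitted <- itc_model_heats(object$experiment, e$Kd_uM, e$dH_kcal,
                                e$n_sites)
    p <- p + ggplot2::geom_line(data = d,
                                ggplot2::aes(y = .data$fitted),
                                colour = "firebrick")
  }
  p
}

#' @export
autoplot.dose_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$response)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)",
                  y = "normalised slope") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    e <- object$estimates
    grid <- tibble::tibble(
      concentration = exp(seq(log(min(object$points$concentration)),
                              log(max(object$points$concentration)),
                              length.out = 100))
    )
    grid$response <- e$bottom + (e$top - e$bottom) /
      (1 + (grid$concentration / e$ec50)^e$hill)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' @export
autoplot.csp_pca <- function(object, ...) {
  d <- object$samples
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = factor(.data$cluster),
                                  shape = .data$outlier)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(colour = "cluster", shape = "outlier") +
    ggplot2::theme_minimal()
}
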