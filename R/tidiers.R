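#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a one-site ITC fit
#'
#' @param x an `itc_fit` from [fit_one_site()]
#' @param ... unused
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error` when the underlying fit converged).
#' @export
tidy.itc_fit <- function(x, ...) {
  est <- x$estimates
  out <- tibble::tibble(
    term = c("Kd_uM", "dH_kcal", "n_sites"),
    estimate = c(est$Kd_uM, est$dH_kcal, est$n_sites)
  )
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    # Kd is fitted on the log scale; delta-method SE back-transform
    se <- c(exp(stats::coef(x$fit)[["lKd"]]) * sm["lKd", "Std. Error"],
            sm["dH", "Std. Error"], sm["n", "Std. Error"])
    out$std.error <- se
  }
  out
}

#' @rdname tidy.itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(rss = x$estimates$rss, fit_ok = x$estimates$fit_ok,
                 n_injections = length(x$experiment$heats))
}

#' Tidy a four-parameter-logistic dose-response fit
#'
#' @param x a `dose_fit` from [fit_dose_response()]
#' @param ... unused
#' @return A tibble with one row per parameter.
#' @export
tidy.dose_fit <- function(x, ...) {
  est <- x$estimates
  out <- tibble::tibble(term = c("ec50", "hill", "top", "bottom"),
                        estimate = c(est$ec50, est$hill, est$top, est$bottom))
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    out$std.error <- sm[c("ec50", "hill", "top", "bottom"), "Std. Error"]
  }
  out
}

#' @rdname tidy.dose_fit
#' @export
glance.dose_fit <- function(x, ...) {
  tibble::tibble(compound = x$estimates$compound, rss = x$estimates$rss,
                 fit_ok = x$estimates$fit_ok,
                 n_points = nrow(x$points))
}

#' Tidy a CSP PCA mining result
#'
#' @param x a `csp_pca` from [pca_mine()]
#' @param what `"samples"` (scores, SPE, T2, outlier flags, clusters) or
#'   `"variance"` (per-component ratios)
#' @param ... unused
#' @return A tibble.
#' @export
tidy.csp_pca <- function(x, what = c("samples", "variance"), ...) {
  what <- match.arg(what)
  if (what == "samples") x$samples else x$variance
}

#' @rdname tidy.csp_pca
#' @export
glance.csp_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_components = x$n_components,
    cumulative_ratio = x$variance$cumulative_ratio[x$n_components],
    n_outliers = sum(x$samples$outlier),
    k_clusters = x$k_clusters
  )
}
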