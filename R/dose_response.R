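#' Fit a four-parameter logistic dose-response curve
#'
#' Fits normalised slope (or any response) against concentration with the
#' 4PL model on log-concentration:
#'
#'   y = bottom + (top - bottom) / (1 + (x / ec50)^hill)
#'
#' so an inhibitor running from top ~ 1 (untreated score) down to bottom
#' has a positive Hill slope and `ec50` is the critical concentration at
#' half effect. Requires at least 5 concentrations spanning >= 1.5
#' decades (a twofold series from 0.098 to 50 uM comfortably qualifies).
#' A response whose range does not exceed `noise_floor` is declared flat
#' (`fit_ok = FALSE`); gross non-monotonicity triggers a warning.
#'
#' @param points tibble with columns `concentration` (uM, > 0) and
#'   `response`
#' @param compound label carried into the result
#' @param noise_floor minimum response range deemed fittable
#' @return An object of class `dose_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods; `$estimates`
#'   is a one-row tibble (`compound`, `ec50`, `hill`, `top`, `bottom`,
#'   `rss`, `fit_ok`).
#' @export
fit_dose_response <- function(points, compound = "compound",
                              noise_floor = 0.1) {
  stopifnot(all(c("concentration", "response") %in% names(points)))
  if (any(points$concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  concs <- sort(unique(points$concentration))
  if (length(concs) < 5L) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  if (log10(max(concs) / min(concs)) < 1.5) {
    stop("concentration range must span at least 1.5 decades", call. = FALSE)
  }
  d <- tibble::as_tibble(points)
  fail <- function(msg = NULL) {
    if (!is.null(msg)) warning(msg, call. = FALSE)
    est <- tibble::tibble(compound = compound, ec50 = NA_real_,
                          hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_, fit_ok = FALSE)
    structure(list(estimates = est, fit = NULL, points = d),
              class = "dose_fit")
  }
  med <- d |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(m = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  if (diff(range(med$m)) < noise_floor) {
    return(fail())
  }
  runs <- sign(diff(med$m))
  if (length(unique(runs[runs != 0])) > 1 &&
      min(cumsum(runs == runs[1])) >= 0 &&
      sum(diff(sign(diff(med$m))) != 0) > length(med$m) / 2) {
    warning("response is grossly non-monotone", call. = FALSE)
  }
  top0 <- max(med$m); bot0 <- min(med$m)
  half <- (top0 + bot0) / 2
  ec0 <- med$concentration[which.min(abs(med$m - half))]
  fit <- try(minpack.lm::nlsLM(
    response ~ bottom + (top - bottom) / (1 + (concentration / ec50)^hill),
    data = d,
    start = list(bottom = bot0, top = top0, ec50 = ec0, hill = 1),
    lower = c(bottom = -Inf, top = -Inf, ec50 = min(concs) / 100, hill = 0.1),
    upper = c(bottom = Inf, top = Inf, ec50 = max(concs) * 100, hill = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail("4PL fit failed to converge"))
  cf <- stats::coef(fit)
  fit_ok <- cf[["ec50"]] >= min(concs) && cf[["ec50"]] <= max(concs)
  est <- tibble::tibble(compound = compound, ec50 = cf[["ec50"]],
                        hill = cf[["hill"]], top = cf[["top"]],
                        bottom = cf[["bottom"]],
                        rss = sum(stats::resid(fit)^2), fit_ok = fit_ok)
  structure(list(estimates = est, fit = fit, points = d),
            class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  print(x$estimates)
  invisible(x)
}
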