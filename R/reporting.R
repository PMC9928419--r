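#' Hit-rate summaries for screening campaigns
#'
#' `hit_rate()` expresses a hit count as a percentage of compounds
#' tested; `summarise_screen()` tabulates classification counts and
#' rates from a classified score table.
#'
#' @param n_hits number of hits
#' @param n_tested number of compounds tested (> 0)
#' @return Percentage (numeric scalar).
#' @examples
#' hit_rate(15, 17)   # NMR-confirmed binders among predicted hits
#' hit_rate(11, 22)   # cell-active among predicted hits
#' @export
hit_rate <- function(n_hits, n_tested) {
  stopifnot(n_tested > 0, n_hits >= 0, n_hits <= n_tested)
  100 * n_hits / n_tested
}

#' @rdname hit_rate
#' @param scored a classified tibble with a `classification` column
#'   (from [score_and_classify()])
#' @export
summarise_screen <- function(scored) {
  stopifnot("classification" %in% names(scored))
  scored |>
    dplyr::count(.data$classification, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
}
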