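#' Read a ligand-by-residue CSP matrix
#'
#' @param path CSV grid: first column ligand labels, remaining columns one
#'   per residue, cells holding weighted-average CSPs (ppm)
#' @return A numeric matrix with ligand rownames and residue colnames.
#' @export
read_csp_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("CSP matrix has missing cells", call. = FALSE)
  m
}

#' Mine a CSP matrix by PCA with outlier tests and clustering
#'
#' Column-mean-centred (optionally unit-variance-scaled) principal
#' component analysis of a ligand-by-residue CSP matrix (or its
#' transpose, to mine residues instead of ligands). Reports per-component
#' and cumulative explained-variance ratios, per-sample squared
#' prediction error (SPE, the residual after `n_components`) with its
#' Jackson-Mudholkar chi-square-approximation cutoff, Hotelling's T^2 in
#' the retained subspace with its F-distribution cutoff, outliers
#' (exceeding either cutoff at `1 - alpha`), a k-means clustering of the
#' retained scores, and the top-loading feature of each component.
#'
#' @param mat numeric matrix, samples in rows (e.g. 15 ligands x 20
#'   residues); or a tibble/data.frame with the first column holding
#'   sample labels
#' @param transpose analyse the transpose (residues as samples)?
#' @param n_components retained components (clipped with a warning if it
#'   exceeds what the matrix supports)
#' @param alpha significance level of the outlier cutoffs
#' @param k_clusters number of k-means clusters (50 restarts)
#' @param scale. unit-variance scaling (default: centring only, since all
#'   cells share ppm units)
#' @param seed RNG seed for the k-means restarts (local to this call)
#' @return An object of class `csp_pca`; see `$samples` (scores, SPE,
#'   T^2, outlier flag, cluster), `$variance` (per-component and
#'   cumulative ratios, top-loading feature), `$loadings`, `$cutoffs`.
#'   Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
pca_mine <- function(mat, transpose = FALSE, n_components = 6, alpha = 0.05,
                     k_clusters = 5, scale. = FALSE, seed = 1L) {
  if (is.data.frame(mat)) {
    labs <- as.character(mat[[1]])
    mat <- as.matrix(mat[, -1, drop = FALSE])
    rownames(mat) <- labs
    storage.mode(mat) <- "double"
  }
  if (any(!is.finite(mat))) {
    stop("matrix has missing cells; impute before mining", call. = FALSE)
  }
  if (transpose) mat <- t(mat)
  n <- nrow(mat)
  p <- ncol(mat)
  max_k <- min(n - 1L, p)
  if (n_components > max_k) {
    warning("n_components clipped to ", max_k, call. = FALSE)
    n_components <- max_k
  }
  k <- n_components
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  ratios <- ev / sum(ev)

  scores <- pc$x[, seq_len(k), drop = FALSE]
  recon <- scores %*% t(pc$rotation[, seq_len(k), drop = FALSE])
  resid <- scale(mat, center = pc$center,
                 scale = if (isTRUE(scale.)) pc$scale else FALSE) - recon
  spe <- rowSums(resid^2)

  # Jackson-Mudholkar SPE limit from the discarded eigenvalues
  lam_res <- ev[-seq_len(k)]
  if (length(lam_res) == 0L || sum(lam_res) < .Machine$double.eps) {
    spe_lim <- 0
  } else {
    th1 <- sum(lam_res); th2 <- sum(lam_res^2); th3 <- sum(lam_res^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-4
    ca <- stats::qnorm(1 - alpha)
    spe_lim <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                        1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }

  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
  # in-model samples: T2 * n / (n-1)^2 ~ Beta(k/2, (n-k-1)/2); the
  # new-observation F form is useless here because it can exceed the
  # attainable maximum (n-1)^2/n when k approaches n
  t2_lim <- if (n > k + 1) {
    (n - 1)^2 / n * stats::qbeta(1 - alpha, k / 2, (n - k - 1) / 2)
  } else {
    Inf
  }

  outlier <- (spe_lim > 0 & spe > spe_lim) | t2 > t2_lim

  km <- with_local_seed(seed, stats::kmeans(scores, centers = k_clusters,
                                            nstart = 50, iter.max = 100))
  top_feature <- vapply(seq_len(k), function(j) {
    rownames(pc$rotation)[which.max(abs(pc$rotation[, j]))]
  }, character(1))

  samples <- tibble::tibble(
    sample = rownames(mat) %||% paste0("s", seq_len(n)),
    spe = spe, t2 = t2, outlier = outlier,
    cluster = unname(km$cluster)
  )
  samples <- dplyr::bind_cols(samples,
                              tibble::as_tibble(scores, .name_repair = "minimal"))
  variance <- tibble::tibble(
    component = seq_along(ratios), variance_ratio = ratios,
    cumulative_ratio = cumsum(ratios),
    top_feature = c(top_feature, rep(NA_character_,
                                     length(ratios) - k))
  )
  structure(list(samples = samples, variance = variance,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 cutoffs = c(spe = spe_lim, t2 = t2_lim),
                 n_components = k, alpha = alpha,
                 k_clusters = k_clusters, transposed = transpose),
            class = "csp_pca")
}

#' @export
print.csp_pca <- function(x, ...) {
  cat("CSP matrix PCA mining (", nrow(x$samples), " samples, ",
      x$n_components, " components)\n", sep = "")
  cat("cumulative variance ratio:",
      round(x$variance$cumulative_ratio[x$n_components], 3), "\n")
  out <- x$samples$sample[x$samples$outlier]
  cat("outliers:", if (length(out)) paste(out, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
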