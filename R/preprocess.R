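# Normalization, feature selection, read-count thinning, outlier flagging.

#' Median-of-ratios size factors
#'
#' Computes per-sample normalization size factors by the median-of-ratios
#' method (Anders & Huber): the reference for gene i is its geometric mean
#' across samples, and the size factor of sample j is the median over genes
#' with a positive geometric mean of `counts[i, j] / geomean_i`.
#'
#' @param counts Non-negative integer genes-by-samples matrix with dimnames.
#' @return Named positive numeric vector, one size factor per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' deseq_size_factors(m) # (1/sqrt(2), sqrt(2))
#' @export
deseq_size_factors <- function(counts) {
  check_count_matrix(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    abort(
      "No gene has all-positive counts; median-of-ratios size factors are undefined.",
      class = "subtypecurves_normalization_error"
    )
  }
  geo <- exp(log_geo[usable])
  sf <- apply(counts, 2L, function(cnt) median(cnt[usable] / geo))
  setNames(sf, colnames(counts))
}

#' Size-factor normalized log2 expression
#'
#' Divides each sample's counts by its size factor and applies `log2(x + 1)`.
#'
#' @param counts Genes-by-samples count matrix.
#' @param size_factors Positive per-sample factors; computed with
#'   [deseq_size_factors()] when `NULL`.
#' @return Numeric matrix of log2-scale expression with attribute
#'   `size_factors`.
#' @export
normalize_log2 <- function(counts, size_factors = NULL) {
  check_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- deseq_size_factors(counts)
  if (length(size_factors) != ncol(counts)) {
    abort("`size_factors` must have one entry per sample.",
      class = "subtypecurves_structure_error"
    )
  }
  if (any(size_factors <= 0)) {
    abort("`size_factors` must be positive.",
      class = "subtypecurves_structure_error"
    )
  }
  x <- log2(sweep(counts, 2L, size_factors, `/`) + 1)
  attr(x, "size_factors") <- setNames(size_factors, colnames(counts))
  x
}

#' Retain the highest-variance genes
#'
#' Keeps the `ceiling(fraction * n_genes)` genes of highest variance (ties
#' broken by input order); the surviving genes keep their input order. With
#' the 25% default, a 20477-gene matrix retains 5120 genes.
#'
#' @param x Genes-by-samples expression matrix.
#' @param fraction Fraction of genes to keep, in `(0, 1]`.
#' @return The filtered matrix.
#' @export
variance_filter <- function(x, fraction = 0.25) {
  if (nrow(x) < 1L) abort("`x` must have at least one gene.")
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].", class = "subtypecurves_config_error")
  }
  keep <- ceiling(fraction * nrow(x))
  v <- row_vars(x)
  chosen <- sort(order(-v, seq_along(v))[seq_len(keep)])
  x[chosen, , drop = FALSE]
}

#' Subset an expression matrix to a gene panel
#'
#' Retains exactly the panel genes present in the matrix, in panel order.
#' Panel genes absent from the matrix are reported in the `missing_genes`
#' attribute (with a warning).
#'
#' @param x Genes-by-samples expression matrix.
#' @param panel Non-empty character vector of gene identifiers.
#' @return The panel-ordered matrix with attribute `missing_genes`.
#' @export
subset_panel <- function(x, panel) {
  if (length(panel) < 1L) abort("`panel` must be non-empty.")
  present <- panel[panel %in% rownames(x)]
  missing <- setdiff(panel, rownames(x))
  if (length(present) == 0L) {
    abort("No panel gene is present in the matrix.",
      class = "subtypecurves_structure_error"
    )
  }
  if (length(missing) > 0L) {
    warn(sprintf("%d panel gene(s) absent from the matrix.", length(missing)))
  }
  out <- x[present, , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}

#' Binomial read-count thinning
#'
#' Downsamples each sample to approximately `target_total` reads: for a sample
#' with total count T > target, every gene count is replaced by a binomial
#' draw with success probability `target_total / T`. This is
#' expectation-equivalent to subsampling reads before counting. Samples at or
#' below the target are left unchanged. Zeros are preserved and no count ever
#' increases.
#'
#' @param counts Genes-by-samples count matrix.
#' @param target_total Target total count per sample (non-negative).
#' @param seed Integer seed.
#' @return Thinned integer count matrix of the same shape.
#' @export
thin_counts <- function(counts, target_total, seed = 1L) {
  check_count_matrix(counts)
  if (length(target_total) != 1L || is.na(target_total) || target_total < 0) {
    abort("`target_total` must be a single non-negative number.",
      class = "subtypecurves_config_error"
    )
  }
  withr::local_seed(seed)
  totals <- colSums(counts)
  out <- counts
  for (j in which(totals > target_total)) {
    out[, j] <- rbinom(nrow(counts), counts[, j], target_total / totals[j])
  }
  storage.mode(out) <- "integer"
  out
}

#' Flag outlier samples from PCA scores and residuals
#'
#' Automated surrogate for visual PCA inspection: samples are flagged when
#' their Hotelling-type score distance on the first `n_components` principal
#' components, or their residual sum of squares off that subspace, exceeds the
#' stated empirical quantile of the cohort's own distances.
#'
#' @param x Genes-by-samples expression matrix.
#' @param n_components Number of leading components for the score distance.
#' @param score_quantile,residual_quantile Empirical quantiles above which a
#'   sample is flagged (strictly greater; 1.0 flags nothing).
#' @return Named logical vector, `TRUE` for flagged samples, with attributes
#'   `score_distance` and `residual_ss`.
#' @export
flag_outliers_pca <- function(x, n_components = 3L, score_quantile = 0.99,
                              residual_quantile = 0.99) {
  if (n_components >= min(dim(x))) {
    abort("`n_components` must be smaller than both matrix dimensions.",
      class = "subtypecurves_config_error"
    )
  }
  obs <- t(x) # samples as observations
  pca <- prcomp(obs, center = TRUE, scale. = FALSE)
  if (all(pca$sdev[seq_len(n_components)] < 1e-12)) {
    abort("Matrix is (numerically) constant; PCA outlier flagging is undefined.",
      class = "subtypecurves_numerical_error"
    )
  }
  k <- seq_len(n_components)
  lambda <- pmax(pca$sdev[k]^2, 1e-12)
  scores <- pca$x[, k, drop = FALSE]
  score_dist <- rowSums(sweep(scores^2, 2L, lambda, `/`))
  recon <- scores %*% t(pca$rotation[, k, drop = FALSE])
  centered <- sweep(obs, 2L, pca$center, `-`)
  residual_ss <- rowSums((centered - recon)^2)
  flags <- score_dist > quantile(score_dist, score_quantile) |
    residual_ss > quantile(residual_ss, residual_quantile)
  attr(flags, "score_distance") <- score_dist
  attr(flags, "residual_ss") <- residual_ss
  flags
}
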