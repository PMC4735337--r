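# Nearest shrunken centroids, implemented from the published construction:
# standardized class-vs-overall contrasts are soft-thresholded, class
# centroids are rebuilt from the shrunken contrasts, and samples are assigned
# to the class minimizing the standardized squared distance to the shrunken
# centroid minus twice the log class prior.

#' Train a nearest shrunken centroids classifier
#'
#' For gene i and class k with n_k training samples (n total, K classes), the
#' standardized contrast is
#' `d_ik = (centroid_ik - overall_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class standard deviation
#' and `s0` the median of the `s_i` (an offset guarding against genes with
#' tiny variance). Each contrast is soft-thresholded,
#' `d'_ik = sign(d_ik) * max(|d_ik| - threshold, 0)`, and the shrunken class
#' centroid is `overall_i + m_k * (s_i + s0) * d'_ik`. At threshold 0 the
#' classifier is plain nearest-centroid on the standardized distance; large
#' thresholds collapse every centroid onto the overall centroid, leaving only
#' the prior term.
#'
#' @param x Genes-by-samples expression matrix (training slice).
#' @param y Class labels, one per sample; every class needs >= 2 samples.
#' @param threshold Non-negative shrinkage threshold.
#' @param priors Class priors; default the empirical training proportions.
#' @return An `nsc_fit` with the overall centroid, shrunken class centroids,
#'   pooled SDs, `s0`, priors and class labels (fixed order).
#' @seealso [predict.nsc_fit()], [nsc_threshold_path()]
#' @export
train_nsc <- function(x, y, threshold = 0, priors = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    abort("NSC training needs at least two classes.",
      class = "subtypecurves_training_error"
    )
  }
  small <- names(which(table(y) < 2L))
  if (length(small) > 0L) {
    abort(sprintf(
      "Class(es) with fewer than 2 training samples: %s.",
      paste(small, collapse = ", ")
    ), class = "subtypecurves_training_error")
  }
  nsc_fit_core(x, y, threshold, priors)
}

# Core fit, also used by the unsupervised arm where singleton clusters are
# tolerated (they contribute no within-class variance; df stays n - K).
nsc_fit_core <- function(x, y, threshold = 0, priors = NULL) {
  if (threshold < 0) {
    abort("`threshold` must be non-negative.",
      class = "subtypecurves_config_error"
    )
  }
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  n <- ncol(x)
  n_k <- as.numeric(table(y)[classes])
  if (is.null(priors)) priors <- n_k / n
  priors <- priors / sum(priors)

  overall <- rowMeans(x)
  centroids <- vapply(
    classes, function(cl) rowMeans(x[, y == cl, drop = FALSE]), numeric(nrow(x))
  )

  wss <- matrix(0, nrow(x), length(classes))
  for (k in seq_along(classes)) {
    xc <- x[, y == classes[k], drop = FALSE]
    wss[, k] <- rowSums((xc - centroids[, k])^2)
  }
  df <- max(n - length(classes), 1L)
  s <- sqrt(rowSums(wss) / df)
  s0 <- median(s)

  m_k <- sqrt(pmax(1 / n_k - 1 / n, 0))
  denom <- outer(s + s0, m_k)
  d <- (centroids - overall) / denom
  d_shrunk <- sign(d) * pmax(abs(d) - threshold, 0)
  shrunken <- overall + denom * d_shrunk

  structure(
    list(
      classes = classes, overall = overall, centroids = shrunken,
      raw_contrasts = d, shrunk_contrasts = d_shrunk,
      s = s, s0 = s0, priors = setNames(priors, classes),
      threshold = threshold, gene_ids = rownames(x)
    ),
    class = "nsc_fit"
  )
}

#' Predict with a fitted NSC model
#'
#' Assigns each sample to the class minimizing
#' `sum_i (x_i - centroid'_ik)^2 / (s_i + s0)^2 - 2 * log(prior_k)`, ties
#' broken by the fixed class-label order. Class scores are the softmax of
#' `-discriminant / 2` and sum to 1 per sample.
#'
#' @param object An `nsc_fit`.
#' @param newx Genes-by-samples matrix with the training gene set, same order.
#' @param ... Unused.
#' @return List with `labels` (factor) and `scores` (samples x classes matrix).
#' @export
predict.nsc_fit <- function(object, newx, ...) {
  if (!identical(rownames(newx), object$gene_ids)) {
    abort("Prediction genes must match the training genes (same order).",
      class = "subtypecurves_structure_error"
    )
  }
  w <- 1 / (object$s + object$s0)^2
  disc <- vapply(seq_along(object$classes), function(k) {
    colSums(w * (newx - object$centroids[, k])^2) - 2 * log(object$priors[k])
  }, numeric(ncol(newx)))
  disc <- matrix(disc, ncol = length(object$classes))
  labels <- factor(object$classes[apply(disc, 1L, which.min)],
    levels = object$classes
  )
  logp <- -disc / 2
  logp <- logp - apply(logp, 1L, max)
  scores <- exp(logp) / rowSums(exp(logp))
  dimnames(scores) <- list(colnames(newx), object$classes)
  list(labels = setNames(labels, colnames(newx)), scores = scores)
}

#' Candidate shrinkage thresholds for NSC tuning
#'
#' An evenly spaced path of `n` thresholds from 0 to the largest absolute
#' standardized contrast in the training data (beyond which every centroid has
#' collapsed onto the overall centroid).
#'
#' @param x,y Training expression matrix and labels.
#' @param n Number of thresholds.
#' @return Increasing numeric vector of length `n` starting at 0.
#' @export
nsc_threshold_path <- function(x, y, n = 15L) {
  fit <- nsc_fit_core(x, y, threshold = 0)
  seq(0, max(abs(fit$raw_contrasts)), length.out = n)
}
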