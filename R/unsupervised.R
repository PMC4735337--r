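# The unsupervised arm: correlation-distance average-linkage clustering,
# significance-of-clustering pruning, cluster centroids, and priority-ordered
# subtype label transfer.

#' Hierarchical clustering with correlation distance and average linkage
#'
#' Sample dissimilarity is `1 - Pearson correlation` between expression
#' profiles; agglomeration is average linkage (UPGMA). Deterministic.
#'
#' @param x Genes-by-samples expression matrix; every sample profile must
#'   have nonzero variance (correlation is undefined for constant profiles).
#' @return An [stats::hclust] tree over the samples.
#' @export
hclust_corr_average <- function(x) {
  if (ncol(x) < 2L) abort("At least two samples are required.")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "Constant expression profile(s): %s.",
      paste(colnames(x)[sds == 0], collapse = ", ")
    ), class = "subtypecurves_structure_error")
  }
  d <- as.dist(1 - cor(x))
  hclust(d, method = "average")
}

#' Significance of a two-way cluster split
#'
#' Tests whether the samples support a real 2-way split against a
#' single-Gaussian null. The test statistic is the cluster index
#' CI = (within-cluster sum of squares of the 2-way split) / (total sum of
#' squares about the grand mean); small CI means a strong split. By default
#' (and in dendrogram pruning) the observed split is the best 2-means
#' partition of the node's samples, as in the published
#' significance-of-clustering procedure; explicit split labels may be given
#' instead. The null is a Gaussian with diagonal covariance whose eigenvalues
#' are the soft-thresholded sample-covariance spectrum: a background variance
#' is estimated from the median absolute deviation of all (centered) matrix
#' entries, and eigenvalues are shifted down by a threshold `tau` and floored
#' at the background, with `tau` chosen so the total variance is preserved —
#' this stops cluster signal leaking into the null through inflated leading
#' eigenvalues. Each simulated null dataset is split by 2-means and its CI
#' recorded; the Monte-Carlo p-value is
#' `(1 + #{CI_sim <= CI_obs}) / (n_sim + 1)`, so the smallest attainable value
#' is `1 / (n_sim + 1)`.
#'
#' @param x Genes-by-samples expression matrix restricted to the candidate
#'   node's samples.
#' @param labels Optional 2-level split labels (one per sample, at least 2
#'   per side). When `NULL`, the observed split is found by 2-means.
#' @param n_sim Number of null simulations (>= 1).
#' @param seed Integer seed.
#' @return Numeric p-value with attributes `ci_observed` and `ci_null`.
#' @export
sigclust_pvalue <- function(x, labels = NULL, n_sim = 100L, seed = 1L) {
  if (n_sim < 1L) {
    abort("`n_sim` must be at least 1.", class = "subtypecurves_config_error")
  }
  obs <- t(x) # samples in rows
  n <- nrow(obs)
  if (n < 4L) {
    abort("At least 4 samples are needed to test a split.",
      class = "subtypecurves_config_error"
    )
  }
  withr::local_seed(seed)
  if (is.null(labels)) {
    labels <- kmeans(obs, centers = 2L, nstart = 5L)$cluster
  } else {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
      abort("The candidate split must have at least 2 samples per side.",
        class = "subtypecurves_config_error"
      )
    }
  }
  ci_obs <- cluster_index(obs, as.factor(labels))

  centered <- sweep(obs, 2L, colMeans(obs), `-`)
  ev <- svd(centered, nu = 0L, nv = 0L)$d^2 / (n - 1L)
  ev <- c(ev, rep(0, max(0L, ncol(obs) - length(ev))))
  sigma2_bg <- max(stats::mad(as.vector(centered))^2, 1e-12)
  ev_null <- soft_threshold_spectrum(ev, sigma2_bg)

  ci_null <- vapply(seq_len(n_sim), function(i) {
    sim <- matrix(rnorm(n * length(ev_null)), n) %*%
      diag(sqrt(ev_null), length(ev_null))
    km <- kmeans(sim, centers = 2L, nstart = 5L)
    km$tot.withinss / sum(sweep(sim, 2L, colMeans(sim), `-`)^2)
  }, numeric(1))

  p <- (1 + sum(ci_null <= ci_obs)) / (n_sim + 1)
  attr(p, "ci_observed") <- ci_obs
  attr(p, "ci_null") <- ci_null
  p
}

# Soft-threshold an eigenvalue spectrum: lambda_j -> max(lambda_j - tau,
# sigma2_bg), with tau >= 0 chosen so the total variance equals the input
# total (flooring small eigenvalues up is paid for by shrinking large ones).
# If even tau = 0 cannot reach the input total (no eigenvalue below the
# background), the plain floored spectrum is returned.
soft_threshold_spectrum <- function(ev, sigma2_bg) {
  target <- sum(ev)
  excess <- function(tau) sum(pmax(ev - tau, sigma2_bg)) - target
  if (excess(0) <= 0) {
    return(pmax(ev, sigma2_bg))
  }
  upper <- max(ev)
  if (excess(upper) >= 0) {
    return(rep(sigma2_bg, length(ev)))
  }
  tau <- stats::uniroot(excess, c(0, upper), tol = 1e-10)$root
  pmax(ev - tau, sigma2_bg)
}

cluster_index <- function(obs, labels) {
  wss <- 0
  for (cl in levels(labels)) {
    part <- obs[labels == cl, , drop = FALSE]
    wss <- wss + sum(sweep(part, 2L, colMeans(part), `-`)^2)
  }
  tss <- sum(sweep(obs, 2L, colMeans(obs), `-`)^2)
  wss / tss
}

#' Prune a dendrogram to significantly reproducible clusters
#'
#' Recursive top-down descent from the root: each node's samples are tested
#' for 2-way cluster structure with [sigclust_pvalue()] (observed split =
#' best 2-means partition of the node, per the published procedure); when the
#' p-value is below `alpha` the split into the node's two dendrogram children
#' is accepted and the descent recurses into both, otherwise the node becomes
#' a terminal cluster. Nodes whose dendrogram split leaves fewer than 2
#' samples on a side are not tested and terminate. With `alpha = 0` no split
#' is ever accepted and a single cluster is returned.
#'
#' @param tree An [hclust_corr_average()] tree.
#' @param x The genes-by-samples matrix the tree was built from.
#' @param alpha Significance level in `[0, 1]`.
#' @param n_sim Null simulations per tested node.
#' @param seed Integer seed (each node derives its own sub-seed).
#' @return Integer cluster labels (1-based, in leaf order of first
#'   occurrence), named by sample.
#' @export
prune_to_significant <- function(tree, x, alpha = 0.05, n_sim = 100L, seed = 1L) {
  stopifnot(inherits(tree, "hclust"))
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must be in [0, 1].", class = "subtypecurves_config_error")
  }
  n <- length(tree$order)
  members <- vector("list", max(nrow(tree$merge), 1L))
  for (i in seq_len(nrow(tree$merge))) {
    m <- tree$merge[i, ]
    members[[i]] <- c(
      if (m[1] < 0) -m[1] else members[[m[1]]],
      if (m[2] < 0) -m[2] else members[[m[2]]]
    )
  }
  node_seeds <- derive_seeds(seed, max(nrow(tree$merge), 1L))

  clusters <- list()
  descend <- function(node) {
    if (node < 0) { # single leaf
      clusters[[length(clusters) + 1L]] <<- -node
      return(invisible())
    }
    kids <- tree$merge[node, ]
    left <- if (kids[1] < 0) -kids[1] else members[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else members[[kids[2]]]
    if (length(left) < 2L || length(right) < 2L || alpha == 0) {
      clusters[[length(clusters) + 1L]] <<- c(left, right)
      return(invisible())
    }
    idx <- c(left, right)
    p <- sigclust_pvalue(
      x[, idx, drop = FALSE],
      n_sim = n_sim, seed = node_seeds[node]
    )
    if (p < alpha) {
      descend(kids[1])
      descend(kids[2])
    } else {
      clusters[[length(clusters) + 1L]] <<- idx
    }
  }
  if (n == 1L) {
    clusters <- list(1L)
  } else {
    descend(nrow(tree$merge))
  }

  # number clusters by first occurrence along the dendrogram leaf order
  leaf_first <- vapply(
    clusters, function(idx) min(match(idx, tree$order)), numeric(1)
  )
  new_id <- order(order(leaf_first))
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- new_id[k]
  setNames(out, tree$labels)
}

#' Per-cluster expression centroids
#'
#' @param x Genes-by-samples expression matrix.
#' @param clusters Cluster labels, one per sample.
#' @return Genes-by-clusters matrix of mean expression.
#' @export
cluster_centroids <- function(x, clusters) {
  clusters <- as.factor(clusters)
  vapply(
    levels(clusters),
    function(cl) rowMeans(x[, clusters == cl, drop = FALSE]),
    numeric(nrow(x))
  )
}

#' Priority-ordered subtype label transfer
#'
#' Assigns subtype labels to clusters by Spearman rank correlation between
#' cluster centroids and reference subtype centroids. Each centroid set is
#' first gene-centered (per-gene mean across its own columns subtracted), the
#' standard step in centroid-based subtype matching: absolute baseline
#' expression otherwise dominates the cross-gene ranks and makes every
#' centroid correlate near-equally with every reference. Labels are processed
#' in the stated priority order (default Basal, Normal, Her2, LumA, LumB);
#' each label goes to the still-unassigned cluster with the highest
#' correlation to that label's reference centroid (ties broken by lowest
#' cluster index). Clusters left over once every label is placed receive
#' their own best-correlated reference label (duplicates allowed). Because
#' Spearman correlation depends only on ranks, the mapping is invariant to
#' any increasing transformation applied to the (centered) centroid values.
#'
#' @param centroids Genes-by-clusters matrix (from [cluster_centroids()]).
#' @param reference Genes-by-subtypes reference centroid matrix with the same
#'   genes in the same order.
#' @param priority Label priority order; must match `colnames(reference)`.
#' @param center Gene-center both centroid sets before correlating (default
#'   `TRUE`).
#' @return Named character vector: cluster -> subtype label.
#' @export
assign_subtype_labels <- function(centroids, reference,
                                  priority = c("Basal", "Normal", "Her2", "LumA", "LumB"),
                                  center = TRUE) {
  if (ncol(centroids) < 1L) abort("At least one cluster is required.")
  if (!identical(rownames(centroids), rownames(reference))) {
    abort("Cluster and reference centroids must share an aligned gene set.",
      class = "subtypecurves_structure_error"
    )
  }
  if (!setequal(priority, colnames(reference))) {
    abort("`priority` must be a permutation of the reference labels.")
  }
  if (center) {
    # both sets centered by the reference per-gene means, so the mapping is
    # well-defined even for a single cluster
    baseline <- rowMeans(reference)
    centroids <- centroids - baseline
    reference <- reference - baseline
  }
  rho <- cor(centroids, reference, method = "spearman")
  assignment <- setNames(rep(NA_character_, ncol(centroids)), colnames(centroids))
  for (label in priority) {
    free <- which(is.na(assignment))
    if (length(free) == 0L) break
    best <- free[which.max(rho[free, label])]
    assignment[best] <- label
  }
  for (k in which(is.na(assignment))) {
    assignment[k] <- colnames(reference)[which.max(rho[k, ])]
  }
  assignment
}

#' Unsupervised subtype classification learning curve
#'
#' Per round and training size: stratified outer holdout; the training subset
#' is clustered ([hclust_corr_average()]), pruned to significant clusters
#' ([prune_to_significant()]); cluster centroids receive subtype labels by
#' priority-ordered Spearman matching against the reference centroids
#' (default: the cohort's true latent class centroids); the outer test set is
#' classified by the nearest-centroid rule (NSC with threshold 0) against the
#' labeled training cluster centroids, and scored against the true subtype
#' labels. Clustering and pruning operate on gene-centered training
#' expression, the standard preparation for correlation-distance expression
#' clustering. Rounds where pruning returns a single cluster predict that
#' cluster's label throughout (with a warning).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config A [curve_config()]; its first dataset definition selects the
#'   feature set.
#' @param alpha,n_sim Pruning significance level and null simulations.
#' @param reference Optional genes-by-subtypes reference centroid matrix;
#'   defaults to the cohort's true centroids on the dataset's genes.
#' @return A `learning_curve` object.
#' @export
run_unsupervised_curve <- function(cohort, config, alpha = 0.05, n_sim = 100L,
                                   reference = NULL) {
  stopifnot(inherits(config, "curve_config"))
  labels <- droplevels(as.factor(cohort$annotation$subtype))
  expr <- normalize_log2(cohort$counts)
  x <- build_dataset(expr, config$datasets[[1L]])
  if (is.null(reference)) {
    reference <- cohort$true_centroids[rownames(x), , drop = FALSE]
  }
  round_seeds <- derive_seeds(config$master_seed, config$n_rounds)

  results <- purrr::map(seq_len(config$n_rounds), function(r) {
    split <- stratified_split(labels, config$test_fraction, seed = round_seeds[r])
    purrr::map(config$training_sizes, function(size) {
      if (size > length(split$train)) {
        warn(sprintf("Training size %d infeasible; skipped.", size))
        return(NULL)
      }
      train_idx <- stratified_subsample(
        split$train, labels, size,
        seed = round_seeds[r] + size
      )
      x_tr <- x[, train_idx, drop = FALSE]
      # cluster on gene-centered expression (standard for correlation-distance
      # expression clustering: shared baseline otherwise swamps class signal)
      x_tr_centered <- x_tr - rowMeans(x_tr)
      tree <- hclust_corr_average(x_tr_centered)
      clusters <- prune_to_significant(
        tree, x_tr_centered,
        alpha = alpha, n_sim = n_sim, seed = round_seeds[r] + size + 1L
      )
      mapping <- assign_subtype_labels(
        cluster_centroids(x_tr, clusters), reference
      )
      x_te <- x[, split$test, drop = FALSE]
      if (length(unique(clusters)) == 1L) {
        warn(sprintf(
          "Round %d size %d: pruning returned a single cluster.", r, size
        ))
        pred <- rep(mapping[[1L]], ncol(x_te))
      } else {
        fit <- nsc_fit_core(x_tr, clusters, threshold = 0)
        pred <- mapping[as.character(predict(fit, x_te)$labels)]
      }
      m <- metrics(as.character(labels[split$test]), unname(pred),
        classes = resolve_report_classes(labels)
      )
      tibble::tibble(
        size = size,
        n_clusters = length(unique(clusters)),
        accuracy = m$accuracy,
        balanced_accuracy = m$balanced_accuracy,
        per_class = list(m$per_class),
        confusion = list(m$confusion)
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows(.id = "round") |>
    dplyr::mutate(
      round = as.integer(.data$round),
      classifier = "unsupervised_centroid",
      dataset = names(config$datasets)[1L], .before = 1L
    )
  new_learning_curve(results, config)
}

#' Export a dendrogram in Newick format
#'
#' @param tree An [stats::hclust] tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
tree_to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "hclust"))
  build <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%g", tree$labels[-node], parent_height)
    } else {
      h <- tree$height[node]
      sprintf(
        "(%s,%s):%g",
        build(tree$merge[node, 1], h), build(tree$merge[node, 2], h),
        parent_height - h
      )
    }
  }
  root <- nrow(tree$merge)
  nwk <- sprintf(
    "(%s,%s);",
    build(tree$merge[root, 1], tree$height[root]),
    build(tree$merge[root, 2], tree$height[root])
  )
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
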