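#' Configuration for a synthetic breast-cancer cohort
#'
#' Describes a synthetic RNA-seq cohort with the statistical structure of the
#' five-subtype breast-cancer classification problem: imbalanced intrinsic
#' subtypes (Basal, Her2, LumA, LumB, Normal), a minority of subtype-informative
#' genes on a log2 scale, negative-binomial (gamma-Poisson) counts with
#' sample-specific library sizes, correlated LumA/LumB centroids, and clinical
#' receptor status (ER/PR/Her2) tied to the marker genes ESR1, PGR and ERBB2
#' with label noise.
#'
#' @param n_samples Number of samples.
#' @param class_proportions Named proportions for the five subtypes, in the
#'   order Basal, Her2, LumA, LumB, Normal; must sum to 1. The default is the
#'   empirical 132/65/393/190/105 split of an N = 885 reference cohort.
#' @param n_genes Total number of gene features (default 20477).
#' @param n_informative Number of genes eligible for subtype effects.
#' @param effect_size Log2-scale centroid shift applied to informative genes.
#' @param lumAB_correlation Fraction of LumB's informative shifts shared with
#'   LumA, in `[0, 1]`; values near 1 make the two luminal subtypes hard to
#'   separate, as they are in real tumours.
#' @param dispersion Negative-binomial dispersion (1/size); single global value.
#' @param library_size_mean,library_size_cv Mean and coefficient of variation
#'   of the log-normal per-sample library sizes (total read counts).
#' @param receptor_noise_rate Probability that an observed receptor label is
#'   flipped relative to its biological truth, in `[0, 0.5]`.
#' @param marker_shift Log2 shift added to ESR1/PGR/ERBB2 in receptor-positive
#'   samples before counts are drawn.
#' @param pr_given_er_pos,pr_given_er_neg Probability of true PR positivity
#'   conditional on true ER status.
#' @param baseline_mean,baseline_sd Normal distribution of per-gene baseline
#'   log2 means, drawn once per cohort.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `cohort_config` list, validated.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_samples = 885L,
                          class_proportions = c(
                            Basal = 132, Her2 = 65, LumA = 393,
                            LumB = 190, Normal = 105
                          ) / 885,
                          n_genes = 20477L,
                          n_informative = 600L,
                          effect_size = 0.45,
                          lumAB_correlation = 0.95,
                          dispersion = 0.30,
                          library_size_mean = 5e6,
                          library_size_cv = 0.3,
                          receptor_noise_rate = 0.03,
                          marker_shift = 2.0,
                          pr_given_er_pos = 0.85,
                          pr_given_er_neg = 0.10,
                          baseline_mean = 4,
                          baseline_sd = 2,
                          seed = 1L) {
  config <- list(
    n_samples = as.integer(n_samples),
    class_proportions = class_proportions,
    n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative),
    effect_size = effect_size,
    lumAB_correlation = lumAB_correlation,
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    receptor_noise_rate = receptor_noise_rate,
    marker_shift = marker_shift,
    pr_given_er_pos = pr_given_er_pos,
    pr_given_er_neg = pr_given_er_neg,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(config)
  structure(config, class = "cohort_config")
}

validate_cohort_config <- function(config) {
  bad <- function(field, why) {
    abort(sprintf("Invalid cohort configuration: `%s` %s.", field, why),
      class = "subtypecurves_config_error"
    )
  }
  with(config, {
    if (n_samples < 1) bad("n_samples", "must be a positive integer")
    if (length(class_proportions) != 5L || any(class_proportions < 0)) {
      bad("class_proportions", "must be 5 non-negative values")
    }
    if (abs(sum(class_proportions) - 1) > 1e-9) {
      bad("class_proportions", "must sum to 1 (within 1e-9)")
    }
    if (n_genes < 4) bad("n_genes", "must allow the 3 marker genes plus one")
    if (n_informative < 0 || n_informative > n_genes - 3L) {
      bad("n_informative", "must be in [0, n_genes - 3]")
    }
    if (effect_size < 0) bad("effect_size", "must be non-negative")
    if (lumAB_correlation < 0 || lumAB_correlation > 1) {
      bad("lumAB_correlation", "must be in [0, 1]")
    }
    for (f in c(
      "dispersion", "library_size_mean", "library_size_cv", "baseline_sd"
    )) {
      if (config[[f]] <= 0) bad(f, "must be positive")
    }
    if (receptor_noise_rate < 0 || receptor_noise_rate > 0.5) {
      bad("receptor_noise_rate", "must be in [0, 0.5]")
    }
    if (marker_shift < 0) bad("marker_shift", "must be non-negative")
    for (f in c("pr_given_er_pos", "pr_given_er_neg")) {
      if (config[[f]] < 0 || config[[f]] > 1) bad(f, "must be a probability")
    }
  })
  invisible(config)
}

marker_genes <- function() c("ESR1", "PGR", "ERBB2")

#' Simulate a synthetic subtype cohort
#'
#' Draws a full cohort under `config`: subtype labels by deterministic
#' largest-remainder allocation of the class proportions (then shuffled),
#' per-gene baseline log2 means, per-class log2 shifts of `effect_size` on a
#' random subset of the informative genes (LumB sharing a `lumAB_correlation`
#' fraction of LumA's shifts), receptor-status truth tied to subtype with the
#' marker genes ESR1/PGR/ERBB2 raised by `marker_shift` in truly positive
#' samples, log-normal library sizes, and negative-binomial counts with mean
#' proportional to `2^latent` scaled to each sample's library size.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` object: list with `counts` (integer genes-by-samples
#'   matrix), `annotation` (tibble: `sample_id`, `subtype`, `ER`, `PR`, `Her2`
#'   observed labels plus hidden `er_true`/`pr_true`/`her2_true` ground truth),
#'   `true_centroids` (genes-by-class matrix of latent log2 class means) and
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_samples = 60, n_genes = 200,
#'   n_informative = 40, seed = 7
#' ))
#' table(cohort$annotation$subtype)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  withr::local_seed(config$seed)

  classes <- subtype_levels()
  n <- config$n_samples
  p <- config$n_genes

  class_counts <- apportion_largest_remainder(n, config$class_proportions)
  subtype <- sample(rep(classes, class_counts))
  subtype <- factor(subtype, levels = classes)

  gene_ids <- c(marker_genes(), sprintf("G%06d", seq_len(p - 3L)))
  sample_ids <- sprintf("S%04d", seq_len(n))

  baseline <- rnorm(p, config$baseline_mean, config$baseline_sd)
  names(baseline) <- gene_ids

  # Per-class log2 shifts on informative genes: each informative gene gets a
  # shift of -effect, 0 or +effect per class (equal probability). LumB copies
  # LumA's shift for a lumAB_correlation fraction of informative genes.
  informative <- sample(setdiff(gene_ids, marker_genes()), config$n_informative)
  delta <- matrix(0, nrow = p, ncol = 5L, dimnames = list(gene_ids, classes))
  draw_shift <- function(k) {
    sample(c(-1, 0, 1), k, replace = TRUE) * config$effect_size
  }
  for (cl in c("Basal", "Her2", "LumA", "Normal")) {
    delta[informative, cl] <- draw_shift(length(informative))
  }
  own <- draw_shift(length(informative))
  shared <- rbinom(length(informative), 1L, config$lumAB_correlation) == 1L
  delta[informative, "LumB"] <- ifelse(
    shared, delta[informative, "LumA"], own
  )

  truth <- draw_receptor_truth(subtype, config)

  latent <- baseline + delta[, as.integer(subtype), drop = FALSE]
  latent["ESR1", truth$er_true] <- latent["ESR1", truth$er_true] + config$marker_shift
  latent["PGR", truth$pr_true] <- latent["PGR", truth$pr_true] + config$marker_shift
  latent["ERBB2", truth$her2_true] <- latent["ERBB2", truth$her2_true] + config$marker_shift

  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  meanlog <- log(config$library_size_mean) - sdlog^2 / 2
  lib_sizes <- rlnorm(n, meanlog, sdlog)

  w <- 2^latent
  mu <- sweep(w, 2L, lib_sizes / colSums(w), `*`)
  counts <- matrix(
    rnbinom(p * n, mu = mu, size = 1 / config$dispersion),
    nrow = p, ncol = n, dimnames = list(gene_ids, sample_ids)
  )
  storage.mode(counts) <- "integer"

  flip <- function(status) {
    noisy <- rbinom(n, 1L, config$receptor_noise_rate) == 1L
    xor(status, noisy)
  }
  as_status <- function(x) factor(ifelse(x, "pos", "neg"), levels = c("neg", "pos"))

  annotation <- tibble::tibble(
    sample_id = sample_ids,
    subtype = subtype,
    ER = as_status(flip(truth$er_true)),
    PR = as_status(flip(truth$pr_true)),
    Her2 = as_status(flip(truth$her2_true)),
    er_true = truth$er_true,
    pr_true = truth$pr_true,
    her2_true = truth$her2_true
  )

  true_centroids <- vapply(
    classes,
    function(cl) rowMeans(latent[, subtype == cl, drop = FALSE]),
    numeric(p)
  )

  structure(
    list(
      counts = counts, annotation = annotation,
      true_centroids = true_centroids,
      informative_genes = informative, config = config
    ),
    class = "cohort"
  )
}

# Biological receptor truth conditional on subtype: ER+ iff luminal, Her2+
# iff Her2-enriched, PR depends on ER.
draw_receptor_truth <- function(subtype, config) {
  er_true <- subtype %in% c("LumA", "LumB")
  her2_true <- subtype == "Her2"
  p_pr <- ifelse(er_true, config$pr_given_er_pos, config$pr_given_er_neg)
  pr_true <- rbinom(length(subtype), 1L, p_pr) == 1L
  list(er_true = er_true, pr_true = pr_true, her2_true = her2_true)
}

#' Redraw observed receptor-status labels for a cohort
#'
#' Re-applies label noise to the cohort's stored biological receptor truth
#' (ER positive for LumA/LumB, Her2 positive for the Her2 class, PR conditional
#' on ER): each true label is flipped independently with probability
#' `receptor_noise_rate`. Marker-gene expression is part of the simulated
#' counts and is unchanged; this regenerates only the clinical labels.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param receptor_noise_rate Flip probability in `[0, 0.5]`; defaults to the
#'   cohort's configured rate.
#' @param seed Integer seed for the flips.
#' @return The cohort's annotation tibble with `ER`, `PR`, `Her2` redrawn.
#' @export
simulate_receptor_status <- function(cohort,
                                     receptor_noise_rate = cohort$config$receptor_noise_rate,
                                     seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "cohort"))
  if (!all(marker_genes() %in% rownames(cohort$counts))) {
    abort("Cohort lacks the marker genes ESR1/PGR/ERBB2.",
      class = "subtypecurves_structure_error"
    )
  }
  if (receptor_noise_rate < 0 || receptor_noise_rate > 0.5) {
    abort("`receptor_noise_rate` must be in [0, 0.5].",
      class = "subtypecurves_config_error"
    )
  }
  ann <- cohort$annotation
  withr::local_seed(seed)
  flip <- function(status) {
    xor(status, rbinom(nrow(ann), 1L, receptor_noise_rate) == 1L)
  }
  as_status <- function(x) factor(ifelse(x, "pos", "neg"), levels = c("neg", "pos"))
  ann$ER <- as_status(flip(ann$er_true))
  ann$PR <- as_status(flip(ann$pr_true))
  ann$Her2 <- as_status(flip(ann$her2_true))
  ann
}

#' Curated informative gene panel for a synthetic cohort
#'
#' Returns a small panel of genes known (by construction) to carry subtype
#' signal — the synthetic analogue of a curated intrinsic-subtype panel such
#' as PAM50. Mirroring how minimal centroid panels are assembled, the panel
#' holds the three receptor marker genes plus, for each subtype in turn, the
#' informative genes whose latent centroid departs most from the across-class
#' mean, cycling over subtypes so every class (including LumB) contributes
#' discriminative genes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_genes Panel size (default 50).
#' @return Character vector of gene identifiers.
#' @export
informative_panel <- function(cohort, n_genes = 50L) {
  stopifnot(inherits(cohort, "cohort"))
  pool <- setdiff(cohort$informative_genes, marker_genes())
  ctr <- cohort$true_centroids[pool, , drop = FALSE]
  dev <- abs(ctr - rowMeans(ctr))
  ranked <- apply(dev, 2L, function(v) pool[order(-v)], simplify = FALSE)
  panel <- marker_genes()
  i <- 1L
  while (length(panel) < min(n_genes, length(pool) + 3L)) {
    for (cl in names(ranked)) {
      cand <- ranked[[cl]][i]
      if (!is.na(cand) && !cand %in% panel) panel <- c(panel, cand)
      if (length(panel) >= min(n_genes, length(pool) + 3L)) break
    }
    i <- i + 1L
  }
  panel
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic subtype cohort: %d genes x %d samples\n",
    nrow(x$counts), ncol(x$counts)
  ))
  print(table(x$annotation$subtype))
  invisible(x)
}
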