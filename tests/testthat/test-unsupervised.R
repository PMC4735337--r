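# Clustering, significance pruning, and subtype label transfer.

test_that("correlation-distance UPGMA matches a naive agglomeration oracle", {
  # naive UPGMA: repeatedly merge the closest pair, averaging dissimilarities
  # weighted by cluster sizes; compare via cophenetic distances
  naive_upgma_cophenetic <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    sizes <- rep(1, n)
    members <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    active <- seq_len(n)
    while (length(active) > 1) {
      best <- c(NA, NA)
      best_d <- Inf
      for (i in active) {
        for (j in active) {
          if (i < j && d[i, j] < best_d) {
            best_d <- d[i, j]
            best <- c(i, j)
          }
        }
      }
      i <- best[1]
      j <- best[2]
      for (a in members[[i]]) {
        for (b in members[[j]]) coph[a, b] <- coph[b, a] <- best_d
      }
      for (k in setdiff(active, c(i, j))) {
        d[i, k] <- d[k, i] <-
          (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
      }
      members[[i]] <- c(members[[i]], members[[j]])
      sizes[i] <- sizes[i] + sizes[j]
      active <- setdiff(active, j)
    }
    coph
  }

  x <- withr::with_seed(3, matrix(rnorm(8 * 12), 8, 12,
    dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:12))
  ))
  tree <- hclust_corr_average(x)
  got <- as.matrix(stats::cophenetic(tree))
  want <- naive_upgma_cophenetic(as.dist(1 - cor(x)))
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("duplicated and affinely related samples are merged at zero height first", {
  x <- withr::with_seed(5, matrix(rnorm(10 * 5), 10, 5,
    dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5))
  ))
  x[, 2] <- x[, 1] # exact duplicate
  x[, 4] <- 3 + 2 * x[, 3] # positive affine transform
  d <- as.matrix(1 - cor(x))
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(d["s3", "s4"], 0, tolerance = 1e-12)
  tree <- hclust_corr_average(x)
  expect_equal(tree$height[1:2], c(0, 0), tolerance = 1e-12)

  const <- x
  const[, 5] <- 1
  expect_error(hclust_corr_average(const), "s5")
})

test_that("sigclust gives the minimal p for point-mass splits and errors on bad input", {
  x <- cbind(
    matrix(rnorm(20 * 10, 0, 0.05), 20),
    matrix(rnorm(20 * 10, 20, 0.05), 20)
  )
  dimnames(x) <- list(sprintf("g%d", 1:20), sprintf("s%d", 1:20))
  p <- sigclust_pvalue(x, rep(1:2, each = 10), n_sim = 49, seed = 2)
  expect_equal(as.numeric(p), 1 / 50)

  expect_error(sigclust_pvalue(x, n_sim = 0), class = "subtypecurves_config_error")
  expect_error(
    sigclust_pvalue(x, c(1, rep(2, 19)), n_sim = 10),
    class = "subtypecurves_config_error"
  )
})

test_that("pruning returns one cluster at alpha 0 and recovers separated structure", {
  co <- separable_cohort()
  # marker genes carry receptor substructure (PR+/- within luminal classes);
  # the five-cluster check uses subtype-informative genes only
  panel <- setdiff(informative_panel(co, 43), c("ESR1", "PGR", "ERBB2"))
  x <- subset_panel(separable_expr(), panel)
  xc <- x - rowMeans(x)
  tree <- hclust_corr_average(xc)
  expect_identical(
    length(unique(prune_to_significant(tree, xc, alpha = 0, n_sim = 5, seed = 1))),
    1L
  )
  cl <- prune_to_significant(tree, xc, alpha = 0.05, n_sim = 60, seed = 8)
  expect_identical(length(unique(cl)), 5L)
  # clusters align with the true subtypes
  tab <- table(cl, co$annotation$subtype)
  expect_true(all(apply(tab, 1, function(r) max(r) / sum(r)) > 0.9))
  # determinism
  expect_identical(cl, prune_to_significant(tree, xc, alpha = 0.05, n_sim = 60, seed = 8))
})

test_that("single-Gaussian data is rarely split", {
  n_single <- vapply(1:10, function(i) {
    x <- withr::with_seed(400 + i, matrix(rnorm(15 * 40), 15, 40,
      dimnames = list(sprintf("g%d", 1:15), sprintf("s%d", 1:40))
    ))
    tree <- hclust_corr_average(x)
    length(unique(prune_to_significant(tree, x, alpha = 0.05, n_sim = 60, seed = i)))
  }, integer(1))
  expect_gte(mean(n_single == 1L), 0.9)
})

test_that("pruned cluster count is non-increasing as alpha decreases", {
  co <- separable_cohort()
  panel <- setdiff(informative_panel(co, 43), c("ESR1", "PGR", "ERBB2"))
  x <- subset_panel(separable_expr(), panel)
  xc <- x - rowMeans(x)
  tree <- hclust_corr_average(xc)
  counts <- vapply(c(0.2, 0.05, 0.01, 0), function(a) {
    length(unique(prune_to_significant(tree, xc, alpha = a, n_sim = 60, seed = 3)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("label transfer recovers identity, inverse permutations, and handles ties", {
  co <- separable_cohort()
  ref <- co$true_centroids[informative_panel(co, 40), ]

  expect_identical(
    unname(assign_subtype_labels(ref, ref)),
    colnames(ref)
  )

  perm <- c(3, 5, 1, 2, 4)
  shuffled <- ref[, perm]
  colnames(shuffled) <- paste0("c", 1:5)
  got <- assign_subtype_labels(shuffled, ref)
  expect_identical(unname(got), colnames(ref)[perm])

  # two identical clusters tied for Basal: first cluster index wins; the
  # loser takes a later-priority label, and no label is duplicated while
  # unassigned clusters remain
  tied <- ref[, c("Basal", "Basal", "LumA")]
  colnames(tied) <- c("c1", "c2", "c3")
  got2 <- assign_subtype_labels(tied, ref)
  expect_identical(unname(got2["c1"]), "Basal")
  expect_false(got2["c2"] == "Basal")
  expect_identical(length(unique(got2)), 3L)

  # more clusters than labels: surplus clusters get their own best reference
  surplus <- ref[, c(colnames(ref), "LumA")]
  colnames(surplus) <- paste0("c", 1:6)
  got3 <- assign_subtype_labels(surplus, ref)
  expect_identical(unname(got3[1:5]), colnames(ref))
  expect_identical(unname(got3["c6"]), "LumA")

  # invariance to a common increasing transform of the centroid values
  shift <- min(ref) - 1
  mono <- function(m) log(m - shift) + (m - shift)^0.3
  expect_identical(
    assign_subtype_labels(mono(shuffled), mono(ref), center = FALSE),
    assign_subtype_labels(shuffled, ref, center = FALSE)
  )

  expect_error(
    assign_subtype_labels(ref[1:10, ], ref),
    class = "subtypecurves_structure_error"
  )
})

test_that("the unsupervised curve is deterministic and below the supervised one", {
  co <- separable_cohort()
  cfg <- curve_config(
    training_sizes = c(60, 100), n_rounds = 2,
    classifiers = list(nsc = classifier_spec("nsc", grid = list(threshold = 0))),
    datasets = list(panel = informative_panel(co, 40)),
    inner_folds = 3, master_seed = 77
  )
  un1 <- run_unsupervised_curve(co, cfg, alpha = 0.05, n_sim = 40)
  un2 <- run_unsupervised_curve(co, cfg, alpha = 0.05, n_sim = 40)
  expect_identical(tidy(un1), tidy(un2))
  sup <- run_learning_curve(co, cfg)
  cmp <- dplyr::inner_join(
    glance(un1)[, c("size", "mean_accuracy")],
    glance(sup)[, c("size", "mean_accuracy")],
    by = "size", suffix = c("_unsup", "_sup")
  )
  expect_true(all(cmp$mean_accuracy_unsup <= cmp$mean_accuracy_sup + 1e-9))
})

test_that("dendrograms export to parseable Newick", {
  x <- withr::with_seed(2, matrix(rnorm(6 * 8), 6, 8,
    dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:8))
  ))
  tree <- hclust_corr_average(x)
  nwk <- tree_to_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  phylo <- ape::read.tree(text = nwk)
  expect_setequal(phylo$tip.label, colnames(x))
  # patristic distance between leaves is twice the UPGMA merge height
  expect_equal(
    2 * as.matrix(stats::cophenetic(tree))[phylo$tip.label, phylo$tip.label],
    as.matrix(ape::cophenetic.phylo(phylo)),
    tolerance = 1e-6
  )
})
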