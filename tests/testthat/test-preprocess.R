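# Normalization, feature selection, thinning, outlier flagging.

test_that("size factors match the median-of-ratios definition", {
  m <- toy_counts(30, 4)
  # identical columns -> all factors 1
  same <- matrix(m[, 1], nrow(m), 4, dimnames = dimnames(m))
  expect_equal(unname(deseq_size_factors(same)), rep(1, 4))

  # exact doubling -> (1/sqrt(2), sqrt(2))
  two <- cbind(a = m[, 1], b = 2L * m[, 1])
  rownames(two) <- rownames(m)
  expect_equal(unname(deseq_size_factors(two)), c(1 / sqrt(2), sqrt(2)),
    tolerance = 1e-12
  )

  # brute-force oracle on a random 50 x 6 matrix
  counts <- toy_counts(50, 6, seed = 99)
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(log(geo)) & geo > 0
  oracle <- apply(counts, 2, function(cnt) median(cnt[ok] / geo[ok]))
  expect_equal(unname(deseq_size_factors(counts)), unname(oracle),
    tolerance = 1e-12
  )
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  # odd gene count: the ratio median and DESeq2's exp(median(log-ratio))
  # coincide exactly at an odd number of usable genes
  counts <- toy_counts(81, 8, seed = 13)
  expect_equal(
    unname(deseq_size_factors(counts)),
    unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
    tolerance = 1e-10
  )
})

test_that("all-zero-ratio matrices are rejected", {
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
    dimnames = list(c("g1", "g2"), c("a", "b"))
  )
  expect_error(deseq_size_factors(m), class = "subtypecurves_normalization_error")
})

test_that("log2 normalization matches its element-wise definition", {
  counts <- toy_counts(20, 3)
  sf <- c(1, 2, 0.5)
  x <- normalize_log2(counts, sf)
  expect_equal(
    x[, 2], log2(counts[, 2] / 2 + 1),
    tolerance = 1e-14, ignore_attr = TRUE
  )
  zero <- counts
  zero[1, ] <- 0L
  expect_equal(unname(normalize_log2(zero, sf)[1, ]), c(0, 0, 0))
  one <- matrix(7L, 1, 1, dimnames = list("g", "s"))
  expect_equal(as.numeric(normalize_log2(one, 1)), 3)
  expect_error(normalize_log2(counts, c(1, 2)),
    class = "subtypecurves_structure_error"
  )
})

test_that("exactly rescaling one sample rescales normalized values by c^(1/n)", {
  counts <- toy_counts(40, 5, seed = 21)
  c_fac <- 4
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * as.integer(c_fac)
  sf1 <- deseq_size_factors(counts)
  sf2 <- deseq_size_factors(scaled)
  # size-factor ratios shift by exactly c for the scaled sample
  expect_equal(sf2[3] / sf2[1], c_fac * sf1[3] / sf1[1], tolerance = 1e-12)
  # normalized counts change only by the global c^(1/n) reference shift
  norm1 <- sweep(counts, 2, sf1, `/`)
  norm2 <- sweep(scaled, 2, sf2, `/`)
  expect_equal(norm2, norm1 * c_fac^(1 / 5), tolerance = 1e-12)
})

test_that("variance filter keeps ceil(fraction * n) genes, ties by input order", {
  wide <- matrix(rnorm(20477 * 3), 20477, 3,
    dimnames = list(sprintf("g%05d", 1:20477), c("a", "b", "c"))
  )
  expect_identical(nrow(variance_filter(wide, 0.25)), 5120L)

  x <- rbind(
    g1 = c(0, 0, 1), g2 = c(0, 0, 8), g3 = c(0, 0, 4), g4 = c(0, 0, 2)
  )
  colnames(x) <- c("a", "b", "c")
  expect_identical(rownames(variance_filter(x, 0.25)), "g2")

  # boundary ties: count respected, membership matches brute-force stable sort
  tied <- rbind(
    g1 = c(0, 2), g2 = c(0, 4), g3 = c(0, 2), g4 = c(0, 2), g5 = c(0, 1)
  )
  colnames(tied) <- c("a", "b")
  got <- variance_filter(tied, 0.5) # keep 3 of 5
  v <- apply(tied, 1, var)
  oracle <- rownames(tied)[sort(order(-v, seq_along(v))[1:3])]
  expect_identical(rownames(got), oracle)
  expect_identical(nrow(got), 3L)

  # fraction 1 is the identity on membership; invalid fractions rejected
  expect_identical(rownames(variance_filter(tied, 1)), rownames(tied))
  expect_error(variance_filter(tied, 0), class = "subtypecurves_config_error")
  expect_error(variance_filter(tied, 1.2), class = "subtypecurves_config_error")
})

test_that("panel subsetting returns panel order and reports missing genes", {
  x <- small_expr()
  all_genes <- rownames(x)
  expect_identical(rownames(subset_panel(x, all_genes)), all_genes)

  panel <- rev(all_genes[5:54])
  got <- subset_panel(x, panel)
  expect_identical(rownames(got), panel)
  expect_identical(nrow(got), 50L)

  with_missing <- c(panel[1:4], "NOPE1", "NOPE2", "NOPE3")
  expect_warning(got2 <- subset_panel(x, with_missing), "3 panel gene")
  expect_identical(rownames(got2), panel[1:4])
  expect_identical(attr(got2, "missing_genes"), c("NOPE1", "NOPE2", "NOPE3"))

  expect_error(
    suppressWarnings(subset_panel(x, c("NO1", "NO2"))),
    class = "subtypecurves_structure_error"
  )
})

test_that("thinning preserves zeros, never increases counts, hits the target mean", {
  counts <- toy_counts(20, 4, seed = 5, lambda = 40)
  counts[3, ] <- 0L
  totals <- colSums(counts)

  expect_identical(thin_counts(counts, max(totals) + 10L, seed = 1), counts)
  expect_true(all(thin_counts(counts, 0L, seed = 1) == 0L))

  thinned <- thin_counts(counts, floor(min(totals) / 2), seed = 2)
  expect_true(all(thinned <= counts))
  expect_true(all(thinned[3, ] == 0L))
  expect_identical(thin_counts(counts, 500L, seed = 3), thin_counts(counts, 500L, seed = 3))
  expect_error(thin_counts(counts, -1), class = "subtypecurves_config_error")

  # 50% thinning expectation over 1000 seeds
  half <- round(totals[1] / 2)
  sums <- matrix(0, nrow(counts), 1000L)
  for (i in 1:1000) {
    sums[, i] <- thin_counts(counts[, 1, drop = FALSE], half, seed = i)
  }
  p <- half / totals[1]
  mc_se <- sqrt(counts[, 1] * p * (1 - p) / 1000)
  dev <- abs(rowMeans(sums) - p * counts[, 1])
  expect_true(all(dev <= 3 * mc_se + 1e-9))
})

test_that("PCA outlier flagging finds gross outliers and respects quantile 1", {
  co <- small_cohort()
  counts <- co$counts[, 1:60]
  counts[, 7] <- counts[, 7] * 100L
  # unit size factors: the inflation must reach the PCA, not be normalized away
  x <- normalize_log2(counts, size_factors = rep(1, 60))
  flags <- flag_outliers_pca(x, n_components = 3, 0.99, 0.99)
  expect_true(flags[7])
  # the gross outlier dominates one of the two distances
  rank_score <- rank(-attr(flags, "score_distance"))[7]
  rank_resid <- rank(-attr(flags, "residual_ss"))[7]
  expect_identical(min(rank_score, rank_resid), 1)
  expect_false(any(flag_outliers_pca(x, 3, 1.0, 1.0)))
  expect_error(flag_outliers_pca(x, n_components = 100),
    class = "subtypecurves_config_error"
  )
})

test_that("flagged fraction on homogeneous data matches the expected exceedance", {
  # score and residual criteria are near-independent for spherical data, so
  # the union flags about 1 - 0.95^2 of samples
  fracs <- vapply(1:40, function(i) {
    x <- withr::with_seed(i, matrix(rnorm(30 * 120), 30, 120,
      dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:120))
    ))
    mean(flag_outliers_pca(x, 3, 0.95, 0.95))
  }, numeric(1))
  expected <- 1 - 0.95^2
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 0.005)
})
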