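# Stratified sampling, metrics, and the nested-CV learning-curve engine.

test_that("stratified split apportions the reference class sizes as computed by hand", {
  labels <- factor(rep(
    c("Basal", "Her2", "LumA", "LumB", "Normal"),
    c(132, 65, 393, 190, 105)
  ))
  split <- stratified_split(labels, 0.10, seed = 5)
  expect_identical(length(split$test), 89L)
  expect_identical(
    as.integer(table(labels[split$test])),
    c(13L, 7L, 39L, 19L, 11L)
  )
  # disjoint and exhaustive
  expect_identical(sort(c(split$train, split$test)), seq_along(labels))

  expect_identical(length(stratified_split(labels, 0, seed = 1)$test), 0L)

  two <- factor(rep(c("A", "B"), each = 10))
  s2 <- stratified_split(two, 0.10, seed = 2)
  expect_identical(as.integer(table(two[s2$test])), c(1L, 1L))
})

test_that("stratified subsampling is proportional, nested in the pool, seeded", {
  labels <- factor(rep(
    c("Basal", "Her2", "LumA", "LumB", "Normal"),
    c(132, 65, 393, 190, 105)
  ))
  pool <- stratified_split(labels, 0.10, seed = 5)$train
  expect_identical(stratified_subsample(pool, labels, length(pool), seed = 1), sort(pool))

  sub <- stratified_subsample(pool, labels, 100, seed = 7)
  expect_identical(length(sub), 100L)
  expect_true(all(sub %in% pool))
  props <- as.numeric(table(labels[pool])) / length(pool)
  expect_true(all(abs(as.integer(table(labels[sub])) - 100 * props) <= 1))

  expect_identical(
    stratified_subsample(pool, labels, 100, seed = 7),
    stratified_subsample(pool, labels, 100, seed = 7)
  )
  expect_error(stratified_subsample(pool, labels, length(pool) + 1), "pool")
})

test_that("metrics reproduce hand-computable confusion matrices", {
  truth <- c("LumA", "LumA", "Basal", "Her2", "Normal")
  m <- metrics(truth, truth)
  expect_equal(m$accuracy, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_true(all(diag(m$rates)[rowSums(m$confusion) > 0] == 1))

  # all predicted as one class over 5 balanced classes
  classes <- c("Her2", "Basal", "LumA", "LumB", "Normal")
  truth5 <- rep(classes, each = 10)
  m5 <- metrics(truth5, rep("LumA", 50))
  expect_equal(m5$accuracy, 0.2)
  expect_equal(m5$balanced_accuracy, 0.2)

  # balanced accuracy equals overall accuracy on a class-balanced test set
  withr::with_seed(8, {
    pred <- sample(classes, 50, replace = TRUE)
  })
  mb <- metrics(truth5, pred)
  expect_equal(mb$balanced_accuracy, mb$accuracy, tolerance = 1e-12)

  expect_error(metrics(truth5, rep("??", 50), classes = classes), "Unknown label")
  expect_error(metrics(truth5[1:3], rep("LumA", 4)), "equal length")
})

test_that("balanced accuracy of a published-style rate matrix is the diagonal mean", {
  classes <- c("Her2", "Basal", "LumA", "LumB", "Normal")
  rates <- rbind(
    c(0.902, 0.008, 0.022, 0.068, 0),
    c(0.038, 0.961, 0, 0.001, 0),
    c(0.018, 0, 0.901, 0.062, 0.02),
    c(0.031, 0, 0.137, 0.832, 0),
    c(0.018, 0.019, 0.04, 0.019, 0.905)
  ) * 1000 # expand each row into ~1000 label pairs (rows carry print rounding)
  truth <- rep(classes, times = rowSums(rates))
  pred <- unlist(lapply(1:5, function(i) rep(classes, rates[i, ])))
  m <- metrics(truth, pred, classes = classes)
  expect_equal(m$balanced_accuracy, mean(diag(m$rates)), tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, 0.9002, tolerance = 5e-4)
  expect_equal(unname(rowSums(m$rates)), rep(1, 5), tolerance = 1e-9)
})

test_that("each nested round keeps the outer test untouched and is reproducible", {
  co <- small_cohort()
  x <- small_expr()[1:60, ]
  y <- co$annotation$subtype
  spec <- classifier_spec("nsc", grid = list(threshold = c(0, 1)))
  a <- evaluate_round(x, y, 120, spec, round_seed = 31)
  b <- evaluate_round(x, y, 120, spec, round_seed = 31)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$hyperparameters, b$hyperparameters)

  # the tuning pool and outer test are disjoint by construction
  split <- stratified_split(y, 0.10, seed = 31)
  sub <- stratified_subsample(split$train, y, 120, seed = 32)
  expect_length(intersect(sub, split$test), 0)

  expect_error(evaluate_round(x, y, 500, spec, round_seed = 1), "exceeds")
})

test_that("run_learning_curve aggregates a full factorial deterministically", {
  co <- small_cohort()
  cfg <- curve_config(
    training_sizes = c(90, 120), n_rounds = 2,
    classifiers = list(nsc = classifier_spec("nsc", grid = list(threshold = c(0, 1)))),
    datasets = list(
      panel = informative_panel(co, 30),
      top25 = 0.25
    ),
    inner_folds = 3, master_seed = 17
  )
  lc1 <- run_learning_curve(co, cfg)
  lc2 <- run_learning_curve(co, cfg)
  expect_identical(tidy(lc1), tidy(lc2))
  expect_identical(nrow(lc1$results), 2L * 2L * 2L) # rounds x sizes x datasets
  expect_identical(nrow(lc1$summary), 4L)
  expect_true(all(lc1$results$accuracy >= 0 & lc1$results$accuracy <= 1))
  expect_equal(lc1$summary$sem_accuracy, lc1$summary$sd_accuracy / sqrt(2))

  # single round: SEM zero by convention, with a warning
  cfg1 <- curve_config(
    training_sizes = 90, n_rounds = 1, inner_folds = 3,
    classifiers = list(nsc = classifier_spec("nsc", grid = list(threshold = 0))),
    datasets = list(top25 = 0.25), master_seed = 2
  )
  expect_warning(lc3 <- run_learning_curve(co, cfg1), "SEM")
  expect_identical(nrow(lc3$results), 1L)
  expect_equal(lc3$summary$sem_accuracy, 0)
})

test_that("read-depth thinning integrates into the factorial with renormalization", {
  co <- small_cohort()
  depth <- floor(min(colSums(co$counts)) / 4)
  cfg <- curve_config(
    training_sizes = 120, n_rounds = 1,
    classifiers = list(nsc = classifier_spec("nsc", grid = list(threshold = 0))),
    datasets = list(panel = informative_panel(co, 30)),
    read_depths = c(NA, depth), master_seed = 23
  )
  lc <- suppressWarnings(run_learning_curve(co, cfg))
  expect_identical(nrow(lc$results), 2L)
  expect_setequal(lc$results$depth, c(NA, depth))
})

test_that("confusion matrices pool across rounds into row-stochastic rates", {
  co <- small_cohort()
  cfg <- curve_config(
    training_sizes = 120, n_rounds = 3,
    classifiers = list(nsc = classifier_spec("nsc", grid = list(threshold = 0))),
    datasets = list(panel = informative_panel(co, 30)), master_seed = 5
  )
  lc <- run_learning_curve(co, cfg)
  cm <- pooled_confusion(lc, size == 120)
  expect_identical(sum(cm$counts), 3L * 20L) # 3 rounds x 20 test samples
  expect_equal(unname(rowSums(cm$rates)[rowSums(cm$counts) > 0]),
    rep(1, sum(rowSums(cm$counts) > 0)),
    tolerance = 1e-9
  )
})

test_that("configuration invariants are enforced", {
  expect_error(curve_config(training_sizes = c(100, 100)),
    class = "subtypecurves_config_error"
  )
  expect_error(curve_config(n_rounds = 0), class = "subtypecurves_config_error")
  expect_error(curve_config(classifiers = list(classifier_spec("nsc"))),
    class = "subtypecurves_config_error"
  )
})
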