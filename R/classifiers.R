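# A single train/predict/tune contract over the three classifier families:
# penalized multinomial regression (glmnet), random forest (ranger), and the
# in-package nearest shrunken centroids.

#' Specify a classifier family and its tuning grid
#'
#' @param family One of `"elastic_net"`, `"random_forest"`, `"nsc"`.
#' @param grid Named list of candidate hyperparameter values. Defaults:
#'   elastic net tunes `alpha` over 0.1..1.0 with a 20-value `lambda` path
#'   derived from the tuning data; random forest tunes `num_trees = 500` and
#'   `mtry` over `sqrt(p)` and `p/4`; NSC tunes `threshold` over a 15-point
#'   path from 0 to the largest standardized contrast. Entries left `NULL`
#'   are resolved from the data inside [tune()].
#' @param seed Integer seed used for any stochastic fitting (random forest).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("elastic_net", "random_forest", "nsc"),
                            grid = NULL, seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    elastic_net = list(alpha = seq(0.1, 1, by = 0.1), lambda = NULL),
    random_forest = list(num_trees = 500L, mtry = NULL),
    nsc = list(threshold = NULL)
  )
  grid <- modifyList(defaults, as.list(grid %||% list()))
  extra <- setdiff(names(grid), names(defaults))
  if (length(extra) > 0L) {
    abort(sprintf(
      "Unknown hyperparameter(s) for %s: %s.", family,
      paste(extra, collapse = ", ")
    ), class = "subtypecurves_config_error")
  }
  resolved <- grid[!vapply(grid, is.null, logical(1))]
  if (any(lengths(resolved) == 0L)) {
    abort("Every supplied grid entry must be non-empty.",
      class = "subtypecurves_config_error"
    )
  }
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# glmnet warns when a class has < 8 observations; small strata are routine
# in stratified inner folds on an imbalanced cohort, so that one warning is
# muffled (anything else propagates).
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Fill data-dependent grid defaults (lambda path, mtry, NSC threshold path).
resolve_grid <- function(spec, x, y) {
  grid <- spec$grid
  if (spec$family == "elastic_net" && is.null(grid$lambda)) {
    fit <- quiet_glmnet(glmnet::glmnet(t(x), y,
      family = "multinomial",
      alpha = max(unlist(grid$alpha)), nlambda = 20L
    ))
    grid$lambda <- fit$lambda
  }
  if (spec$family == "random_forest" && is.null(grid$mtry)) {
    p <- nrow(x)
    grid$mtry <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 4))))
  }
  if (spec$family == "nsc" && is.null(grid$threshold)) {
    grid$threshold <- nsc_threshold_path(x, y)
  }
  grid
}

grid_table <- function(grid) {
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(g)
}

#' Train a classifier and predict test labels
#'
#' One uniform contract for all three families. The training and test
#' matrices must carry identical, identically ordered gene sets. With a
#' single training class the model degenerates to always predicting that
#' class. Results are deterministic under a fixed `spec$seed`.
#'
#' @param spec A [classifier_spec()].
#' @param x_train,x_test Genes-by-samples expression matrices.
#' @param y_train Training labels.
#' @param hyperparameters Named list of concrete hyperparameter values (one
#'   value each); defaults to the first point of the resolved grid.
#' @return List with `labels` (factor, one per test sample), `scores`
#'   (samples x classes probability matrix, rows summing to 1) and
#'   `hyperparameters`.
#' @export
train_predict <- function(spec, x_train, y_train, x_test,
                          hyperparameters = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!identical(rownames(x_train), rownames(x_test))) {
    abort("Train and test gene sets must be identical and ordered identically.",
      class = "subtypecurves_structure_error"
    )
  }
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) == 1L) {
    only <- levels(y_train)
    scores <- matrix(1, ncol(x_test), 1L,
      dimnames = list(colnames(x_test), only)
    )
    return(list(
      labels = setNames(
        factor(rep(only, ncol(x_test)), levels = only), colnames(x_test)
      ),
      scores = scores, hyperparameters = hyperparameters %||% list()
    ))
  }
  if (is.null(hyperparameters)) {
    hyperparameters <- as.list(grid_table(resolve_grid(spec, x_train, y_train))[1L, ])
  }
  fit_fun <- switch(spec$family,
    elastic_net = predict_elastic_net,
    random_forest = predict_random_forest,
    nsc = predict_nsc_family
  )
  out <- fit_fun(x_train, y_train, x_test, hyperparameters, spec$seed)
  out$hyperparameters <- hyperparameters
  out
}

predict_elastic_net <- function(x_train, y_train, x_test, hp, seed) {
  fit <- quiet_glmnet(glmnet::glmnet(t(x_train), y_train,
    family = "multinomial", alpha = hp$alpha
  ))
  prob <- predict(fit, t(x_test), s = hp$lambda, type = "response")[, , 1L]
  prob <- matrix(prob,
    ncol = nlevels(y_train),
    dimnames = list(colnames(x_test), levels(y_train))
  )
  labels <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
    levels = levels(y_train)
  )
  list(labels = setNames(labels, colnames(x_test)), scores = prob)
}

predict_random_forest <- function(x_train, y_train, x_test, hp, seed) {
  fit <- ranger::ranger(
    x = t(x_train), y = y_train,
    num.trees = hp$num_trees, mtry = min(hp$mtry, nrow(x_train)),
    probability = TRUE, seed = seed, num.threads = 1L
  )
  prob <- predict(fit, t(x_test), num.threads = 1L)$predictions
  prob <- prob[, levels(y_train), drop = FALSE]
  rownames(prob) <- colnames(x_test)
  labels <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
    levels = levels(y_train)
  )
  list(labels = setNames(labels, colnames(x_test)), scores = prob)
}

predict_nsc_family <- function(x_train, y_train, x_test, hp, seed) {
  fit <- train_nsc(x_train, y_train, threshold = hp$threshold)
  predict(fit, x_test)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into folds, so fold class compositions differ by at most one.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    small <- names(which(table(y) < k))
    abort(sprintf(
      "Class(es) too small for %d-fold stratified CV: %s.",
      k, paste(small, collapse = ", ")
    ), class = "subtypecurves_training_error")
  }
  folds <- integer(length(y))
  withr::local_seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Tune hyperparameters by stratified inner cross-validation
#'
#' Evaluates every point of the (resolved) grid by k-fold stratified
#' cross-validation on the training data and returns the point with the
#' highest mean held-out accuracy; ties are broken by first occurrence in
#' grid order (first grid entry varying fastest).
#'
#' @param spec A [classifier_spec()].
#' @param x,y Training expression matrix and labels.
#' @param inner_folds Number of inner folds (>= 2); every class must have at
#'   least this many samples.
#' @param seed Integer seed for the fold assignment.
#' @return Named list of chosen hyperparameter values, with attribute
#'   `inner_accuracy` holding the per-grid-point mean accuracies.
#' @export
tune <- function(spec, x, y, inner_folds = 5L, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (inner_folds < 2L) {
    abort("`inner_folds` must be at least 2.",
      class = "subtypecurves_config_error"
    )
  }
  y <- droplevels(as.factor(y))
  grid <- grid_table(resolve_grid(spec, x, y))
  if (nrow(grid) == 1L) {
    chosen <- as.list(grid[1L, ])
    attr(chosen, "inner_accuracy") <- NA_real_
    return(chosen)
  }
  folds <- stratified_folds(y, inner_folds, seed)
  hits <- matrix(0, nrow(grid), inner_folds)
  weight <- tabulate(folds, inner_folds)
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    hits[, f] <- inner_fold_accuracy(
      spec, grid,
      x[, tr, drop = FALSE], y[tr], x[, !tr, drop = FALSE], y[!tr]
    )
  }
  mean_acc <- as.vector(hits %*% weight) / sum(weight)
  best <- which.max(mean_acc) # first occurrence on ties
  chosen <- as.list(grid[best, ])
  attr(chosen, "inner_accuracy") <- mean_acc
  chosen
}

# Per-fold accuracy for every grid row. The elastic-net family is evaluated
# per alpha with one path fit covering all lambdas; other families refit per
# grid row.
inner_fold_accuracy <- function(spec, grid, x_tr, y_tr, x_te, y_te) {
  acc <- numeric(nrow(grid))
  if (spec$family == "elastic_net") {
    for (a in unique(grid$alpha)) {
      rows <- which(grid$alpha == a)
      fit <- quiet_glmnet(
        glmnet::glmnet(t(x_tr), y_tr, family = "multinomial", alpha = a)
      )
      prob <- predict(fit, t(x_te), s = grid$lambda[rows], type = "response")
      cls <- dimnames(prob)[[2L]]
      for (i in seq_along(rows)) {
        pred <- cls[max.col(
          matrix(prob[, , i], ncol = length(cls)),
          ties.method = "first"
        )]
        acc[rows[i]] <- mean(pred == as.character(y_te))
      }
    }
  } else {
    for (g in seq_len(nrow(grid))) {
      pred <- train_predict(spec, x_tr, y_tr, x_te,
        hyperparameters = as.list(grid[g, ])
      )$labels
      acc[g] <- mean(as.character(pred) == as.character(y_te))
    }
  }
  acc
}
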