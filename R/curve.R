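# The nested cross-validation learning-curve engine: stratified outer
# holdout, stratified training subsets of increasing size, inner-CV tuning,
# and accuracy/balanced-accuracy/confusion metrics aggregated across rounds.

#' Stratified train/test split
#'
#' Draws a class-balanced test set: the test total is `test_fraction * N`
#' (rounded half-up) and per-class test counts follow largest-remainder
#' apportionment of the class sizes, so test classes are in the same
#' proportion as the full cohort. For class sizes (132, 65, 393, 190, 105)
#' at 10% this gives a test set of 89 with per-class counts (13, 7, 39, 19, 11).
#'
#' @param labels Class labels (factor or character), or a data frame with a
#'   `subtype` column.
#' @param test_fraction Fraction of samples held out.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.10, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$subtype
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) == 0L)) {
    abort("Every class must have at least one sample.")
  }
  n_test <- round_half_up(test_fraction * length(labels))
  class_sizes <- table(labels)
  per_class <- apportion_largest_remainder(n_test, as.numeric(class_sizes))
  withr::local_seed(seed)
  test <- integer(0)
  for (k in seq_along(class_sizes)) {
    idx <- which(labels == names(class_sizes)[k])
    test <- c(test, sample(idx, per_class[k]))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Stratified subsample from a pool
#'
#' Selects `n` samples from `pool` with class composition proportional to the
#' pool's composition (largest-remainder apportionment).
#'
#' @param pool Integer indices available for sampling.
#' @param labels Class labels for the full cohort (factor/character), or a
#'   data frame with a `subtype` column.
#' @param n Subset size, at most `length(pool)`.
#' @param seed Integer seed.
#' @return Sorted integer vector of `n` indices, a subset of `pool`.
#' @export
stratified_subsample <- function(pool, labels, n, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$subtype
  labels <- as.factor(labels)
  if (n > length(pool)) {
    abort(sprintf("Cannot draw %d samples from a pool of %d.", n, length(pool)))
  }
  pool_labels <- droplevels(labels[pool])
  class_sizes <- table(pool_labels)
  per_class <- apportion_largest_remainder(n, as.numeric(class_sizes))
  withr::local_seed(seed)
  out <- integer(0)
  for (k in seq_along(class_sizes)) {
    idx <- pool[pool_labels == names(class_sizes)[k]]
    out <- c(out, sample(idx, min(per_class[k], length(idx))))
  }
  sort(out)
}

#' Classification metrics with confusion matrix
#'
#' Overall accuracy (correct / total), per-class accuracy (class-wise recall,
#' the diagonal of the row-normalized confusion matrix) and balanced accuracy
#' (unweighted mean of per-class accuracies over classes present in the
#' truth).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class set and report order; defaults to the fixed subtype
#'   report order (Her2, Basal, LumA, LumB, Normal) when the labels are
#'   subtypes, otherwise to the sorted union of observed labels.
#' @return List with `accuracy`, `balanced_accuracy`, `per_class` (tibble of
#'   class/n/accuracy), `confusion` (count matrix, true classes in rows) and
#'   `rates` (row-normalized confusion matrix).
#' @export
metrics <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (is.null(classes)) {
    seen <- union(truth, predicted)
    classes <- if (all(seen %in% report_levels())) {
      intersect(report_levels(), seen)
    } else {
      sort(seen)
    }
  }
  unknown <- setdiff(union(truth, predicted), classes)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown label(s): %s.", paste(unknown, collapse = ", ")))
  }
  confusion <- table(
    factor(truth, levels = classes), factor(predicted, levels = classes)
  )
  confusion <- matrix(confusion,
    nrow = length(classes),
    dimnames = list(true = classes, predicted = classes)
  )
  row_totals <- rowSums(confusion)
  rates <- confusion / ifelse(row_totals > 0, row_totals, 1)
  per_class_acc <- diag(rates)
  present <- row_totals > 0
  list(
    accuracy = mean(truth == predicted),
    balanced_accuracy = mean(per_class_acc[present]),
    per_class = tibble::tibble(
      class = classes, n = as.integer(row_totals),
      accuracy = ifelse(present, per_class_acc, NA_real_)
    ),
    confusion = confusion,
    rates = rates
  )
}

#' Configuration for learning-curve experiments
#'
#' @param training_sizes Strictly increasing training-set sizes (default 100
#'   to 750).
#' @param test_fraction Outer holdout fraction (default 0.10).
#' @param n_rounds Number of independent outer cross-validation rounds
#'   (default 100); each round redraws the stratified holdout.
#' @param classifiers Named list of [classifier_spec()]s.
#' @param datasets Named list of feature-set definitions: a character vector
#'   is treated as a gene panel ([subset_panel()]), a single number in (0, 1]
#'   as a variance-filter fraction ([variance_filter()]).
#' @param read_depths Optional vector of target total read counts per sample;
#'   `NA` means the full, unthinned data. Thinned counts are renormalized
#'   (size factors recomputed) before use.
#' @param inner_folds Inner CV folds for tuning.
#' @param master_seed Master seed; spawns all per-round and per-depth seeds.
#' @return A `curve_config` list.
#' @export
curve_config <- function(training_sizes = seq(100L, 750L, by = 50L),
                         test_fraction = 0.10,
                         n_rounds = 100L,
                         classifiers = list(elastic_net = classifier_spec("elastic_net")),
                         datasets = list(top25 = 0.25),
                         read_depths = NA,
                         inner_folds = 5L,
                         master_seed = 1L) {
  if (any(diff(training_sizes) <= 0) || any(training_sizes < 1)) {
    abort("`training_sizes` must be strictly increasing positive integers.",
      class = "subtypecurves_config_error"
    )
  }
  if (n_rounds < 1) {
    abort("`n_rounds` must be positive.", class = "subtypecurves_config_error")
  }
  if (is.null(names(classifiers)) || any(names(classifiers) == "")) {
    abort("`classifiers` must be a named list.",
      class = "subtypecurves_config_error"
    )
  }
  structure(
    list(
      training_sizes = as.integer(training_sizes),
      test_fraction = test_fraction, n_rounds = as.integer(n_rounds),
      classifiers = classifiers, datasets = datasets,
      read_depths = read_depths, inner_folds = as.integer(inner_folds),
      master_seed = as.integer(master_seed)
    ),
    class = "curve_config"
  )
}

build_dataset <- function(expr, definition) {
  if (is.character(definition)) {
    suppressWarnings(subset_panel(expr, definition))
  } else if (is.numeric(definition) && length(definition) == 1L) {
    variance_filter(expr, definition)
  } else {
    abort("Dataset definition must be a gene panel or a variance fraction.",
      class = "subtypecurves_config_error"
    )
  }
}

#' One nested cross-validation round
#'
#' Draws the stratified outer holdout, subsamples the remaining pool to the
#' requested training size, tunes the classifier by stratified inner CV on
#' that training set only, refits with the chosen hyperparameters, and scores
#' predictions on the untouched outer test set.
#'
#' @param expr Genes-by-samples expression matrix (one dataset).
#' @param labels Per-sample class labels (same order as columns).
#' @param size Training-set size.
#' @param spec A [classifier_spec()].
#' @param round_seed Integer seed for this round's splits.
#' @param test_fraction Outer holdout fraction.
#' @param inner_folds Inner CV folds.
#' @return One-row tibble: accuracy, balanced accuracy, chosen
#'   hyperparameters, plus list-columns `per_class` and `confusion`.
#' @export
evaluate_round <- function(expr, labels, size, spec, round_seed,
                           test_fraction = 0.10, inner_folds = 5L) {
  labels <- droplevels(as.factor(labels))
  split <- stratified_split(labels, test_fraction, seed = round_seed)
  if (size > length(split$train)) {
    abort(sprintf(
      "Training size %d exceeds the available pool of %d.",
      size, length(split$train)
    ))
  }
  train_idx <- stratified_subsample(
    split$train, labels, size,
    seed = round_seed + 1L
  )
  x_tr <- expr[, train_idx, drop = FALSE]
  y_tr <- labels[train_idx]
  x_te <- expr[, split$test, drop = FALSE]
  y_te <- labels[split$test]
  chosen <- tune(spec, x_tr, y_tr, inner_folds = inner_folds, seed = round_seed + 2L)
  pred <- train_predict(spec, x_tr, y_tr, x_te,
    hyperparameters = as.list(chosen)
  )
  m <- metrics(y_te, pred$labels, classes = resolve_report_classes(labels))
  tibble::tibble(
    accuracy = m$accuracy,
    balanced_accuracy = m$balanced_accuracy,
    hyperparameters = list(as.list(chosen)),
    per_class = list(m$per_class),
    confusion = list(m$confusion)
  )
}

resolve_report_classes <- function(labels) {
  lv <- levels(as.factor(labels))
  if (all(lv %in% report_levels())) intersect(report_levels(), lv) else lv
}

#' Run the full learning-curve experiment
#'
#' Full factorial over rounds x training sizes x classifiers x datasets x
#' read depths. Each read depth thins the counts ([thin_counts()]) and
#' recomputes size factors before normalization; each dataset definition is
#' applied to the normalized expression; each round draws an independent
#' stratified outer holdout. Per-condition means and standard errors of the
#' mean (SEM = SD / sqrt(n_rounds); 0 by convention for a single round) are
#' aggregated in the `summary` component.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `counts` and
#'   `annotation` in the same shape.
#' @param config A [curve_config()].
#' @param labels Optional label vector overriding `annotation$subtype`.
#' @return A `learning_curve` object: list with `results` (one row per round
#'   x condition), `summary` (per-condition mean/SD/SEM) and `config`.
#' @export
run_learning_curve <- function(cohort, config, labels = NULL) {
  stopifnot(inherits(config, "curve_config"))
  labels <- labels %||% cohort$annotation$subtype
  labels <- droplevels(as.factor(labels))
  depths <- config$read_depths
  seeds <- derive_seeds(config$master_seed, config$n_rounds * 3L + length(depths))
  round_seeds <- seeds[seq_len(config$n_rounds) * 3L]
  depth_seeds <- seeds[config$n_rounds * 3L + seq_along(depths)]

  grid <- tidyr::expand_grid(
    depth = depths,
    dataset = names(config$datasets)
  )
  results <- purrr::pmap(grid, function(depth, dataset) {
    counts <- cohort$counts
    if (!is.na(depth)) {
      counts <- thin_counts(counts, depth,
        seed = depth_seeds[match(depth, depths)]
      )
    }
    expr <- normalize_log2(counts)
    x <- build_dataset(expr, config$datasets[[dataset]])
    per_round <- purrr::map(seq_len(config$n_rounds), function(r) {
      purrr::imap(config$classifiers, function(spec, cname) {
        per_size <- purrr::map(config$training_sizes, function(size) {
          pool_max <- length(labels) -
            round_half_up(config$test_fraction * length(labels))
          if (size > pool_max) {
            warn(sprintf(
              "Training size %d infeasible for cohort of %d; skipped.",
              size, length(labels)
            ))
            return(NULL)
          }
          rec <- evaluate_round(
            x, labels, size, spec,
            round_seed = round_seeds[r] + size,
            test_fraction = config$test_fraction,
            inner_folds = config$inner_folds
          )
          dplyr::mutate(rec, size = size, .before = 1L)
        })
        dplyr::mutate(
          dplyr::bind_rows(per_size),
          classifier = cname, .before = 1L
        )
      }) |> dplyr::bind_rows()
    })
    dplyr::bind_rows(per_round, .id = "round") |>
      dplyr::mutate(
        round = as.integer(.data$round),
        dataset = dataset, depth = depth, .before = 1L
      )
  }) |> dplyr::bind_rows()

  new_learning_curve(results, config)
}

new_learning_curve <- function(results, config) {
  structure(
    list(
      results = results,
      summary = summarize_curve(results),
      config = config
    ),
    class = "learning_curve"
  )
}

#' Summarize per-round learning-curve results
#'
#' Per (dataset, depth, classifier, size) condition: mean, SD and standard
#' error of the cross-validation mean (SEM = SD / sqrt(rounds)) for accuracy
#' and balanced accuracy. With a single round the SEM is reported as 0 (with
#' a warning).
#'
#' @param results Tidy per-round results tibble (from a `learning_curve`
#'   object or its `tidy()` method).
#' @return Per-condition summary tibble.
#' @export
summarize_curve <- function(results) {
  if (inherits(results, "learning_curve")) results <- results$results
  if (nrow(results) == 0L) abort("No results to summarize.")
  group_cols <- intersect(
    c("dataset", "depth", "classifier", "size"), names(results)
  )
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_rounds = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = ifelse(dplyr::n() > 1L, sd(.data$accuracy), 0),
      mean_balanced_accuracy = mean(.data$balanced_accuracy),
      sd_balanced_accuracy = ifelse(
        dplyr::n() > 1L, sd(.data$balanced_accuracy), 0
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sem_accuracy = .data$sd_accuracy / sqrt(.data$n_rounds),
      sem_balanced_accuracy = .data$sd_balanced_accuracy / sqrt(.data$n_rounds)
    )
  if (any(out$n_rounds == 1L)) {
    warn("Single-round conditions present; their SEM is reported as 0.")
  }
  out
}

#' Pool confusion matrices across rounds
#'
#' Sums the per-round confusion counts for one condition and row-normalizes,
#' giving the aggregate misclassification pattern across cross-validation
#' rounds.
#'
#' @param curve A `learning_curve` object.
#' @param ... Filtering conditions passed to [dplyr::filter()] on the
#'   per-round results (e.g. `size == 350`, `classifier == "elastic_net"`).
#' @return List with `counts` and row-normalized `rates` matrices.
#' @export
pooled_confusion <- function(curve, ...) {
  stopifnot(inherits(curve, "learning_curve"))
  rows <- dplyr::filter(curve$results, ...)
  if (nrow(rows) == 0L) abort("No rows match the given condition.")
  total <- Reduce(`+`, rows$confusion)
  rt <- rowSums(total)
  list(counts = total, rates = total / ifelse(rt > 0, rt, 1))
}
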