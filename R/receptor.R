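# Single-gene logistic receptor-status models with ROC / Youden cutoff
# selection, and their learning curves.

#' Fit a single-gene logistic receptor-status model
#'
#' Logistic regression of clinical receptor status (positive/negative) on the
#' expression of one marker gene (ESR1 for ER, PGR for PR, ERBB2 for Her2).
#' The fitted score is monotone in the predictor, so score rankings — and
#' hence the ROC curve — are invariant to affine rescaling of the predictor.
#'
#' @param expression Numeric vector, one marker-gene expression value per
#'   sample.
#' @param status Binary labels; factor with levels `c("neg", "pos")`, or any
#'   two-level vector (the second sorted level is treated as positive).
#' @return A `receptor_model`: list with the `glm` fit and a
#'   `score(expression)` function returning positive-class probabilities.
#' @export
fit_receptor_model <- function(expression, status) {
  status <- as.factor(status)
  status <- droplevels(status)
  if (nlevels(status) != 2L) {
    abort("`status` must contain exactly two classes.",
      class = "subtypecurves_training_error"
    )
  }
  y <- as.integer(status == levels(status)[2L])
  df <- data.frame(y = y, x = expression)
  # perfect separation is legitimate here (scores are only ranked)
  fit <- suppressWarnings(glm(y ~ x, family = binomial(), data = df))
  structure(
    list(
      fit = fit,
      levels = levels(status),
      score = function(expression) {
        as.numeric(predict(fit,
          newdata = data.frame(x = expression),
          type = "response"
        ))
      }
    ),
    class = "receptor_model"
  )
}

#' ROC curve over exhaustive score cutpoints
#'
#' Candidate cutpoints are the midpoints between adjacent distinct sorted
#' scores, plus -Inf and +Inf sentinels; a sample is called positive when its
#' score exceeds the cutpoint. Sensitivity, specificity and Youden's
#' J = sensitivity + specificity - 1 are reported at every cutpoint, and the
#' AUC is computed by the rank (Mann-Whitney) statistic with tie correction.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; `TRUE`/`"pos"`/second factor level = positive.
#' @return A `roc_result` tibble with columns `cutpoint`, `sensitivity`,
#'   `specificity`, `youden`, and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- normalize_binary(labels)
  if (length(scores) != length(pos)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (!any(pos) || all(pos)) {
    abort("Both classes must be present to compute a ROC curve.",
      class = "subtypecurves_training_error"
    )
  }
  s <- sort(unique(scores))
  cuts <- c(-Inf, if (length(s) > 1L) (head(s, -1L) + s[-1L]) / 2, Inf)
  sens <- vapply(cuts, function(cc) mean(scores[pos] > cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores[!pos] <= cc), numeric(1))
  r <- rank(scores)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  out <- tibble::tibble(
    cutpoint = cuts, sensitivity = sens, specificity = spec,
    youden = sens + spec - 1
  )
  attr(out, "auc") <- auc
  class(out) <- c("roc_result", class(out))
  out
}

normalize_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- droplevels(as.factor(labels))
  if (nlevels(f) > 2L) abort("Binary labels expected.")
  positive <- if ("pos" %in% levels(f)) "pos" else levels(f)[nlevels(f)]
  f == positive
}

#' Youden-optimal cutpoint
#'
#' Returns the cutpoint maximizing Youden's J; ties are broken toward higher
#' specificity (and, among equal-specificity ties, the larger cutpoint).
#'
#' @param roc A [roc_curve()] result.
#' @return Single numeric cutpoint.
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result") || nrow(roc) == 0L) {
    abort("`roc` must be a non-empty roc_result.")
  }
  ord <- order(-roc$youden, -roc$specificity, -roc$cutpoint)
  roc$cutpoint[ord[1L]]
}

#' Receptor-status learning curve
#'
#' Per round: a stratified 10% holdout on the receptor labels; for each
#' training size, a stratified training subset; logistic fit of status on the
#' marker gene; ROC and Youden cutoff computed on the *training* scores only;
#' the cutoff applied unchanged to the test scores, and test accuracy
#' recorded. Sensitivity, specificity and training AUC are also emitted.
#'
#' @param cohort A [simulate_cohort()] result (or list with `counts` and
#'   `annotation`).
#' @param marker_gene Predictor gene, e.g. `"ESR1"`.
#' @param receptor Annotation column with the status labels, e.g. `"ER"`.
#' @param config A [curve_config()] (classifier/dataset entries are ignored).
#' @return A `learning_curve` object with binary-accuracy results.
#' @export
run_receptor_curve <- function(cohort, marker_gene = "ESR1", receptor = "ER",
                               config = curve_config()) {
  if (!marker_gene %in% rownames(cohort$counts)) {
    abort(sprintf("Marker gene %s not present in the cohort.", marker_gene),
      class = "subtypecurves_structure_error"
    )
  }
  status <- cohort$annotation[[receptor]]
  if (length(unique(status)) < 2L) {
    abort("Both receptor statuses must be present.",
      class = "subtypecurves_training_error"
    )
  }
  expr <- normalize_log2(cohort$counts)[marker_gene, ]
  round_seeds <- derive_seeds(config$master_seed, config$n_rounds)

  results <- purrr::map(seq_len(config$n_rounds), function(r) {
    split <- stratified_split(status, config$test_fraction, seed = round_seeds[r])
    purrr::map(config$training_sizes, function(size) {
      if (size > length(split$train)) {
        warn(sprintf("Training size %d infeasible; skipped.", size))
        return(NULL)
      }
      train_idx <- stratified_subsample(
        split$train, status, size,
        seed = round_seeds[r] + size
      )
      y_tr <- droplevels(as.factor(status[train_idx]))
      if (nlevels(y_tr) < 2L) {
        warn(sprintf(
          "Round %d size %d: a status level is missing in the stratum; skipped.",
          r, size
        ))
        return(NULL)
      }
      model <- fit_receptor_model(expr[train_idx], y_tr)
      roc <- roc_curve(model$score(expr[train_idx]), y_tr)
      cut <- youden_cutoff(roc)
      test_scores <- model$score(expr[split$test])
      truth_pos <- normalize_binary(status[split$test])
      pred_pos <- test_scores > cut
      m <- metrics(
        ifelse(truth_pos, "pos", "neg"), ifelse(pred_pos, "pos", "neg"),
        classes = c("neg", "pos")
      )
      tibble::tibble(
        size = size,
        accuracy = m$accuracy,
        balanced_accuracy = m$balanced_accuracy,
        sensitivity = if (any(truth_pos)) mean(pred_pos[truth_pos]) else NA_real_,
        specificity = if (any(!truth_pos)) mean(!pred_pos[!truth_pos]) else NA_real_,
        cutoff = cut,
        train_auc = attr(roc, "auc"),
        per_class = list(m$per_class),
        confusion = list(m$confusion)
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows(.id = "round") |>
    dplyr::mutate(
      round = as.integer(.data$round),
      classifier = paste0("logistic_", marker_gene),
      dataset = receptor, .before = 1L
    )
  new_learning_curve(results, config)
}
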