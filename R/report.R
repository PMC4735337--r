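# YAML-driven experiment runner and report assembly.

#' Run experiments from a YAML configuration file
#'
#' Executes the selected experiments end-to-end and writes tidy result
#' tables, per-condition summaries, pooled confusion matrices and a JSON run
#' manifest (seed, package version, config echo) to the output directory.
#' Identical config and seed give byte-identical outputs.
#'
#' The YAML schema:
#' \preformatted{
#' cohort:                # exactly one of `synthetic:` or `files:`
#'   synthetic: {n_samples: 200, seed: 1, ...}   # cohort_config() fields
#'   files: {counts: counts.tsv, annotation: ann.tsv}
#' curve:                 # curve_config() fields; classifiers by family name
#'   training_sizes: [100, 200]
#'   n_rounds: 3
#'   classifiers: [nsc]
#'   datasets: {panel: {n_genes: 50}}   # or {top25: 0.25} / gene-ID lists
#' experiments: [supervised, receptor, unsupervised]
#' unsupervised: {alpha: 0.05, n_sim: 50}
#' output_dir: results/
#' }
#'
#' @param path Path to the YAML config.
#' @return Invisibly, a named list of the `learning_curve` objects produced.
#' @export
run_from_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
      class = "subtypecurves_config_error"
    )
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("cohort", "experiments", "output_dir")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("Config field `%s` is required.", field),
        class = "subtypecurves_config_error"
      )
    }
  }
  sources <- intersect(c("synthetic", "files"), names(cfg$cohort))
  if (length(sources) != 1L) {
    abort("`cohort` must contain exactly one of `synthetic` or `files`.",
      class = "subtypecurves_config_error"
    )
  }
  cohort <- if (sources == "synthetic") {
    simulate_cohort(do.call(cohort_config, cfg$cohort$synthetic))
  } else {
    for (f in unlist(cfg$cohort$files)) {
      if (!file.exists(f)) {
        abort(sprintf("Cohort file not found: %s", f),
          class = "subtypecurves_config_error"
        )
      }
    }
    counts <- read_count_matrix(cfg$cohort$files$counts)
    list(counts = counts, annotation = read_annotation(cfg$cohort$files$annotation))
  }

  curve_cfg <- build_curve_config(cfg$curve %||% list(), cohort)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- list()
  for (exp in cfg$experiments) {
    runs[[exp]] <- switch(exp,
      supervised = run_learning_curve(cohort, curve_cfg),
      depth = run_learning_curve(cohort, curve_cfg),
      receptor = {
        markers <- cfg$receptor$markers %||%
          list(ER = "ESR1", PR = "PGR", Her2 = "ERBB2")
        per <- purrr::imap(markers, function(gene, rec) {
          run_receptor_curve(cohort, gene, rec, curve_cfg)$results
        })
        new_learning_curve(dplyr::bind_rows(per), curve_cfg)
      },
      unsupervised = run_unsupervised_curve(
        cohort, curve_cfg,
        alpha = cfg$unsupervised$alpha %||% 0.05,
        n_sim = cfg$unsupervised$n_sim %||% 100L
      ),
      abort(sprintf("Unknown experiment `%s`.", exp),
        class = "subtypecurves_config_error"
      )
    )
    write_curve_outputs(runs[[exp]], cfg$output_dir, exp)
  }

  manifest <- list(
    config = cfg,
    master_seed = curve_cfg$master_seed,
    package_version = as.character(utils::packageVersion("subtypecurves")),
    experiments = names(runs)
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
    file.path(cfg$output_dir, "manifest.json")
  )
  invisible(runs)
}

build_curve_config <- function(curve, cohort) {
  classifiers <- curve$classifiers %||% list("elastic_net")
  if (is.character(classifiers)) classifiers <- as.list(classifiers)
  specs <- setNames(
    lapply(classifiers, function(cl) {
      classifier_spec(cl, seed = curve$master_seed %||% 1L)
    }),
    vapply(classifiers, identity, character(1))
  )
  datasets <- purrr::imap(curve$datasets %||% list(top25 = 0.25), function(d, nm) {
    if (is.list(d) && !is.null(d$n_genes)) {
      informative_panel(cohort, d$n_genes)
    } else if (is.character(d) && length(d) > 1L) {
      d
    } else {
      as.numeric(d)
    }
  })
  curve_config(
    training_sizes = curve$training_sizes %||% seq(100L, 750L, 50L),
    test_fraction = curve$test_fraction %||% 0.10,
    n_rounds = curve$n_rounds %||% 100L,
    classifiers = specs,
    datasets = datasets,
    read_depths = curve$read_depths %||% NA,
    inner_folds = curve$inner_folds %||% 5L,
    master_seed = curve$master_seed %||% 1L
  )
}

write_curve_outputs <- function(curve, out_dir, prefix) {
  per_round <- tidy(curve)
  readr::write_tsv(per_round, file.path(out_dir, paste0(prefix, "_rounds.tsv")))
  readr::write_tsv(glance(curve), file.path(out_dir, paste0(prefix, "_summary.tsv")))
  conditions <- dplyr::distinct(
    curve$results,
    dplyr::across(dplyr::any_of(c("dataset", "classifier", "size")))
  )
  largest <- conditions[conditions$size == max(conditions$size), , drop = FALSE]
  for (i in seq_len(nrow(largest))) {
    cm <- pooled_confusion(
      curve,
      .data$dataset == largest$dataset[i],
      .data$classifier == largest$classifier[i],
      .data$size == largest$size[i]
    )
    readr::write_tsv(
      tibble::as_tibble(round(cm$rates, 4), rownames = "true_label"),
      file.path(out_dir, sprintf(
        "%s_confusion_%s_%s_n%d.tsv",
        prefix, largest$dataset[i], largest$classifier[i], largest$size[i]
      ))
    )
  }
  invisible(out_dir)
}
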