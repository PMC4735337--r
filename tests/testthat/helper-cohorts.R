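# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small general-purpose cohort: modest depth, clear but imperfect signal.
small_cohort <- function() {
  cached("small", function() {
    simulate_cohort(cohort_config(
      n_samples = 200, n_genes = 400, n_informative = 120,
      effect_size = 1, dispersion = 0.2, library_size_mean = 1e5,
      seed = 101
    ))
  })
}

# Strongly separated cohort (easy classification / clustering).
separable_cohort <- function() {
  cached("separable", function() {
    simulate_cohort(cohort_config(
      n_samples = 150, n_genes = 300, n_informative = 150,
      effect_size = 3, dispersion = 0.1, lumAB_correlation = 0.2,
      library_size_mean = 2e5, receptor_noise_rate = 0, marker_shift = 4,
      seed = 202
    ))
  })
}

# Zero-signal cohort: no subtype effects, no marker shifts.
null_cohort <- function() {
  cached("null", function() {
    simulate_cohort(cohort_config(
      n_samples = 300, n_genes = 300, n_informative = 100,
      effect_size = 0, marker_shift = 0, library_size_mean = 1e5,
      seed = 303
    ))
  })
}

small_expr <- function() cached("small_expr", function() {
  normalize_log2(small_cohort()$counts)
})

separable_expr <- function() cached("separable_expr", function() {
  normalize_log2(separable_cohort()$counts)
})

# Deterministic dense count matrix for oracle tests.
toy_counts <- function(n_genes = 50, n_samples = 6, seed = 7, lambda = 60) {
  withr::with_seed(seed, {
    m <- matrix(
      rpois(n_genes * n_samples, lambda), n_genes, n_samples,
      dimnames = list(
        sprintf("g%03d", seq_len(n_genes)), sprintf("s%02d", seq_len(n_samples))
      )
    )
    storage.mode(m) <- "integer"
    m
  })
}
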