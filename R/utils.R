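# Internal helpers shared across the pipeline.

#' Largest-remainder apportionment
#'
#' Allocates an integer `total` across categories proportionally to `weights`,
#' using the largest-remainder (Hamilton) method: each category receives the
#' floor of its exact quota, and remaining units go to the categories with the
#' largest fractional remainders (ties broken by category order). Unlike
#' multinomial sampling, the allocation is deterministic and always sums to
#' `total`, which is what stratified splits and subsamples need.
#'
#' @param total Non-negative integer to distribute.
#' @param weights Non-negative numeric weights, at least one positive.
#' @return Integer vector of the same length as `weights`, summing to `total`.
#' @examples
#' apportion_largest_remainder(89, c(132, 65, 393, 190, 105))
#' @export
apportion_largest_remainder <- function(total, weights) {
  if (length(total) != 1L || is.na(total) || total < 0) {
    abort("`total` must be a single non-negative integer.")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative with a positive sum.")
  }
  quota <- total * weights / sum(weights)
  alloc <- floor(quota)
  left <- as.integer(round(total - sum(alloc)))
  if (left > 0L) {
    take <- order(-(quota - alloc), seq_along(quota))[seq_len(left)]
    alloc[take] <- alloc[take] + 1
  }
  as.integer(alloc)
}

# Round half away from zero (base round() rounds half to even, which would
# turn a 88.5-sample test quota into 88 rather than 89).
round_half_up <- function(x) floor(x + 0.5)

# Spawn `n` child seeds from a master seed, deterministically and independent
# of the caller's RNG state. Kept well below .Machine$integer.max so that
# small per-size offsets added downstream cannot overflow.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(2^30, n))
}

# Subtype class labels in generation order (matches class_proportions order)
# and in the fixed order used for confusion-matrix reports.
subtype_levels <- function() c("Basal", "Her2", "LumA", "LumB", "Normal")
report_levels <- function() c("Her2", "Basal", "LumA", "LumB", "Normal")

check_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric genes-by-samples matrix.", arg))
  }
  if (any(counts < 0)) abort(sprintf("`%s` contains negative entries.", arg))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames.", arg))
  }
  invisible(counts)
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}
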