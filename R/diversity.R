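#' Richness: number of distinct events
#'
#' @param counts Named numeric vector of event counts, or a tibble with an
#'   `event` column.
#' @return Integer count of events with positive count.
#' @export
richness <- function(counts) {
  if (is.data.frame(counts)) return(dplyr::n_distinct(counts$event))
  sum(counts > 0)
}

#' Shannon index (alpha diversity, bits)
#'
#' `SI = -sum(p * log2(p))` over event proportions; `0 log 0` is 0 and an
#' empty sample has index 0.
#'
#' @param counts Numeric vector of event counts (or a tibble with a
#'   `count` column).
#' @return Shannon index in bits.
#' @export
shannon_index <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Sorensen-Dice dissimilarity between two event sets
#'
#' `1 - 2J/(A + B)` with J the number of shared events and A, B the set
#' sizes; presence/absence only.  Two empty sets are defined as identical
#' (0).
#'
#' @param set_a,set_b Vectors of event identifiers.
#' @return Dissimilarity in `[0, 1]`.
#' @export
sorensen_dice <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) return(0)
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-sample alpha diversity table
#'
#' @param events Tibble with `sample_id` and `event` columns (one row per
#'   observation, or with a `count` column).
#' @return Tibble: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(events) {
  if (!"count" %in% names(events)) {
    events <- dplyr::count(events, .data$sample_id, .data$event,
                           name = "count")
  }
  events |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(richness = dplyr::n_distinct(.data$event),
                     shannon = shannon_index(.data$count),
                     .groups = "drop")
}

#' Pairwise Sorensen-Dice dissimilarity matrix
#'
#' @param events Tibble with `sample_id` and `event` columns.
#' @return Symmetric matrix with zero diagonal, one row/column per sample.
#' @export
beta_diversity_matrix <- function(events) {
  samples <- sort(unique(events$sample_id))
  stopifnot(length(samples) >= 1)
  sets <- lapply(samples, function(s)
    unique(events$event[events$sample_id == s]))
  n <- length(samples)
  m <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- sorensen_dice(sets[[i]], sets[[j]])
    }
  }
  m + t(m)
}

#' Subsample all samples to the smallest sample size
#'
#' Seeded sampling without replacement, so groups are compared at equal
#' depth.
#'
#' @param samples Named list of vectors (or tibbles of reads/events).
#' @param seed Integer seed.
#' @return List of the same shape with every element reduced to the
#'   minimum size.
#' @export
subsample_to_min <- function(samples, seed = 1) {
  sizes <- vapply(samples, function(s)
    if (is.data.frame(s)) nrow(s) else length(s), integer(1))
  n_min <- min(sizes)
  withr::with_seed(derive_seed(seed, "subsample"), {
    lapply(samples, function(s) {
      n <- if (is.data.frame(s)) nrow(s) else length(s)
      idx <- sort(sample.int(n, n_min))
      if (is.data.frame(s)) s[idx, ] else s[idx]
    })
  })
}
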