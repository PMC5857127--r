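#' Quality-control configuration (step 1)
#'
#' @param quality_threshold Phred score below which a base counts as
#'   low quality.
#' @param low_quality_fraction Fraction of bases that must be below the
#'   threshold for the read to be excluded ("at least" — inclusive).
#' @param complexity_entropy_min Minimum Shannon entropy (bits) of the
#'   overlapping-dinucleotide distribution; below it a read is low
#'   complexity.
#' @param max_homopolymer_fraction Longest single-base run, as a fraction
#'   of read length, at or above which a read is low complexity.
#' @param rdna_min_identity,rdna_min_aligned_fraction Identity and coverage
#'   thresholds for the rDNA exclusion alignment.
#' @return A list of class `rop_qc_config`.
#' @export
qc_config <- function(quality_threshold = 30,
                      low_quality_fraction = 0.75,
                      complexity_entropy_min = 1.0,
                      max_homopolymer_fraction = 0.6,
                      rdna_min_identity = 0.9,
                      rdna_min_aligned_fraction = 0.8) {
  stopifnot(low_quality_fraction > 0, low_quality_fraction <= 1,
            quality_threshold >= 0, max_homopolymer_fraction > 0,
            max_homopolymer_fraction <= 1)
  structure(list(
    quality_threshold = quality_threshold,
    low_quality_fraction = low_quality_fraction,
    complexity_entropy_min = complexity_entropy_min,
    max_homopolymer_fraction = max_homopolymer_fraction,
    rdna_min_identity = rdna_min_identity,
    rdna_min_aligned_fraction = rdna_min_aligned_fraction
  ), class = "rop_qc_config")
}

#' Low-quality read test
#'
#' A read is low quality when at least `low_quality_fraction` of its bases
#' have Phred score below `quality_threshold` (default: quality < 30 in at
#' least 75% of base pairs, inclusive).
#'
#' @param reads Read tibble (or a single quality string).
#' @param config QC configuration.
#' @return Logical vector, one per read.
#' @export
is_low_quality <- function(reads, config = qc_config()) {
  quals <- if (is.character(reads)) reads else reads$quality
  vapply(quals, function(q) {
    s <- phred_to_int(q)
    sum(s < config$quality_threshold) >=
      config$low_quality_fraction * length(s)
  }, logical(1), USE.NAMES = FALSE)
}

dinucleotide_entropy <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(0)
  codes <- utf8ToInt(seq)
  pairs <- codes[-n] * 256L + codes[-1]
  p <- tabulate(match(pairs, unique(pairs)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

longest_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

#' Low-complexity read test
#'
#' A read is low complexity when its overlapping-dinucleotide Shannon
#' entropy falls below `complexity_entropy_min` bits or its longest
#' homopolymer run reaches `max_homopolymer_fraction` of its length —
#' a deterministic reading of "consecutive repetitive nucleotides".
#'
#' @param reads Read tibble (or a character vector of sequences).
#' @param config QC configuration.
#' @return Logical vector, one per read.
#' @export
is_low_complexity <- function(reads, config = qc_config()) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  vapply(seqs, function(s) {
    dinucleotide_entropy(s) < config$complexity_entropy_min ||
      longest_homopolymer(s) >= config$max_homopolymer_fraction * nchar(s)
  }, logical(1), USE.NAMES = FALSE)
}

#' rDNA exclusion filter
#'
#' Partitions reads into those matching the rDNA repeating unit (identity
#' at least `rdna_min_identity` over at least `rdna_min_aligned_fraction`
#' of the read) and the rest.
#'
#' @param reads Read tibble.
#' @param rdna_index `rop_index` built over the rDNA unit only.
#' @param config QC configuration.
#' @param aligner Aligner configuration.
#' @return List with `rdna` and `passed` read tibbles (exact disjoint
#'   partition of the input).
#' @export
filter_rdna <- function(reads, rdna_index, config = qc_config(),
                        aligner = aligner_config()) {
  if (nrow(reads) == 0) return(list(rdna = reads, passed = reads))
  budget <- floor((1 - config$rdna_min_identity) * max(nchar(reads$sequence)))
  hits <- align_reads(reads, rdna_index, budget, aligner)
  ok <- hits[hits$edit_distance <=
               (1 - config$rdna_min_identity) * hits$read_length, ]
  is_rdna <- reads$read_id %in% ok$read_id
  list(rdna = reads[is_rdna, ], passed = reads[!is_rdna, ])
}

#' Run the full QC step
#'
#' Evaluation order is low-quality, then low-complexity, then rDNA; the
#' first matching rule wins, so the output is an exact partition.
#'
#' @param reads Read tibble.
#' @param rdna_index `rop_index` over the rDNA unit (or `NULL` to skip the
#'   rDNA filter).
#' @param config QC configuration.
#' @param aligner Aligner configuration.
#' @return List of read tibbles: `low_quality`, `low_complexity`, `rdna`,
#'   `passed`.
#' @export
run_qc <- function(reads, rdna_index = NULL, config = qc_config(),
                   aligner = aligner_config()) {
  lq <- is_low_quality(reads, config)
  rest <- reads[!lq, ]
  lc <- is_low_complexity(rest, config)
  rest2 <- rest[!lc, ]
  if (!is.null(rdna_index)) {
    part <- filter_rdna(rest2, rdna_index, config, aligner)
  } else {
    part <- list(rdna = rest2[0, ], passed = rest2)
  }
  list(low_quality = reads[lq, ], low_complexity = rest[lc, ],
       rdna = part$rdna, passed = part$passed)
}
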