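#' Aligner configuration
#'
#' Parameters of the internal seed-and-extend aligner.  Two edit-distance
#' budgets mirror the two-tier design of the protocol: a strict primary
#' budget (2 edits, the conventional spliced-aligner tolerance) for initial
#' host mapping, and a sensitive budget of 10% of the read length for the
#' lost-human remap and later steps.
#'
#' @param k Seed k-mer length.
#' @param max_edit_distance_primary Primary mapping budget.
#' @param sensitive_fraction Sensitive budget as a fraction of read length
#'   (budget = `ceiling(sensitive_fraction * read_length)`).
#' @param min_aligned_fraction Minimum aligned fraction of the read
#'   (alignments here are full-read anchored, so returned hits always
#'   satisfy it; soft clipping appears only in split alignments).
#' @param min_segment_length Minimum split-alignment segment length.
#' @param max_segment_overlap Maximum overlap of the two split segments on
#'   the read.
#' @param max_hits Number of equally good loci beyond which a read is
#'   treated as multi-mapped ambiguous.
#' @param max_per_kmer Seed positions per k-mer beyond which the seed is
#'   skipped (repetitive-seed guard; never binds at desk scale).
#' @param max_candidates Cap on candidate anchor offsets examined per read.
#' @return A list of class `rop_aligner_config`.
#' @export
aligner_config <- function(k = 16, max_edit_distance_primary = 2,
                           sensitive_fraction = 0.1,
                           min_aligned_fraction = 0.8,
                           min_segment_length = 20,
                           max_segment_overlap = 5,
                           max_hits = 10,
                           max_per_kmer = 512,
                           max_candidates = 50000) {
  stopifnot(k >= 8, max_edit_distance_primary >= 0,
            min_aligned_fraction > 0, min_aligned_fraction <= 1)
  structure(list(
    k = as.integer(k),
    max_edit_distance_primary = as.integer(max_edit_distance_primary),
    sensitive_fraction = sensitive_fraction,
    min_aligned_fraction = min_aligned_fraction,
    min_segment_length = as.integer(min_segment_length),
    max_segment_overlap = as.integer(max_segment_overlap),
    max_hits = as.integer(max_hits),
    max_per_kmer = as.integer(max_per_kmer),
    max_candidates = as.integer(max_candidates)
  ), class = "rop_aligner_config")
}

#' Sensitive edit-distance budget for a read length
#' @param config Aligner configuration.
#' @param read_length Read length in bases.
#' @return Integer budget `ceiling(fraction * read_length)`.
#' @export
sensitive_budget <- function(config, read_length) {
  as.integer(ceiling(config$sensitive_fraction * read_length))
}

#' Build an exact k-mer index over reference sequences
#'
#' @param sequences Named character vector of reference sequences.
#' @param k Seed length.
#' @return An index handle of class `rop_index`.
#' @export
build_index <- function(sequences, k = 16) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  ptr <- .cpp_build_index(names(sequences), unname(toupper(sequences)),
                          as.integer(k))
  structure(list(ptr = ptr, names = names(sequences), k = as.integer(k),
                 lengths = nchar(sequences)),
            class = "rop_index")
}

#' @export
print.rop_index <- function(x, ...) {
  cat("<rop_index> k =", x$k, ",", length(x$names), "sequences,",
      sum(x$lengths), "bp\n")
  invisible(x)
}

#' Count query k-mers shared with an index
#'
#' Used for k-mer rejection when generating separable reference
#' compartments; checks the given orientation only (call again on
#' [revcomp()] for both strands).
#'
#' @param index An `rop_index`.
#' @param seq Query sequence.
#' @return Integer count of query k-mer start positions present in the
#'   index.
#' @export
shared_kmer_count <- function(index, seq) {
  length(.cpp_kmer_hit_positions(index$ptr, toupper(seq)))
}

empty_alignments <- function() {
  tibble::tibble(read_id = character(), ref_id = character(),
                 strand = character(), ref_start = integer(),
                 ref_end = integer(), edit_distance = integer(),
                 cigar = character(), score = numeric(),
                 read_length = integer())
}

#' Align reads against an index
#'
#' Read-anchored semi-global alignment: every returned hit consumes the
#' whole read (aligned fraction 1) starting at `ref_start`, with edit
#' distance (mismatches + gap columns) at most `budget`.  All anchored
#' offsets within the budget are reported, ordered by edit distance, then
#' reference name, start, and strand — a fully deterministic ranking.
#'
#' @param reads Read tibble (or character vector of sequences).
#' @param index An `rop_index`.
#' @param budget Maximum edit distance.
#' @param config Aligner configuration.
#' @param strand `"both"` or `"plus"` (query orientation as given).
#' @return Alignment tibble with one row per hit, best first within each
#'   read; `score = read_length - 2 * edit_distance`.
#' @export
align_reads <- function(reads, index, budget, config = aligner_config(),
                        strand = c("both", "plus")) {
  strand <- match.arg(strand)
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = if (is.null(names(reads))) {
        paste0("q", seq_along(reads))
      } else names(reads),
      sequence = unname(reads)
    )
  }
  if (nrow(reads) == 0) return(empty_alignments())
  hits <- .cpp_align(index$ptr, reads$sequence, as.integer(budget), strand,
                     config$max_per_kmer, config$max_candidates)
  out <- tibble::tibble(
    read_id = reads$read_id[hits$query],
    ref_id = index$names[hits$ref],
    strand = hits$strand,
    ref_start = hits$ref_start,
    ref_end = hits$ref_end,
    edit_distance = hits$edit_distance,
    cigar = hits$cigar,
    read_length = nchar(reads$sequence)[hits$query]
  )
  out$score <- out$read_length - 2 * out$edit_distance
  dplyr::arrange(out, match(.data$read_id, reads$read_id),
                 .data$edit_distance, .data$ref_id, .data$ref_start,
                 .data$strand)
}

#' Split (two-segment) alignment of reads that fail contiguous alignment
#'
#' Finds the best pair of segments such that the first covers a read prefix
#' and the second the remaining suffix (each at least
#' `config$min_segment_length`, overlapping by at most
#' `config$max_segment_overlap` bases on the read), minimising combined
#' edit distance within `budget`; the leftmost breakpoint wins ties.
#' Segments are reported in read order with reference coordinates on the
#' forward strand.
#'
#' @inheritParams align_reads
#' @return Tibble with two rows (`segment` 1 and 2) per solved read:
#'   `ref_id`, `strand`, `ref_start`, `ref_end`, `read_start`, `read_end`
#'   (0-based half-open on the original read), `total_edit_distance`.
#'   Unsolved reads are absent.
#' @export
split_align_reads <- function(reads, index, budget,
                              config = aligner_config(),
                              strand = c("both", "plus")) {
  strand <- match.arg(strand)
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = paste0("q", seq_along(reads)),
                            sequence = unname(reads))
  }
  if (nrow(reads) == 0) {
    return(tibble::tibble(read_id = character(), segment = integer(),
                          ref_id = character(), strand = character(),
                          ref_start = integer(), ref_end = integer(),
                          read_start = integer(), read_end = integer(),
                          total_edit_distance = integer()))
  }
  hits <- .cpp_split_align(index$ptr, reads$sequence, as.integer(budget),
                           config$min_segment_length,
                           config$max_segment_overlap, strand,
                           config$max_per_kmer, config$max_candidates)
  tibble::tibble(
    read_id = reads$read_id[hits$query],
    segment = hits$segment,
    ref_id = index$names[hits$ref],
    strand = hits$strand,
    ref_start = hits$ref_start,
    ref_end = hits$ref_end,
    read_start = hits$read_start,
    read_end = hits$read_end,
    total_edit_distance = hits$total_edit_distance
  )
}

#' Enumerate mismatch positions of a gap-free alignment
#'
#' @param read_seq Read sequence as aligned (already reverse-complemented
#'   for minus-strand hits).
#' @param ref_window Reference substring of equal length.
#' @return Tibble with `read_pos` (1-based), `ref_base`, `read_base`.
#' @export
alignment_mismatches <- function(read_seq, ref_window) {
  stopifnot(nchar(read_seq) == nchar(ref_window))
  a <- utf8ToInt(read_seq)
  b <- utf8ToInt(ref_window)
  pos <- which(a != b)
  tibble::tibble(read_pos = pos,
                 ref_base = strsplit(ref_window, "")[[1]][pos],
                 read_base = strsplit(read_seq, "")[[1]][pos])
}
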