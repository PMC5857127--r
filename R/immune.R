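#' V(D)J detection configuration (step 6)
#'
#' The stringent E-value threshold of alignment-tool-based repertoire
#' detection is replaced by an explicit overlap/mismatch rule: the read
#' must span a V 3' end and a J 5' start of the same locus.
#'
#' @param min_segment_overlap Minimum bases aligned to each of V and J.
#' @param max_mismatch_rate Maximum per-segment mismatch rate (tolerates
#'   somatic hypermutation).
#' @param max_junction_insert Maximum unaligned bases between the V and J
#'   portions of the read (absorbs the D segment and junctional
#'   insertions).
#' @param loci Loci to scan (`NULL` = all loci present in the libraries).
#' @return A list of class `rop_vj_config`.
#' @export
vj_config <- function(min_segment_overlap = 20, max_mismatch_rate = 0.1,
                      max_junction_insert = 40, loci = NULL) {
  stopifnot(min_segment_overlap >= 1, max_mismatch_rate >= 0,
            max_mismatch_rate <= 1)
  structure(list(
    min_segment_overlap = as.integer(min_segment_overlap),
    max_mismatch_rate = max_mismatch_rate,
    max_junction_insert = as.integer(max_junction_insert),
    loci = loci
  ), class = "rop_vj_config")
}

#' Detect reads spanning V(D)J recombination junctions
#'
#' A read is a V(D)J junction read when a prefix aligns (ungapped) to the
#' 3' end of a V segment and the remaining suffix to the 5' start of a J
#' segment of the same locus, each with at least
#' `config$min_segment_overlap` bases and at most
#' `config$max_mismatch_rate` mismatches, separated on the read by at most
#' `config$max_junction_insert` bases.  Both read orientations are
#' scanned; the best (V, J) pair by combined matches wins, ties broken by
#' segment order.
#'
#' @param reads Read tibble.
#' @param v_segments,j_segments Segment tibbles (`name`, `locus`,
#'   `sequence`).
#' @param config V(D)J detection configuration.
#' @return Event tibble: `read_id`, `locus`, `v_gene`, `j_gene`,
#'   `v_overlap`, `j_overlap`, `v_mismatch`, `j_mismatch`,
#'   `insert_length`, `orientation`.  Reads without a qualifying junction
#'   are absent.
#' @export
detect_vj <- function(reads, v_segments, j_segments, config = vj_config()) {
  empty <- tibble::tibble(read_id = character(), locus = character(),
                          v_gene = character(), j_gene = character(),
                          v_overlap = integer(), j_overlap = integer(),
                          v_mismatch = integer(), j_mismatch = integer(),
                          insert_length = integer(),
                          orientation = character())
  if (nrow(reads) == 0) return(empty)
  if (nrow(v_segments) == 0 || nrow(j_segments) == 0) {
    stop("empty V or J segment library")
  }
  if (!is.null(config$loci)) {
    v_segments <- v_segments[v_segments$locus %in% config$loci, ]
    j_segments <- j_segments[j_segments$locus %in% config$loci, ]
  }
  loci <- sort(unique(c(v_segments$locus, j_segments$locus)))
  v_lid <- match(v_segments$locus, loci)
  j_lid <- match(j_segments$locus, loci)
  scan <- function(seqs) {
    .cpp_vj_scan(seqs, v_segments$sequence, v_lid, j_segments$sequence,
                 j_lid, config$min_segment_overlap, config$max_mismatch_rate,
                 config$max_junction_insert)
  }
  fwd <- scan(reads$sequence)
  rev <- scan(revcomp(reads$sequence))
  fwd$orientation <- rep("+", nrow(fwd))
  rev$orientation <- rep("-", nrow(rev))
  hits <- dplyr::bind_rows(fwd, rev)
  if (!nrow(hits)) return(empty)
  hits <- hits |>
    dplyr::arrange(.data$query, dplyr::desc(.data$matches),
                   .data$orientation) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)
  tibble::tibble(
    read_id = reads$read_id[hits$query],
    locus = v_segments$locus[hits$v],
    v_gene = v_segments$name[hits$v],
    j_gene = j_segments$name[hits$j],
    v_overlap = hits$v_overlap, j_overlap = hits$j_overlap,
    v_mismatch = hits$v_mismatch, j_mismatch = hits$j_mismatch,
    insert_length = hits$insert_length,
    orientation = hits$orientation)
}

#' Per-locus VJ combination matrices and cross-sample support
#'
#' @param events Event tibble from [detect_vj()], optionally with a
#'   `sample_id` column (single sample assumed otherwise).
#' @return List with `counts` (per sample, locus, V, J), and
#'   `sample_support` (per locus, V, J: fraction of samples with at least
#'   one event).
#' @export
vj_matrix <- function(events) {
  if (!"sample_id" %in% names(events)) {
    events$sample_id <- rep("sample1", nrow(events))
  }
  if (!nrow(events)) {
    return(list(counts = tibble::tibble(sample_id = character(),
                                        locus = character(),
                                        v_gene = character(),
                                        j_gene = character(),
                                        count = integer()),
                sample_support = tibble::tibble(locus = character(),
                                                v_gene = character(),
                                                j_gene = character(),
                                                support = numeric())))
  }
  counts <- events |>
    dplyr::count(.data$sample_id, .data$locus, .data$v_gene, .data$j_gene,
                 name = "count")
  n_samples <- dplyr::n_distinct(events$sample_id)
  support <- counts |>
    dplyr::group_by(.data$locus, .data$v_gene, .data$j_gene) |>
    dplyr::summarise(support = dplyr::n_distinct(.data$sample_id) / n_samples,
                     .groups = "drop")
  list(counts = counts, sample_support = support)
}
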