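#' Hyper-editing detection configuration (step 3)
#'
#' @param min_fraction Substitution-type mismatches must exceed this
#'   fraction of the read length (strict `>`; default 0.05, i.e. "exceeds
#'   5% of its length").
#' @param min_substitution_share Substitution-type mismatches must make up
#'   at least this share of all mismatches in the recovered alignment.
#' @param cluster_window All substitution-type mismatches must fall within
#'   a window of this fraction of the read length (the dense-cluster
#'   rule).
#' @param max_other_mismatches Maximum non-substitution mismatches
#'   tolerated (defaults to the primary alignment budget).
#' @return A list of class `rop_hyper_config`.
#' @export
hyper_config <- function(min_fraction = 0.05,
                         min_substitution_share = 0.6,
                         cluster_window = 0.9,
                         max_other_mismatches = 2) {
  structure(list(
    min_fraction = min_fraction,
    min_substitution_share = min_substitution_share,
    cluster_window = cluster_window,
    max_other_mismatches = as.integer(max_other_mismatches)
  ), class = "rop_hyper_config")
}

#' Apply a single-base transformation to sequences
#'
#' Replaces every `from` base by `to`, leaving other bases unchanged; an
#' idempotent, length-preserving map (e.g. all A into G for the A-to-I
#' editing search).
#'
#' @param sequences Character vector of DNA sequences.
#' @param from,to Single bases, `from != to`.
#' @return Transformed character vector.
#' @export
transform_bases <- function(sequences, from = "A", to = "G") {
  stopifnot(from %in% DNA_BASES, to %in% DNA_BASES, from != to)
  chartr(from, to, sequences)
}

all_substitutions <- function() {
  g <- expand.grid(from = DNA_BASES, to = DNA_BASES,
                   stringsAsFactors = FALSE)
  g[g$from != g$to, ]
}

#' Detect hyper-edited reads by transformed realignment
#'
#' Both the reads and the reference genome are transformed (`from` to
#' `to`), transformed reads are realigned at the primary budget, original
#' sequences are recovered at each hit, and a read is reported when its
#' recovered mismatches form a dense cluster of the substitution type:
#' more than `min_fraction` of the read length are `from`-to-`to`
#' mismatches, they are at least `min_substitution_share` of all
#' mismatches, they fit inside the cluster window, and other mismatches
#' stay within the primary budget.  Reads sampled from the opposite strand
#' carry the complementary substitution, so each read is also tested in
#' reverse-complement orientation against the same transformed genome.
#'
#' @param reads Read tibble.
#' @param genome Named character vector of reference sequences.
#' @param from,to The directed substitution searched (default A to G).
#' @param config Hyper-editing configuration.
#' @param aligner Aligner configuration.
#' @param genome_index Optional pre-built index of the transformed genome
#'   (as built internally; supplied by the control-table loop).
#' @return Tibble of hits: `read_id`, `ref_id`, `ref_start`, `strand`,
#'   `n_sub`, `n_other`, `mismatch_fraction`, `cluster_span`,
#'   `positions` (comma-joined read coordinates, 1-based),
#'   `contexts` (ref bases around each edited site).
#' @export
detect_hyper_editing <- function(reads, genome, from = "A", to = "G",
                                 config = hyper_config(),
                                 aligner = aligner_config(),
                                 genome_index = NULL) {
  empty <- tibble::tibble(read_id = character(), ref_id = character(),
                          ref_start = integer(), strand = character(),
                          n_sub = integer(), n_other = integer(),
                          mismatch_fraction = numeric(),
                          cluster_span = integer(), positions = character(),
                          contexts = character())
  if (nrow(reads) == 0) return(empty)
  tgenome <- transform_bases(genome, from, to)
  idx <- genome_index %||% build_index(tgenome, aligner$k)
  budget <- aligner$max_edit_distance_primary

  rows <- list()
  for (orient in c("+", "-")) {
    qseq <- if (orient == "+") reads$sequence else revcomp(reads$sequence)
    q <- tibble::tibble(read_id = reads$read_id,
                        sequence = transform_bases(qseq, from, to))
    hits <- align_reads(q, idx, budget, aligner, strand = "plus")
    if (!nrow(hits)) next
    best <- hits |> dplyr::distinct(.data$read_id, .keep_all = TRUE)
    # gap-free recovery only: reference span must equal the read length
    best <- best[best$ref_end - best$ref_start == best$read_length, ]
    if (!nrow(best)) next
    ord <- match(best$read_id, reads$read_id)
    for (i in seq_len(nrow(best))) {
      ri <- ord[i]
      orig <- if (orient == "+") reads$sequence[ri] else
        revcomp(reads$sequence[ri])
      len <- nchar(orig)
      win <- substring(genome[[best$ref_id[i]]], best$ref_start[i] + 1,
                       best$ref_end[i])
      mm <- alignment_mismatches(orig, win)
      is_sub <- mm$ref_base == from & mm$read_base == to
      n_sub <- sum(is_sub)
      n_other <- sum(!is_sub)
      if (n_sub == 0) next
      span <- diff(range(mm$read_pos[is_sub])) + 1L
      if (n_sub <= config$min_fraction * len) next
      if (n_sub < config$min_substitution_share * (n_sub + n_other)) next
      if (span > config$cluster_window * len) next
      if (n_other > config$max_other_mismatches) next
      pos_aligned <- mm$read_pos[is_sub]
      pos_read <- if (orient == "+") pos_aligned else
        sort(len + 1L - pos_aligned)
      ref_pos <- best$ref_start[i] + pos_aligned  # 1-based genome coords
      ctx <- substring(rep(genome[[best$ref_id[i]]], length(ref_pos)),
                       ref_pos - 1, ref_pos + 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = best$read_id[i], ref_id = best$ref_id[i],
        ref_start = best$ref_start[i], strand = orient,
        n_sub = n_sub, n_other = n_other,
        mismatch_fraction = n_sub / len,
        cluster_span = span,
        positions = paste(pos_read, collapse = ","),
        contexts = paste(ctx, collapse = ","))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty)
  # a read detected in both orientations keeps the denser call (then '+')
  out |>
    dplyr::arrange(match(.data$read_id, reads$read_id),
                   dplyr::desc(.data$n_sub), .data$strand) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
}

#' All-substitution control profile
#'
#' Runs the hyper-editing detector for each of the 12 directed
#' substitution types and tabulates hits: a read may be reported under
#' several types (the per-type table), and is uniquely assigned to the
#' type with the highest mismatch fraction (ties excluded) in the
#' unique-assignment table.  A 6-type table collapses complementary
#' directions, as the editing literature usually reports.
#'
#' @inheritParams detect_hyper_editing
#' @return List with `directed` (12-row tibble: from, to, hits, fraction),
#'   `collapsed` (6 unordered base pairs), `unique_assignment` (per-type
#'   counts of uniquely assigned reads and their fraction of all uniquely
#'   assigned reads), and `hits` (all per-read hits with their type).
#' @export
hyper_editing_controls <- function(reads, genome, config = hyper_config(),
                                   aligner = aligner_config()) {
  subs <- all_substitutions()
  all_hits <- list()
  for (i in seq_len(nrow(subs))) {
    h <- detect_hyper_editing(reads, genome, subs$from[i], subs$to[i],
                              config, aligner)
    if (nrow(h)) {
      h$from <- subs$from[i]
      h$to <- subs$to[i]
      all_hits[[i]] <- h
    }
  }
  hits <- dplyr::bind_rows(all_hits)
  directed <- subs |>
    tibble::as_tibble() |>
    dplyr::mutate(type = paste0(.data$from, ">", .data$to))
  if (nrow(hits)) {
    cnt <- hits |> dplyr::count(.data$from, .data$to, name = "hits")
    directed <- dplyr::left_join(directed, cnt, by = c("from", "to"))
  } else {
    directed$hits <- NA_integer_
  }
  directed$hits[is.na(directed$hits)] <- 0L
  directed$fraction <- if (sum(directed$hits) > 0) {
    directed$hits / sum(directed$hits)
  } else 0
  collapsed <- directed |>
    dplyr::mutate(pair = purrr::map2_chr(.data$from, .data$to, function(a, b)
      paste(sort(c(a, b)), collapse = ":"))) |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(hits = sum(.data$hits), .groups = "drop") |>
    dplyr::mutate(fraction = if (sum(.data$hits) > 0)
      .data$hits / sum(.data$hits) else 0)
  if (nrow(hits)) {
    uniq <- hits |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(.data$mismatch_fraction == max(.data$mismatch_fraction)) |>
      dplyr::filter(dplyr::n() == 1) |>
      dplyr::ungroup() |>
      dplyr::count(.data$from, .data$to, name = "unique_hits")
    total_u <- sum(uniq$unique_hits)
    uniq$fraction <- if (total_u > 0) uniq$unique_hits / total_u else 0
  } else {
    uniq <- tibble::tibble(from = character(), to = character(),
                           unique_hits = integer(), fraction = numeric())
  }
  list(directed = directed[, c("type", "from", "to", "hits", "fraction")],
       collapsed = collapsed, unique_assignment = uniq, hits = hits)
}
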