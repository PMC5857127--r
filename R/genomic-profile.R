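# Mapped-read profiling.  Alignments arrive as genomic block tables: one
# row per aligned block (transcript-space hits are mapped back to genomic
# blocks, so junction reads carry two or more blocks), with columns
# read_id, aln_id, chrom, start, end, block, n_blocks, edit_distance,
# read_length.

GENOMIC_PRIORITY <- c("CDS", "UTR5", "UTR3", "intron")

overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  hit <- logical(length(q_chrom))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi] + 1, q_end[qi]),
      IRanges::IRanges(s_start[si] + 1, s_end[si]))
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Categorize mapped reads into genomic categories
#'
#' Decision order per read: multi-mapped (more than one distinct locus at
#' the best edit distance), mitochondrial, junction (alignment crosses an
#' exon-exon boundary, i.e. more than one genomic block), then the highest
#' priority overlapped feature (CDS > UTR5 > UTR3 > intron; one shared base
#' suffices), then intergenic within `deep_distance` of a gene, else deep
#' intergenic.
#'
#' @param blocks Genomic block table (see package internals); one or more
#'   alignments per read.
#' @param annotation Feature tibble from [read_gtf()]/[build_references()].
#' @param deep_distance Distance from the nearest gene beyond which an
#'   intergenic read is "deep" (bases).
#' @return Tibble with `read_id`, `category`, `n_loci`.
#' @export
categorize_mapped <- function(blocks, annotation, deep_distance = 10000) {
  if (nrow(blocks) == 0) {
    return(tibble::tibble(read_id = character(), category = character(),
                          n_loci = integer()))
  }
  stopifnot(all(c("read_id", "aln_id", "chrom", "start", "end", "block",
                  "n_blocks", "edit_distance") %in% names(blocks)))
  mito <- unique(annotation$chrom[annotation$kind == "mitochondrial_contig"])
  genes <- annotation[annotation$kind == "gene", ]
  feats <- annotation[annotation$kind %in% GENOMIC_PRIORITY, ]

  # best alignments per read, then distinct-locus count (loci separated
  # when on different chromosomes or with disjoint spans)
  spans <- blocks |>
    dplyr::group_by(.data$read_id, .data$aln_id) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end),
                     edit_distance = .data$edit_distance[1],
                     n_blocks = .data$n_blocks[1], .groups = "drop") |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$edit_distance == min(.data$edit_distance)) |>
    dplyr::ungroup()

  # distinct-locus count: connected components of overlapping spans,
  # computed with a cheap sweep (most reads have one or two spans)
  spans <- dplyr::arrange(spans, .data$read_id, .data$chrom, .data$start)
  grp <- split(seq_len(nrow(spans)), spans$read_id)
  n_loci <- tibble::tibble(
    read_id = names(grp),
    n_loci = vapply(grp, function(idx) {
      if (length(idx) == 1) return(1L)
      ch <- spans$chrom[idx]; st <- spans$start[idx]; en <- spans$end[idx]
      k <- 0L
      for (c2 in unique(ch)) {
        s <- st[ch == c2]; e <- en[ch == c2]  # already start-sorted
        hi <- cummax(e)
        k <- k + 1L + sum(s[-1] > hi[-length(hi)])
      }
      k
    }, integer(1), USE.NAMES = FALSE))

  # representative (deterministically first) alignment per read
  rep_aln <- spans |>
    dplyr::arrange(.data$read_id, .data$edit_distance, .data$chrom,
                   .data$start) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE) |>
    dplyr::left_join(n_loci, by = "read_id")

  cat_out <- character(nrow(rep_aln))
  cat_out[rep_aln$n_loci > 1] <- "multi_mapped"
  todo <- which(cat_out == "")
  is_mito <- rep_aln$chrom %in% mito
  cat_out[todo[is_mito[todo]]] <- "mitochondrial"
  todo <- which(cat_out == "")
  cat_out[todo[rep_aln$n_blocks[todo] > 1]] <- "junction"
  todo <- which(cat_out == "")
  if (length(todo)) {
    for (kind in GENOMIC_PRIORITY) {
      f <- feats[feats$kind == kind, ]
      if (!nrow(f) || !length(todo)) next
      hit <- overlaps_any(rep_aln$chrom[todo], rep_aln$start[todo],
                          rep_aln$end[todo], f$chrom, f$start, f$end)
      cat_out[todo[hit]] <- kind
      todo <- which(cat_out == "")
    }
  }
  if (length(todo)) {
    near <- overlaps_any(rep_aln$chrom[todo],
                         pmax(rep_aln$start[todo] - deep_distance, 0),
                         rep_aln$end[todo] + deep_distance,
                         genes$chrom, genes$start, genes$end)
    cat_out[todo] <- ifelse(near, "intergenic", "deep_intergenic")
  }
  tibble::tibble(read_id = rep_aln$read_id, category = cat_out,
                 n_loci = rep_aln$n_loci)
}

#' Repeat-element profile of mapped reads
#'
#' A read counts toward a repeat element when its alignment overlaps the
#' repeat interval by at least `min_overlap_fraction` of the read; among
#' several qualifying repeats the largest overlap wins (ties broken by
#' name).  Relative abundance of a class is its count over all repeat
#' counts.
#'
#' @param blocks Genomic block table of the reads' best alignments.
#' @param repeat_annotation Repeat interval tibble (`chrom`, `start`,
#'   `end`, `name`, `class`, `family`).
#' @param min_overlap_fraction Minimum overlap as a fraction of the read.
#' @return List with `assignments` (read_id, name, class, family,
#'   overlap), `counts` (per element) and `class_abundance` (percent per
#'   class).
#' @export
repeat_profile <- function(blocks, repeat_annotation,
                           min_overlap_fraction = 0.5) {
  empty <- list(
    assignments = tibble::tibble(read_id = character(), name = character(),
                                 class = character(), family = character(),
                                 overlap = integer()),
    counts = tibble::tibble(class = character(), family = character(),
                            name = character(), count = integer()),
    class_abundance = tibble::tibble(class = character(),
                                     relative_abundance = numeric()))
  if (nrow(blocks) == 0 || nrow(repeat_annotation) == 0) return(empty)
  res <- list()
  for (ch in intersect(unique(blocks$chrom), unique(repeat_annotation$chrom))) {
    b <- blocks[blocks$chrom == ch, ]
    r <- repeat_annotation[repeat_annotation$chrom == ch, ]
    ov <- IRanges::findOverlaps(IRanges::IRanges(b$start + 1, b$end),
                                IRanges::IRanges(r$start + 1, r$end))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    res[[ch]] <- tibble::tibble(
      read_id = b$read_id[qh],
      read_length = b$read_length[qh],
      name = r$name[sh], class = r$class[sh], family = r$family[sh],
      overlap = pmin(b$end[qh], r$end[sh]) - pmax(b$start[qh], r$start[sh])
    )
  }
  hits <- dplyr::bind_rows(res)
  if (!nrow(hits)) return(empty)
  assignments <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$name,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$overlap >= min_overlap_fraction * .data$read_length) |>
    dplyr::select("read_id", "name", "class", "family", "overlap")
  counts <- assignments |>
    dplyr::count(.data$class, .data$family, .data$name, name = "count")
  class_ab <- counts |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(relative_abundance = 100 * .data$count / sum(.data$count))
  list(assignments = assignments, counts = counts,
       class_abundance = class_ab)
}

#' Count reads overlapping immune-receptor gene segments
#'
#' Conservative union counting: a read counts for a V/D/J/C segment only
#' when it overlaps that segment and no other; reads touching two segments
#' are dropped as ambiguous.
#'
#' @param blocks Genomic block table of the reads' best alignments.
#' @param immune_loci Segment interval tibble (`chrom`, `start`, `end`,
#'   `segment_type`, `name`, `locus`).
#' @return Tibble of counts per segment (`locus`, `segment_type`, `name`,
#'   `count`).
#' @export
count_immune_locus_overlap <- function(blocks, immune_loci) {
  immune_locus_reads(blocks, immune_loci) |>
    dplyr::count(.data$locus, .data$segment_type, .data$name,
                 name = "count")
}

# per-read unique segment assignment behind count_immune_locus_overlap;
# also used by the pipeline to label mapped_immune_locus reads
immune_locus_reads <- function(blocks, immune_loci) {
  empty <- tibble::tibble(read_id = character(), name = character(),
                          locus = character(), segment_type = character())
  if (nrow(blocks) == 0 || nrow(immune_loci) == 0) return(empty)
  res <- list()
  for (ch in intersect(unique(blocks$chrom), unique(immune_loci$chrom))) {
    b <- blocks[blocks$chrom == ch, ]
    s <- immune_loci[immune_loci$chrom == ch, ]
    ov <- IRanges::findOverlaps(IRanges::IRanges(b$start + 1, b$end),
                                IRanges::IRanges(s$start + 1, s$end))
    if (!length(ov)) next
    res[[ch]] <- tibble::tibble(
      read_id = b$read_id[S4Vectors::queryHits(ov)],
      name = s$name[S4Vectors::subjectHits(ov)],
      locus = s$locus[S4Vectors::subjectHits(ov)],
      segment_type = s$segment_type[S4Vectors::subjectHits(ov)])
  }
  hits <- dplyr::bind_rows(res)
  if (!nrow(hits)) return(empty)
  hits |>
    dplyr::distinct() |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
}
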