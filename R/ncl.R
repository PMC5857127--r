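#' Non-co-linear read classification configuration (step 5)
#'
#' @param trans_min_gap Genomic gap beyond which a co-linear same-chromosome
#'   junction is trans-splicing regardless of gene context (bases).
#' @param circ_max_span Maximum genomic span of a head-to-tail (circRNA)
#'   junction.
#' @param breakpoint_tolerance Breakpoint distance within which reads are
#'   grouped into one event.
#' @param min_support Events with support strictly greater than this are
#'   reported (default 1: "> 1 read").
#' @return A list of class `rop_ncl_config`.
#' @export
ncl_config <- function(trans_min_gap = 1e6, circ_max_span = 1e5,
                       breakpoint_tolerance = 5, min_support = 1) {
  structure(list(
    trans_min_gap = trans_min_gap, circ_max_span = circ_max_span,
    breakpoint_tolerance = as.integer(breakpoint_tolerance),
    min_support = as.integer(min_support)
  ), class = "rop_ncl_config")
}

#' Classify a split alignment into an NCL subtype
#'
#' Given the two segments of a split read (in read order, reference
#' coordinates on the forward strand), returns one row per read with the
#' subtype: `fusion` when the segments lie on different chromosomes;
#' `circRNA` when, on one chromosome and strand, the second segment's
#' interval ends before the first begins (head-to-tail), both fall within
#' one annotated gene span, and the genomic span is within
#' `circ_max_span`; `trans_splicing` when the order is co-linear but the
#' gap exceeds `trans_min_gap`, or the segments lie in different genes
#' separated by more than the larger gene span; `none` otherwise (ordinary
#' splicing).  Minus-strand split reads are normalised by swapping the
#' segments before applying the head-to-tail rule.
#'
#' @param segments Split-alignment tibble from [split_align_reads()].
#' @param annotation Feature tibble (gene spans are used).
#' @param config NCL configuration.
#' @return Tibble: `read_id`, `subtype`, `chrom_a`, `pos_a`, `strand_a`,
#'   `chrom_b`, `pos_b`, `strand_b`, `gene_a`, `gene_b`.  Breakpoint `a`
#'   is the junction-side end of the read's first segment and `b` the
#'   junction-side start of the second, after strand normalisation.
#' @export
classify_split <- function(segments, annotation, config = ncl_config()) {
  empty <- tibble::tibble(read_id = character(), subtype = character(),
                          chrom_a = character(), pos_a = integer(),
                          strand_a = character(), chrom_b = character(),
                          pos_b = integer(), strand_b = character(),
                          gene_a = character(), gene_b = character())
  if (nrow(segments) == 0) return(empty)
  genes <- annotation[annotation$kind == "gene", ]
  gene_at <- function(chrom, start, end) {
    g <- genes[genes$chrom == chrom & genes$start < end & genes$end > start, ]
    if (nrow(g)) {
      list(id = g$gene_id[1], start = g$start[1], end = g$end[1])
    } else {
      list(id = NA_character_, start = NA_integer_, end = NA_integer_)
    }
  }
  out <- list()
  for (rid in unique(segments$read_id)) {
    s <- segments[segments$read_id == rid, ]
    s <- s[order(s$segment), ]
    if (nrow(s) != 2) next
    # normalise to the transcribed (+) orientation of the junction: a
    # minus-strand read reports the junction segments in reverse order
    if (all(s$strand == "-")) s <- s[2:1, ]
    a <- s[1, ]; b <- s[2, ]
    ga <- gene_at(a$ref_id, a$ref_start, a$ref_end)
    gb <- gene_at(b$ref_id, b$ref_start, b$ref_end)
    subtype <- "none"
    if (a$ref_id != b$ref_id) {
      subtype <- "fusion"
    } else if (b$ref_end <= a$ref_start && a$strand == b$strand) {
      # head-to-tail: downstream sequence precedes upstream on the read
      span <- a$ref_end - b$ref_start
      same_gene <- !is.na(ga$id) && !is.na(gb$id) && ga$id == gb$id
      if (same_gene && span <= config$circ_max_span) subtype <- "circRNA"
    } else if (b$ref_start >= a$ref_end) {
      gap <- b$ref_start - a$ref_end
      spans <- c(if (!is.na(ga$id)) ga$end - ga$start,
                 if (!is.na(gb$id)) gb$end - gb$start)
      diff_gene <- !is.na(ga$id) && !is.na(gb$id) && ga$id != gb$id
      if (gap > config$trans_min_gap ||
          (diff_gene && gap > max(spans))) {
        subtype <- "trans_splicing"
      }
    }
    out[[rid]] <- tibble::tibble(
      read_id = rid, subtype = subtype,
      chrom_a = a$ref_id, pos_a = a$ref_end, strand_a = a$strand,
      chrom_b = b$ref_id, pos_b = b$ref_start, strand_b = b$strand,
      gene_a = ga$id, gene_b = gb$id)
  }
  dplyr::bind_rows(out)
}

#' Aggregate classified NCL reads into events
#'
#' Reads are grouped by subtype and breakpoint pair within
#' `breakpoint_tolerance`; support is the distinct read count.  All events
#' are returned with a `reported` flag for the `support > min_support`
#' filter (strict, reporting-only — the threshold is deliberately liberal
#' and stricter cutoffs belong to downstream use).
#'
#' @param classified Output of [classify_split()] (rows with subtype
#'   `none` are ignored).
#' @param config NCL configuration.
#' @return Event tibble: `subtype`, `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `gene_a`, `gene_b`, `support`, `reported`.
#' @export
aggregate_ncl_events <- function(classified, config = ncl_config()) {
  cl <- classified[classified$subtype != "none", ]
  if (!nrow(cl)) {
    return(tibble::tibble(subtype = character(), chrom_a = character(),
                          pos_a = integer(), chrom_b = character(),
                          pos_b = integer(), gene_a = character(),
                          gene_b = character(), support = integer(),
                          reported = logical()))
  }
  tol <- config$breakpoint_tolerance
  cl <- dplyr::arrange(cl, .data$subtype, .data$chrom_a, .data$chrom_b,
                       .data$pos_a, .data$pos_b)
  key <- character(nrow(cl))
  anchors <- list()
  for (i in seq_len(nrow(cl))) {
    found <- NULL
    grp <- paste(cl$subtype[i], cl$chrom_a[i], cl$chrom_b[i])
    for (k in seq_along(anchors)) {
      an <- anchors[[k]]
      if (an$grp == grp && abs(an$pos_a - cl$pos_a[i]) <= tol &&
          abs(an$pos_b - cl$pos_b[i]) <= tol) {
        found <- k
        break
      }
    }
    if (is.null(found)) {
      anchors[[length(anchors) + 1]] <- list(grp = grp, pos_a = cl$pos_a[i],
                                             pos_b = cl$pos_b[i])
      found <- length(anchors)
    }
    key[i] <- found
  }
  cl$event_key <- key
  cl |>
    dplyr::group_by(.data$event_key) |>
    dplyr::summarise(subtype = .data$subtype[1], chrom_a = .data$chrom_a[1],
                     pos_a = .data$pos_a[1], chrom_b = .data$chrom_b[1],
                     pos_b = .data$pos_b[1], gene_a = .data$gene_a[1],
                     gene_b = .data$gene_b[1],
                     support = dplyr::n_distinct(.data$read_id),
                     .groups = "drop") |>
    dplyr::mutate(reported = .data$support > config$min_support) |>
    dplyr::select(-"event_key") |>
    dplyr::arrange(.data$subtype, .data$chrom_a, .data$pos_a, .data$pos_b)
}
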