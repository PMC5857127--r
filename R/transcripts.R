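# Transcript models: exon structures per transcript, spliced sequences, and
# the mapping between transcript-space and genomic coordinates.  Primary
# mapping aligns against spliced transcripts in addition to the genome, so
# exon-junction reads are recovered; their hits are mapped back to genomic
# blocks here.

#' Transcript models from a feature annotation
#'
#' @param annotation Feature tibble from [read_gtf()] or
#'   [build_references()].
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` (list column of start/end tibbles sorted by
#'   genomic start), `width`.
#' @export
transcript_models <- function(annotation) {
  ex <- annotation[annotation$kind == "exon" & !is.na(annotation$transcript_id), ]
  if (!nrow(ex)) {
    return(tibble::tibble(transcript_id = character(), gene_id = character(),
                          chrom = character(), strand = character(),
                          exons = list(), width = integer()))
  }
  ex |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$start), ]
      tibble::tibble(
        gene_id = d$gene_id[1], chrom = d$chrom[1], strand = d$strand[1],
        exons = list(tibble::tibble(start = d$start, end = d$end)),
        width = sum(d$end - d$start)
      )
    }) |>
    dplyr::ungroup()
}

#' Spliced transcript sequences
#'
#' Exons are concatenated in genomic order; minus-strand transcripts are
#' reverse-complemented so sequences read 5' to 3'.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param models Transcript models from [transcript_models()].
#' @return Named character vector of transcript sequences.
#' @export
transcript_sequences <- function(genome, models) {
  seqs <- vapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    s <- paste(substring(genome[[models$chrom[i]]], ex$start + 1, ex$end),
               collapse = "")
    if (models$strand[i] == "-") revcomp(s) else s
  }, character(1))
  stats::setNames(seqs, models$transcript_id)
}

# genomic blocks covered by transcript-space interval [s, e), 0-based
# half-open in 5'->3' transcript coordinates
tx_to_genomic <- function(model_row, s, e) {
  ex <- model_row$exons[[1]]
  w <- ex$end - ex$start
  if (model_row$strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), ]
    w <- rev(w)
  }
  cum <- cumsum(c(0, w))
  blocks <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(s, cum[i]); hi <- min(e, cum[i + 1])
    if (lo >= hi) next
    if (model_row$strand == "+") {
      blocks[[length(blocks) + 1]] <- c(ex$start[i] + (lo - cum[i]),
                                        ex$start[i] + (hi - cum[i]))
    } else {
      blocks[[length(blocks) + 1]] <- c(ex$end[i] - (hi - cum[i]),
                                        ex$end[i] - (lo - cum[i]))
    }
  }
  m <- do.call(rbind, blocks)
  tibble::tibble(chrom = model_row$chrom, start = m[, 1], end = m[, 2])
}
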