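#' Read gene annotation from GTF
#'
#' Imports a 9-column GTF (1-based inclusive coordinates) and converts it to
#' the internal 0-based half-open convention.  Introns are derived as gaps
#' between consecutive exons of a transcript, and unlabelled `UTR` features
#' are resolved to `UTR5`/`UTR3` from their position relative to the CDS and
#' the transcript strand.
#'
#' @param path Path to a GTF file.
#' @return A feature tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `kind` (one of gene, exon, CDS, UTR5, UTR3,
#'   intron, mitochondrial_contig), `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (any(df$end < df$start - 1)) stop("feature with end < start in ", path)
  feats <- tibble::tibble(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = as.character(df$strand),
    kind = as.character(df$type),
    gene_id = if ("gene_id" %in% names(df)) as.character(df$gene_id) else NA,
    transcript_id = if ("transcript_id" %in% names(df)) {
      as.character(df$transcript_id)
    } else NA
  )
  feats$gene_id[!is.na(feats$gene_id) & feats$gene_id == ""] <- NA
  feats$transcript_id[!is.na(feats$transcript_id) &
                        feats$transcript_id == ""] <- NA
  feats$kind[feats$kind == "five_prime_utr"] <- "UTR5"
  feats$kind[feats$kind == "three_prime_utr"] <- "UTR3"
  annotate_derived_features(feats)
}

# introns from exon gaps; UTR sides from CDS extent per transcript
annotate_derived_features <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$transcript_id), ]
  introns <- list()
  if (nrow(ex)) {
    for (tid in unique(ex$transcript_id)) {
      e <- ex[ex$transcript_id == tid, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1) {
        introns[[tid]] <- tibble::tibble(
          chrom = e$chrom[1], start = e$end[-nrow(e)], end = e$start[-1],
          strand = e$strand[1], kind = "intron",
          gene_id = e$gene_id[1], transcript_id = tid
        )
      }
    }
  }
  utr <- which(feats$kind == "UTR")
  if (length(utr)) {
    cds <- feats[feats$kind == "CDS", ]
    for (i in utr) {
      tid <- feats$transcript_id[i]
      cd <- cds[cds$transcript_id == tid, ]
      if (!nrow(cd)) next
      upstream <- feats$end[i] <= min(cd$start)
      if (feats$strand[i] == "+") {
        feats$kind[i] <- if (upstream) "UTR5" else "UTR3"
      } else {
        feats$kind[i] <- if (upstream) "UTR3" else "UTR5"
      }
    }
  }
  out <- dplyr::bind_rows(feats[feats$kind != "intron", ],
                          dplyr::bind_rows(introns))
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end, .data$kind)
  tibble::as_tibble(out)
}

#' Write gene annotation to GTF
#'
#' The inverse boundary conversion of [read_gtf()]: internal 0-based
#' half-open features are written as 1-based inclusive GTF lines.  Derived
#' features (introns) are dropped, and `UTR5`/`UTR3` are written as `UTR`
#' lines, so `read_gtf(write_gtf(x))` restores `x` on annotations produced
#' by [build_references()].
#'
#' @param feats Feature tibble (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(feats, path) {
  keep <- feats[feats$kind != "intron", ]
  type <- keep$kind
  type[type %in% c("UTR5", "UTR3")] <- "UTR"
  attr_str <- sprintf(
    'gene_id "%s"; transcript_id "%s";',
    ifelse(is.na(keep$gene_id), "", keep$gene_id),
    ifelse(is.na(keep$transcript_id), "", keep$transcript_id)
  )
  lines <- sprintf("%s\treadorigin\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   keep$chrom, type, keep$start + 1L, keep$end,
                   keep$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}
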