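#' Write alignments as plain-text SAM
#'
#' Emits the SAM subset the pipeline uses: header `@SQ` lines plus QNAME,
#' FLAG (strand and unmapped bits only), RNAME, POS, MAPQ, CIGAR, SEQ, QUAL
#' and the `NM:i:` edit-distance tag.  Coordinates convert from the internal
#' 0-based half-open convention to SAM's 1-based.
#'
#' @param alignments Alignment tibble with columns `read_id`, `ref_id`,
#'   `ref_start`, `strand`, `edit_distance`, `cigar`, and optionally
#'   `sequence`, `quality`.
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, ref_lengths) {
  stopifnot(!is.null(names(ref_lengths)))
  unknown <- setdiff(unique(alignments$ref_id), names(ref_lengths))
  if (length(unknown)) stop("unknown reference name: ", unknown[1])
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  seqs <- alignments$sequence %||% rep("*", nrow(alignments))
  qual <- alignments$quality %||% rep("*", nrow(alignments))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  alignments$read_id, flag, alignments$ref_id,
                  alignments$ref_start + 1L, alignments$cigar, seqs, qual,
                  alignments$edit_distance)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read plain-text SAM alignments
#'
#' Parses the subset written by [write_sam()].  Reference names must appear
#' in the `@SQ` header.
#'
#' @param path Path to a SAM file.
#' @return Alignment tibble with 0-based half-open `ref_start`, `strand`,
#'   `cigar`, `edit_distance`, `sequence`, `quality` and soft-clip widths
#'   decoded from the CIGAR.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  refs <- sub(".*SN:([^\t]+).*", "\\1", hdr[startsWith(hdr, "@SQ")])
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) {
    return(tibble::tibble(read_id = character(), ref_id = character(),
                          ref_start = integer(), strand = character(),
                          cigar = character(), edit_distance = integer(),
                          sequence = character(), quality = character(),
                          soft_clip_left = integer(),
                          soft_clip_right = integer()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  rname <- get(3)
  unknown <- setdiff(unique(rname[rname != "*"]), refs)
  if (length(unknown)) stop("unknown reference name in SAM: ", unknown[1])
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  cigar <- get(6)
  clip <- function(side) {
    vapply(cigar, function(cg) {
      m <- if (side == "left") regmatches(cg, regexpr("^[0-9]+S", cg))
           else regmatches(cg, regexpr("[0-9]+S$", cg))
      if (length(m) && nzchar(m)) as.integer(sub("S", "", m)) else 0L
    }, integer(1), USE.NAMES = FALSE)
  }
  tibble::tibble(
    read_id = get(1),
    ref_id = rname,
    ref_start = as.integer(get(4)) - 1L,
    strand = ifelse(bitwAnd(as.integer(get(2)), 16L) > 0, "-", "+"),
    cigar = cigar,
    edit_distance = nm,
    sequence = get(10),
    quality = get(11),
    soft_clip_left = clip("left"),
    soft_clip_right = clip("right")
  )
}
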