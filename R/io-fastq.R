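#' Read a FASTQ file into a read table
#'
#' Reads 4-line FASTQ records with Phred+33 qualities.  Malformed records
#' (truncated blocks, separator missing, quality length differing from the
#' sequence length) raise an error naming the offending line.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality` (Phred+33
#'   string), `mate` and `truth_label`.  Mate is parsed from `/1`, `/2`
#'   read-name suffixes when present.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) {
    return(new_read_tibble(character(), character(), character(),
                           character(), character()))
  }
  if (n %% 4 != 0) {
    stop("truncated FASTQ record starting at line ", 4 * (n %/% 4) + 1,
         " in ", path)
  }
  hdr <- lines[seq(1, n, by = 4)]
  seqs <- toupper(lines[seq(2, n, by = 4)])
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("missing '@' header at line ", 4 * (bad[1] - 1) + 1)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("missing '+' separator at line ", 4 * (bad[1] - 1) + 3)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("quality length differs from sequence length at line ",
         4 * (bad[1] - 1) + 4)
  }
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path)
  if (any(grepl("[^ACGTN]", seqs))) stop("non-ACGTN base in ", path)
  ids <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[[`, "", 1L))
  mate <- rep("unpaired", length(ids))
  mate[grepl("/1$", ids)] <- "r1"
  mate[grepl("/2$", ids)] <- "r2"
  new_read_tibble(ids, seqs, qual, mate)
}

#' Write a read table to FASTQ
#'
#' @param reads Read tibble as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$sequence
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}
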