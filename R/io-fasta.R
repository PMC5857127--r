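#' Read a FASTA file as a named character vector
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' sequences are uppercased.  Duplicate names and sequence data before the
#' first header are errors.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 1 && nzchar(first) && !startsWith(first, ">")) {
    stop("sequence data before first FASTA header in ", path)
  }
  ss <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in ", path, ": ",
         nm[duplicated(nm)][1])
  }
  stats::setNames(toupper(as.character(ss)), nm)
}

#' Write named sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(!is.null(names(x)), !anyDuplicated(names(x)))
  ss <- Biostrings::DNAStringSet(unname(x))
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
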