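DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param q Quality string.
#' @return Integer vector of per-base Phred scores.
#' @export
phred_to_int <- function(q) {
  utf8ToInt(q) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores (0..93).
#' @return Quality string.
#' @export
int_to_phred <- function(scores) {
  stopifnot(all(scores >= 0), all(scores <= 93))
  intToUtf8(scores + 33L)
}

# Stable derived seed: fold a purpose string into the user seed so that
# independent simulation substreams do not share RNG state.  Plain 32-bit
# polynomial string hash; all arithmetic stays exact in doubles.
derive_seed <- function(seed, purpose) {
  h <- 0
  for (c in utf8ToInt(purpose)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

random_dna <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# vectorised substring mismatch count between equal-length strings
count_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# replace characters at 1-based positions
replace_at <- function(seq, pos, replacement) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- replacement
  paste(ch, collapse = "")
}

new_read_tibble <- function(read_id, sequence, quality, mate = "unpaired",
                            truth_label = NA_character_) {
  tibble::tibble(
    read_id = read_id, sequence = sequence, quality = quality,
    mate = mate, truth_label = truth_label
  )
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(reads$read_id[bad], 3), collapse = ", "))
  }
  if (any(nchar(reads$sequence) < 1)) stop("empty read sequence")
  invisible(reads)
}

ROP_CATEGORIES <- c(
  "mapped_genomic", "mapped_repeat", "mapped_immune_locus",
  "low_quality", "low_complexity", "rdna", "lost_human", "hyper_edited",
  "lost_repeat", "ncl", "immune_vj", "microbial", "unaccounted"
)
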