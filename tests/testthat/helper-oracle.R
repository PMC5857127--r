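# Independent alignment oracle: exhaustive offset enumeration with base R
# Levenshtein distance (utils::adist), minimised over reference end
# positions within the band.  Shares no code with the package's
# seed-and-extend path.

oracle_align <- function(read, ref, budget) {
  len <- nchar(read)
  L <- nchar(ref)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else readorigin::revcomp(read)
    for (o in 0:(L - 1)) {
      if (o + len - budget > L) next
      ends <- max(len - budget, 0):min(len + budget, L - o)
      subs <- substring(ref, o + 1, o + ends)
      d <- min(utils::adist(q, subs))
      if (d <= budget) {
        out[[length(out) + 1]] <-
          data.frame(strand = strand, ref_start = o, edit_distance = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), ref_start = integer(),
                      edit_distance = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$ref_start), , drop = FALSE]
}

expect_matches_oracle <- function(read, ref, budget, k = 16) {
  idx <- build_index(c(ref1 = ref), k)
  got <- align_reads(read, idx, budget)
  got <- got[order(got$strand, got$ref_start),
             c("strand", "ref_start", "edit_distance")]
  want <- oracle_align(read, ref, budget)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
}
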