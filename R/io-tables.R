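#' Read a RepeatMasker-style repeat annotation table
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `strand`, `name`,
#' `class`, `family`; coordinates 0-based half-open (as written by
#' [write_repeat_annotation()]).
#'
#' @param path Path to the TSV.
#' @return Repeat-annotation tibble.
#' @export
read_repeat_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand", "name", "class",
                  "family") %in% names(df)))
  if (any(df$end <= df$start)) stop("repeat interval with end <= start")
  tibble::as_tibble(df)
}

#' Write a repeat annotation table
#' @param ann Repeat-annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon map
#'
#' Two tab-separated columns: genome name and semicolon-joined taxon path
#' (domain;...;species).
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `genome`, `taxon_path`.
#' @export
read_taxa <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("genome", "taxon_path") %in% names(df)))
  if (any(is.na(df$taxon_path) | !nzchar(as.character(df$taxon_path)))) {
    stop("empty taxon path")
  }
  tibble::as_tibble(df)
}

#' Write a taxon map
#' @param taxa Tibble with columns `genome`, `taxon_path`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa <- function(taxa, path) {
  utils::write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
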