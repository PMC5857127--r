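#' Write a reference bundle to a directory of standard files
#'
#' Writes `refs/host.fasta`, `refs/rdna.fasta`, `refs/repeats.fasta`,
#' `refs/v_segments.fasta`, `refs/j_segments.fasta`, `refs/microbes.fasta`,
#' `annotation.gtf`, `repeats.tsv` (annotation), `repeat_classes.tsv`,
#' `segments.tsv` (segment/locus map), `immune_loci.tsv` and `taxa.tsv`.
#'
#' @param bundle Bundle from [build_references()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  refs <- file.path(dir, "refs")
  dir.create(refs, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$host_genome, file.path(refs, "host.fasta"))
  write_fasta(c(rdna = bundle$rdna_unit), file.path(refs, "rdna.fasta"))
  write_fasta(stats::setNames(bundle$repeat_consensus$sequence,
                              bundle$repeat_consensus$name),
              file.path(refs, "repeats.fasta"))
  write_fasta(stats::setNames(bundle$v_segments$sequence,
                              bundle$v_segments$name),
              file.path(refs, "v_segments.fasta"))
  write_fasta(stats::setNames(bundle$j_segments$sequence,
                              bundle$j_segments$name),
              file.path(refs, "j_segments.fasta"))
  write_fasta(bundle$microbial_genomes, file.path(refs, "microbes.fasta"))
  write_gtf(bundle$host_annotation, file.path(dir, "annotation.gtf"))
  write_repeat_annotation(bundle$repeat_annotation,
                          file.path(dir, "repeats.tsv"))
  utils::write.table(bundle$repeat_consensus[, c("name", "class", "family")],
                     file.path(dir, "repeat_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seg <- dplyr::bind_rows(
    tibble::tibble(name = bundle$v_segments$name, type = "V",
                   locus = bundle$v_segments$locus),
    tibble::tibble(name = bundle$j_segments$name, type = "J",
                   locus = bundle$j_segments$locus))
  utils::write.table(seg, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$immune_loci, file.path(dir, "immune_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_taxa(bundle$microbial_taxa, file.path(dir, "taxa.tsv"))
  invisible(dir)
}

#' Read a reference bundle from a directory
#'
#' Inverse of [write_bundle()]; transcript models and spliced sequences are
#' rebuilt from the annotation.
#'
#' @param dir Directory written by [write_bundle()].
#' @return An `rop_bundle`.
#' @export
read_bundle <- function(dir) {
  refs <- file.path(dir, "refs")
  genome <- read_fasta(file.path(refs, "host.fasta"))
  annotation <- read_gtf(file.path(dir, "annotation.gtf"))
  classes <- utils::read.table(file.path(dir, "repeat_classes.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  cons <- read_fasta(file.path(refs, "repeats.fasta"))
  seg <- utils::read.table(file.path(dir, "segments.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  vseq <- read_fasta(file.path(refs, "v_segments.fasta"))
  jseq <- read_fasta(file.path(refs, "j_segments.fasta"))
  mito <- annotation$chrom[annotation$kind == "mitochondrial_contig"]
  models <- transcript_models(annotation)
  structure(list(
    host_genome = genome,
    host_annotation = annotation,
    mito_chrom = if (length(mito)) mito[1] else NA_character_,
    transcripts = models,
    transcript_seqs = transcript_sequences(genome, models),
    rdna_unit = unname(read_fasta(file.path(refs, "rdna.fasta"))[1]),
    repeat_consensus = tibble::tibble(
      name = classes$name, class = classes$class, family = classes$family,
      sequence = unname(cons[classes$name])),
    repeat_annotation = read_repeat_annotation(file.path(dir, "repeats.tsv")),
    immune_loci = tibble::as_tibble(
      utils::read.table(file.path(dir, "immune_loci.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)),
    v_segments = tibble::tibble(
      name = seg$name[seg$type == "V"], locus = seg$locus[seg$type == "V"],
      sequence = unname(vseq[seg$name[seg$type == "V"]])),
    j_segments = tibble::tibble(
      name = seg$name[seg$type == "J"], locus = seg$locus[seg$type == "J"],
      sequence = unname(jseq[seg$name[seg$type == "J"]])),
    microbial_genomes = read_fasta(file.path(refs, "microbes.fasta")),
    microbial_taxa = read_taxa(file.path(dir, "taxa.tsv"))
  ), class = "rop_bundle")
}
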