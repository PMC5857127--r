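# Synthetic reference bundle.  The layout is fixed relative to the
# chromosome length: genes on a regular grid with repeat slots in the
# intergenic gaps, and all immune loci contiguous on chr2 (as each human
# locus is contiguous on its chromosome) so a germline V+J split alignment
# is short-range co-linear, not a spurious fusion.

REPEAT_FAMILIES <- tibble::tibble(
  name = c("AluSim", "L1Sim", "MIRSim", "SVASim"),
  class = c("SINE", "LINE", "SINE", "Retroposon"),
  family = c("Alu", "L1", "MIR", "SVA"),
  length = c(300L, 600L, 260L, 400L),
  planted = c(TRUE, TRUE, TRUE, FALSE)
)

MICROBIAL_TAXA <- c(
  "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia;Escherichia_sim",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas;Pseudomonas_sim",
  "Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;Streptococcus_sim",
  "Bacteria;Actinobacteria;Actinomycetia;Propionibacteriales;Propionibacteriaceae;Cutibacterium;Cutibacterium_sim",
  "Eukaryota;Ascomycota;Saccharomycetes;Saccharomycetales;Saccharomycetaceae;Candida;Candida_sim",
  "Viruses;Phixviricota;Malgrandaviricetes;Petitvirales;Microviridae;Sinsheimervirus;Phage_phiX_sim"
)

# mutate a sequence by substituting each base with given probability
mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos],
                    function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
  paste(ch, collapse = "")
}

# resample k-mers of `seq` until it shares none (either strand) with the
# rejection index
reject_shared_kmers <- function(seq, index, k, max_iter = 100) {
  for (i in seq_len(max_iter)) {
    fw <- .cpp_kmer_hit_positions(index$ptr, seq)
    rcseq <- revcomp(seq)
    rc <- .cpp_kmer_hit_positions(index$ptr, rcseq)
    if (!length(fw) && !length(rc)) return(seq)
    n <- nchar(seq)
    pos <- unique(c(fw + 1, n - (rc + k - 1) + 1))
    for (p in pos) {
      substr(seq, p, p + k - 1) <- random_dna(k)
    }
  }
  stop("k-mer rejection did not converge; constraints infeasible")
}

gene_features <- function(gene_id, chrom, s, strand,
                          exon_len = 200L, intron_len = 400L,
                          utr5 = 60L, utr3 = 80L) {
  tid <- paste0(gene_id, ".t1")
  e1 <- c(s, s + exon_len)
  e2 <- c(s + exon_len + intron_len, s + 2 * exon_len + intron_len)
  e3 <- c(s + 2 * (exon_len + intron_len), s + 3 * exon_len + 2 * intron_len)
  span <- c(s, e3[2])
  row <- function(kind, start, end, transcript = tid) {
    tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                   kind = kind, gene_id = gene_id, transcript_id = transcript)
  }
  feats <- dplyr::bind_rows(
    row("gene", span[1], span[2], NA_character_),
    row("exon", e1[1], e1[2]), row("exon", e2[1], e2[2]),
    row("exon", e3[1], e3[2])
  )
  if (strand == "+") {
    feats <- dplyr::bind_rows(
      feats,
      row("UTR5", e1[1], e1[1] + utr5),
      row("CDS", e1[1] + utr5, e1[2]),
      row("CDS", e2[1], e2[2]),
      row("CDS", e3[1], e3[2] - utr3),
      row("UTR3", e3[2] - utr3, e3[2])
    )
  } else {
    feats <- dplyr::bind_rows(
      feats,
      row("UTR5", e3[2] - utr5, e3[2]),
      row("CDS", e3[1], e3[2] - utr5),
      row("CDS", e2[1], e2[2]),
      row("CDS", e1[1] + utr3, e1[2]),
      row("UTR3", e1[1], e1[1] + utr3)
    )
  }
  feats
}

#' Build a synthetic reference bundle
#'
#' Generates, deterministically for a given seed: a host genome (two
#' chromosomes plus a mitochondrial contig) with annotated multi-exon genes
#' (UTR5/CDS/introns/UTR3); repeat consensus sequences, three families
#' planted as diverged genomic copies and one (SVA-like) kept out of the
#' host; germline V and J segments per immune locus planted contiguously on
#' chr2; an rDNA unit absent from the host; and microbial genomes with
#' taxon paths, rejection-sampled to share no k-mer (either strand) with
#' any host-side compartment.
#'
#' @param config A [sim_config()].
#' @return A list of class `rop_bundle` with elements `host_genome`,
#'   `host_annotation`, `mito_chrom`, `transcripts` (models),
#'   `transcript_seqs`, `rdna_unit`, `repeat_consensus`,
#'   `repeat_annotation`, `immune_loci`, `v_segments`, `j_segments`,
#'   `microbial_genomes`, `microbial_taxa`.
#' @export
build_references <- function(config = sim_config()) {
  stopifnot(inherits(config, "rop_sim_config"))
  withr::with_seed(derive_seed(config$seed, "references"), {
    L <- config$chromosome_length
    genome <- c(chr1 = random_dna(L), chr2 = random_dna(L),
                chrM = random_dna(config$mito_length))

    # genes: 6 on chr1, 4 on chr2, alternating strand
    gene_starts <- list(chr1 = 1000L + 4500L * (0:5),
                        chr2 = 1000L + 4500L * (0:3))
    feats <- list()
    gi <- 0
    for (chrom in names(gene_starts)) {
      for (s in gene_starts[[chrom]]) {
        gi <- gi + 1
        strand <- if (gi %% 2 == 1) "+" else "-"
        feats[[gi]] <- gene_features(sprintf("g%02d", gi), chrom, s, strand)
      }
    }
    annotation <- dplyr::bind_rows(
      feats,
      tibble::tibble(chrom = "chrM", start = 0L,
                     end = config$mito_length, strand = "+",
                     kind = "mitochondrial_contig",
                     gene_id = NA_character_, transcript_id = NA_character_)
    )

    # repeat consensus + planted copies in intergenic slots
    fam <- REPEAT_FAMILIES
    consensus <- stats::setNames(
      vapply(fam$length, random_dna, character(1)), fam$name)
    slots <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", pos = c(3200L, 7700L, 12200L, 16700L,
                                             21200L)),
      tibble::tibble(chrom = "chr2", pos = c(3200L, 7700L, 12200L))
    )
    copy_plan <- tibble::tibble(
      name = c("AluSim", "L1Sim", "AluSim", "MIRSim", "MIRSim",
               "AluSim", "L1Sim", "MIRSim"),
      chrom = slots$chrom, pos = slots$pos
    )
    rep_ann <- list()
    for (i in seq_len(nrow(copy_plan))) {
      nm <- copy_plan$name[i]
      len <- fam$length[fam$name == nm]
      copy <- mutate_sequence(consensus[[nm]], config$repeat_copy_divergence)
      s <- copy_plan$pos[i]
      substr(genome[[copy_plan$chrom[i]]], s + 1, s + len) <- copy
      rep_ann[[i]] <- tibble::tibble(
        chrom = copy_plan$chrom[i], start = s, end = s + len, strand = "+",
        name = nm, class = fam$class[fam$name == nm],
        family = fam$family[fam$name == nm]
      )
    }
    repeat_annotation <- dplyr::bind_rows(rep_ann)

    # immune loci: V then J segments, contiguous on chr2
    host_idx <- build_index(genome, config$k_reject)
    v_rows <- list(); j_rows <- list(); loci_rows <- list()
    vi <- 0; ji <- 0
    for (locus in config$loci) {
      for (v in seq_len(config$n_v)) {
        vi <- vi + 1
        seq <- reject_shared_kmers(random_dna(config$v_length), host_idx,
                                   config$k_reject)
        v_rows[[vi]] <- tibble::tibble(name = sprintf("%sV%d", locus, v),
                                       locus = locus, sequence = seq)
      }
      for (j in seq_len(config$n_j)) {
        ji <- ji + 1
        seq <- reject_shared_kmers(random_dna(config$j_length), host_idx,
                                   config$k_reject)
        j_rows[[ji]] <- tibble::tibble(name = sprintf("%sJ%d", locus, j),
                                       locus = locus, sequence = seq)
      }
    }
    v_segments <- dplyr::bind_rows(v_rows)
    j_segments <- dplyr::bind_rows(j_rows)
    vpos <- 17000L + 400L * (seq_len(nrow(v_segments)) - 1)
    jpos <- 24500L + 200L * (seq_len(nrow(j_segments)) - 1)
    for (i in seq_len(nrow(v_segments))) {
      substr(genome[["chr2"]], vpos[i] + 1,
             vpos[i] + config$v_length) <- v_segments$sequence[i]
      loci_rows[[length(loci_rows) + 1]] <- tibble::tibble(
        chrom = "chr2", start = vpos[i], end = vpos[i] + config$v_length,
        strand = "+", segment_type = "V", name = v_segments$name[i],
        locus = v_segments$locus[i])
    }
    for (i in seq_len(nrow(j_segments))) {
      substr(genome[["chr2"]], jpos[i] + 1,
             jpos[i] + config$j_length) <- j_segments$sequence[i]
      loci_rows[[length(loci_rows) + 1]] <- tibble::tibble(
        chrom = "chr2", start = jpos[i], end = jpos[i] + config$j_length,
        strand = "+", segment_type = "J", name = j_segments$name[i],
        locus = j_segments$locus[i])
    }
    immune_loci <- dplyr::bind_rows(loci_rows)

    # rDNA unit and the host-absent repeat family, rejected against the
    # final host genome
    host_idx <- build_index(genome, config$k_reject)
    rdna_unit <- reject_shared_kmers(random_dna(config$rdna_length),
                                     host_idx, config$k_reject)
    consensus[["SVASim"]] <- reject_shared_kmers(
      consensus[["SVASim"]], host_idx, config$k_reject)

    # microbial genomes: rejected against host + rDNA + repeat consensus +
    # immune segment libraries
    reject_refs <- c(genome, rdna = rdna_unit, consensus,
                     stats::setNames(v_segments$sequence, v_segments$name),
                     stats::setNames(j_segments$sequence, j_segments$name))
    rej_idx <- build_index(reject_refs, config$k_reject)
    taxa <- MICROBIAL_TAXA[seq_len(config$n_microbial)]
    microbial <- character(config$n_microbial)
    names(microbial) <- sprintf("microbe%02d", seq_len(config$n_microbial))
    for (i in seq_len(config$n_microbial)) {
      len <- sample(seq(config$microbial_length_range[1],
                        config$microbial_length_range[2]), 1)
      microbial[i] <- reject_shared_kmers(random_dna(len), rej_idx,
                                          config$k_reject)
    }
    if (config$homology_stress) {
      sva <- consensus[["SVASim"]]
      substr(microbial[1], 2001, 2000 + nchar(sva)) <- sva
    }

    models <- transcript_models(annotation)
    bundle <- structure(list(
      host_genome = genome,
      host_annotation = annotate_derived_features(annotation),
      mito_chrom = "chrM",
      transcripts = models,
      transcript_seqs = transcript_sequences(genome, models),
      rdna_unit = rdna_unit,
      repeat_consensus = tibble::tibble(
        name = fam$name, class = fam$class, family = fam$family,
        sequence = unname(consensus[fam$name])),
      repeat_annotation = repeat_annotation,
      immune_loci = immune_loci,
      v_segments = v_segments,
      j_segments = j_segments,
      microbial_genomes = microbial,
      microbial_taxa = tibble::tibble(genome = names(microbial),
                                      taxon_path = taxa)
    ), class = "rop_bundle")
    bundle
  })
}

#' @export
print.rop_bundle <- function(x, ...) {
  cat("<rop_bundle>\n",
      " host:", length(x$host_genome), "sequences,",
      sum(nchar(x$host_genome)), "bp;",
      nrow(x$transcripts), "transcripts\n",
      " repeats:", nrow(x$repeat_consensus), "consensus,",
      nrow(x$repeat_annotation), "planted copies\n",
      " immune:", nrow(x$v_segments), "V +", nrow(x$j_segments),
      "J segments\n",
      " microbial:", length(x$microbial_genomes), "genomes\n")
  invisible(x)
}
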