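# Labelled read mixture over every protocol category.  Each class has its
# own derived RNG substream, so adding reads of one class never perturbs
# another class's draws.

apply_sequencing_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos],
                    function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
  paste(ch, collapse = "")
}

# uniform substring of length len from a sequence pool, weighted by length
draw_fragment <- function(seqs, len) {
  w <- nchar(seqs) - len + 1
  keep <- w > 0
  stopifnot(any(keep))
  i <- sample(which(keep), 1, prob = w[keep])
  s <- sample.int(w[i], 1)
  list(ref = names(seqs)[i] %||% as.character(i),
       pos = s - 1L,
       seq = substring(seqs[[i]], s, s + len - 1))
}

truth_skeleton <- function(read_id, class) {
  tibble::tibble(
    read_id = read_id, class = class,
    source_ref = NA_character_, source_pos = NA_integer_,
    orientation = "+",
    n_edits = NA_integer_, edited_positions = NA_character_,
    v_gene = NA_character_, j_gene = NA_character_, locus = NA_character_,
    v_overlap = NA_integer_, j_overlap = NA_integer_,
    genome = NA_character_, taxon_path = NA_character_,
    ncl_subtype = NA_character_, event_id = NA_character_,
    bp_a_chrom = NA_character_, bp_a_pos = NA_integer_,
    bp_b_chrom = NA_character_, bp_b_pos = NA_integer_,
    repeat_name = NA_character_, repeat_source = NA_character_
  )
}

#' Simulate a labelled read mixture
#'
#' Generates reads for every class requested in `config$n_reads` from a
#' reference bundle: spliced transcriptomic reads (including
#' junction-spanning ones), mitochondrial and immune-locus genomic reads,
#' repeat reads (planted copies and the host-absent consensus), rDNA reads,
#' low-quality reads (Phred-driven corruption), low-complexity reads
#' (homopolymer and dinucleotide runs), lost-human reads (a fixed number of
#' substitutions beyond the primary budget), hyper-edited reads (clustered
#' A-to-G conversions, both orientations), the three non-co-linear classes
#' (head-to-tail circRNA, cross-chromosome fusion, distant co-linear
#' trans-splicing), V(D)J junction reads and microbial reads.  Sequencing
#' errors are applied after class construction at `config$base_error_rate`.
#'
#' @param bundle A bundle from [build_references()].
#' @param config The [sim_config()] used for the bundle.
#' @return A list with `reads` (read tibble with `truth_label`) and `truth`
#'   (per-read truth table with class-specific detail columns).
#' @export
simulate_reads <- function(bundle, config = sim_config()) {
  stopifnot(inherits(bundle, "rop_bundle"))
  len <- config$read_length
  n <- config$n_reads
  out_reads <- list()
  out_truth <- list()
  q40 <- strrep("I", len)

  gen_class <- function(class, n_class, fn) {
    if (n_class == 0) return()
    withr::with_seed(derive_seed(config$seed, paste0("reads/", class)), {
      ids <- sprintf("%s_%05d", gsub("[^a-z_]", "", class), seq_len(n_class))
      res <- fn(ids)
      res$reads$truth_label <- class
      out_reads[[class]] <<- res$reads
      out_truth[[class]] <<- res$truth
    })
  }

  simple_class <- function(class, pool, n_class) {
    gen_class(class, n_class, function(ids) {
      tr <- truth_skeleton(ids, class)
      seqs <- character(length(ids))
      for (i in seq_along(ids)) {
        fr <- draw_fragment(pool, len)
        seqs[i] <- apply_sequencing_errors(fr$seq, config$base_error_rate)
        tr$source_ref[i] <- fr$ref
        tr$source_pos[i] <- fr$pos
      }
      list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
           truth = tr)
    })
  }

  simple_class("transcriptomic", bundle$transcript_seqs, n[["transcriptomic"]])
  simple_class("mitochondrial",
               bundle$host_genome[bundle$mito_chrom], n[["mitochondrial"]])
  simple_class("rdna", c(rdna = bundle$rdna_unit), n[["rdna"]])
  simple_class("microbial", bundle$microbial_genomes, n[["microbial"]])

  # microbial truth gains taxon paths
  if (!is.null(out_truth[["microbial"]])) {
    tt <- out_truth[["microbial"]]
    tt$genome <- tt$source_ref
    tt$taxon_path <- bundle$microbial_taxa$taxon_path[
      match(tt$genome, bundle$microbial_taxa$genome)]
    out_truth[["microbial"]] <- tt
  }

  # immune-locus reads: wholly inside planted germline V segments
  gen_class("immune_locus", n[["immune_locus"]], function(ids) {
    vs <- bundle$immune_loci[bundle$immune_loci$segment_type == "V", ]
    tr <- truth_skeleton(ids, "immune_locus")
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      r <- vs[sample.int(nrow(vs), 1), ]
      s <- r$start + sample.int(r$end - r$start - len + 1, 1) - 1L
      seqs[i] <- apply_sequencing_errors(
        substring(bundle$host_genome[[r$chrom]], s + 1, s + len),
        config$base_error_rate)
      tr$source_ref[i] <- r$chrom
      tr$source_pos[i] <- s
      tr$locus[i] <- r$locus
      tr$v_gene[i] <- r$name
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  # repeat reads: half from planted genomic copies, half from the
  # host-absent consensus
  gen_class("repeat", n[["repeat"]], function(ids) {
    tr <- truth_skeleton(ids, "repeat")
    seqs <- character(length(ids))
    absent <- bundle$repeat_consensus[
      !bundle$repeat_consensus$name %in% bundle$repeat_annotation$name, ]
    for (i in seq_along(ids)) {
      if (i %% 2 == 1) {
        r <- bundle$repeat_annotation[
          sample.int(nrow(bundle$repeat_annotation), 1), ]
        s <- r$start + sample.int(r$end - r$start - len + 1, 1) - 1L
        seqs[i] <- substring(bundle$host_genome[[r$chrom]], s + 1, s + len)
        tr$source_ref[i] <- r$chrom
        tr$source_pos[i] <- s
        tr$repeat_name[i] <- r$name
        tr$repeat_source[i] <- "genomic_copy"
      } else {
        r <- absent[sample.int(nrow(absent), 1), ]
        s <- sample.int(nchar(r$sequence) - len + 1, 1) - 1L
        seqs[i] <- substring(r$sequence, s + 1, s + len)
        tr$source_ref[i] <- r$name
        tr$source_pos[i] <- s
        tr$repeat_name[i] <- r$name
        tr$repeat_source[i] <- "consensus_absent"
      }
      seqs[i] <- apply_sequencing_errors(seqs[i], config$base_error_rate)
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  # low-quality: transcriptomic fragments whose base errors follow their
  # (poor) quality scores; identified by quality alone at QC
  gen_class("low_quality", n[["low_quality"]], function(ids) {
    tr <- truth_skeleton(ids, "low_quality")
    seqs <- character(length(ids))
    quals <- character(length(ids))
    n_low <- ceiling(config$low_quality_position_fraction * len)
    for (i in seq_along(ids)) {
      fr <- draw_fragment(bundle$transcript_seqs, len)
      q <- rep(40L, len)
      low_pos <- sample.int(len, n_low)
      q[low_pos] <- sample(2:20, n_low, replace = TRUE)
      p_err <- 10^(-q / 10)
      flip <- which(stats::runif(len) < p_err)
      seq <- fr$seq
      if (length(flip)) {
        ch <- strsplit(seq, "")[[1]]
        ch[flip] <- vapply(ch[flip],
                           function(b) sample(setdiff(DNA_BASES, b), 1),
                           character(1), USE.NAMES = FALSE)
        seq <- paste(ch, collapse = "")
      }
      seqs[i] <- seq
      quals[i] <- int_to_phred(q)
      tr$source_ref[i] <- fr$ref
      tr$source_pos[i] <- fr$pos
    }
    list(reads = new_read_tibble(ids, seqs, quals), truth = tr)
  })

  # low-complexity: mostly homopolymers (poly(A) tails dominate real
  # low-complexity unmapped reads), the rest dinucleotide repeats
  gen_class("low_complexity", n[["low_complexity"]], function(ids) {
    tr <- truth_skeleton(ids, "low_complexity")
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      if (stats::runif(1) < 0.7) {
        base <- sample(DNA_BASES, 1, prob = c(0.7, 0.1, 0.1, 0.1))
        seqs[i] <- strrep(base, len)
        tr$source_ref[i] <- paste0("homopolymer_", base)
      } else {
        b <- sample(DNA_BASES, 2)
        seqs[i] <- substring(strrep(paste0(b[1], b[2]), ceiling(len / 2) + 1),
                             1, len)
        tr$source_ref[i] <- paste0("dinucleotide_", b[1], b[2])
      }
      seqs[i] <- apply_sequencing_errors(seqs[i], config$base_error_rate)
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  # lost-human: transcriptomic fragments with a fixed number of extra
  # substitutions — beyond the primary budget, within the sensitive one
  gen_class("lost_human", n[["lost_human"]], function(ids) {
    tr <- truth_skeleton(ids, "lost_human")
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      fr <- draw_fragment(bundle$transcript_seqs, len)
      pos <- sample.int(len, config$lost_human_edits)
      ch <- strsplit(fr$seq, "")[[1]]
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(DNA_BASES, b), 1),
                        character(1), USE.NAMES = FALSE)
      seqs[i] <- apply_sequencing_errors(paste(ch, collapse = ""),
                                         config$base_error_rate)
      tr$source_ref[i] <- fr$ref
      tr$source_pos[i] <- fr$pos
      tr$n_edits[i] <- config$lost_human_edits
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  # hyper-edited: A-rich transcript fragments with clustered A->G
  # conversions; half sampled in reverse-complement orientation
  gen_class("hyper_edited", n[["hyper_edited"]], function(ids) {
    tr <- truth_skeleton(ids, "hyper_edited")
    seqs <- character(length(ids))
    win <- round(config$hyper_edit_window * len)
    for (i in seq_along(ids)) {
      repeat {
        fr <- draw_fragment(bundle$transcript_seqs, len)
        w0 <- sample.int(len - win + 1, 1)
        ch <- strsplit(fr$seq, "")[[1]]
        a_pos <- which(ch == "A")
        a_in <- a_pos[a_pos >= w0 & a_pos < w0 + win]
        if (length(a_in) >= config$hyper_edit_min_a) break
      }
      n_edit <- ceiling(config$hyper_edit_fraction * length(a_in))
      edited <- sort(sample(a_in, n_edit))
      ch[edited] <- "G"
      seq <- paste(ch, collapse = "")
      pos_read <- edited
      orient <- "+"
      if (stats::runif(1) < 0.5) {
        seq <- revcomp(seq)
        pos_read <- sort(len + 1L - edited)
        orient <- "-"
      }
      seqs[i] <- apply_sequencing_errors(seq, config$base_error_rate)
      tr$source_ref[i] <- fr$ref
      tr$source_pos[i] <- fr$pos
      tr$orientation[i] <- orient
      tr$n_edits[i] <- n_edit
      tr$edited_positions[i] <- paste(pos_read, collapse = ",")
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  # non-co-linear classes; events are breakpoint pairs shared by ~10 reads
  plus_genes <- function(chrom = NULL) {
    g <- bundle$host_annotation[bundle$host_annotation$kind == "gene" &
                                  bundle$host_annotation$strand == "+", ]
    if (!is.null(chrom)) g <- g[g$chrom == chrom, ]
    g
  }
  junction_read <- function(chrom_a, pos_a, chrom_b, pos_b, s) {
    # s bases ending at pos_a, then len - s bases starting at pos_b
    paste0(substring(bundle$host_genome[[chrom_a]], pos_a - s + 1, pos_a),
           substring(bundle$host_genome[[chrom_b]], pos_b + 1,
                     pos_b + (len - s)))
  }
  gen_ncl <- function(class, make_event) {
    gen_class(class, n[[class]], function(ids) {
      tr <- truth_skeleton(ids, class)
      seqs <- character(length(ids))
      n_events <- max(1L, ceiling(length(ids) / 10))
      events <- lapply(seq_len(n_events), make_event)
      for (i in seq_along(ids)) {
        ev <- events[[(i - 1) %% n_events + 1]]
        s <- sample(40:60, 1)
        seq <- junction_read(ev$chrom_a, ev$pos_a, ev$chrom_b, ev$pos_b, s)
        orient <- "+"
        if (stats::runif(1) < 0.5) {
          seq <- revcomp(seq)
          orient <- "-"
        }
        seqs[i] <- apply_sequencing_errors(seq, config$base_error_rate)
        tr$ncl_subtype[i] <- sub("ncl_", "", class)
        tr$event_id[i] <- sprintf("%s_ev%02d", class, (i - 1) %% n_events + 1)
        tr$orientation[i] <- orient
        tr$bp_a_chrom[i] <- ev$chrom_a; tr$bp_a_pos[i] <- ev$pos_a
        tr$bp_b_chrom[i] <- ev$chrom_b; tr$bp_b_pos[i] <- ev$pos_b
      }
      list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
           truth = tr)
    })
  }
  # circRNA: back-splice from the end of exon 2 to the start of exon 1 of
  # one plus-strand gene (downstream sequence first on the read)
  gen_ncl("ncl_circ", function(e) {
    g <- plus_genes()
    g <- g[sample.int(nrow(g), 1), ]
    list(chrom_a = g$chrom, pos_a = g$start + 800L,
         chrom_b = g$chrom, pos_b = g$start)
  })
  # fusion: junction across chromosomes between exonic positions
  gen_ncl("ncl_fusion", function(e) {
    ga <- plus_genes("chr1"); gb <- plus_genes("chr2")
    ga <- ga[sample.int(nrow(ga), 1), ]; gb <- gb[sample.int(nrow(gb), 1), ]
    list(chrom_a = ga$chrom, pos_a = ga$start + 700L + 7L * e,
         chrom_b = gb$chrom, pos_b = gb$start + 600L + 7L * e)
  })
  # trans-splicing: co-linear junction between two distant genes on chr1
  gen_ncl("ncl_trans", function(e) {
    g <- plus_genes("chr1")
    g <- g[order(g$start), ]
    ga <- g[1, ]; gb <- g[nrow(g), ]
    list(chrom_a = ga$chrom, pos_a = ga$start + 700L + 7L * e,
         chrom_b = gb$chrom, pos_b = gb$start + 600L + 7L * e)
  })

  # V(D)J junction reads: V 3' suffix + random insert + J 5' prefix
  gen_class("immune_vj", n[["immune_vj"]], function(ids) {
    tr <- truth_skeleton(ids, "immune_vj")
    seqs <- character(length(ids))
    ins_r <- config$junction_insert_range
    vo_r <- config$v_overlap_range
    for (i in seq_along(ids)) {
      locus <- sample(config$loci, 1)
      v <- bundle$v_segments[bundle$v_segments$locus == locus, ]
      j <- bundle$j_segments[bundle$j_segments$locus == locus, ]
      v <- v[sample.int(nrow(v), 1), ]
      j <- j[sample.int(nrow(j), 1), ]
      ins <- sample(ins_r[1]:ins_r[2], 1)
      # the read must end inside J, so the V overlap floor rises when the
      # insert is short
      vo_min <- max(vo_r[1], len - ins - nchar(j$sequence))
      vo <- sample(vo_min:vo_r[2], 1)
      jo <- len - vo - ins
      stopifnot(jo >= 1, jo <= nchar(j$sequence))
      seq <- paste0(substring(v$sequence, nchar(v$sequence) - vo + 1),
                    random_dna(ins),
                    substring(j$sequence, 1, jo))
      orient <- "+"
      if (stats::runif(1) < 0.5) {
        seq <- revcomp(seq)
        orient <- "-"
      }
      seqs[i] <- apply_sequencing_errors(seq, config$base_error_rate)
      tr$locus[i] <- locus
      tr$v_gene[i] <- v$name
      tr$j_gene[i] <- j$name
      tr$v_overlap[i] <- vo
      tr$j_overlap[i] <- jo
      tr$orientation[i] <- orient
    }
    list(reads = new_read_tibble(ids, seqs, rep(q40, length(ids))),
         truth = tr)
  })

  reads <- dplyr::bind_rows(out_reads)
  truth <- dplyr::bind_rows(out_truth)
  # deterministic shuffle so class order carries no information
  withr::with_seed(derive_seed(config$seed, "shuffle"), {
    perm <- sample.int(nrow(reads))
  })
  reads <- reads[perm, ]
  truth <- truth[match(reads$read_id, truth$read_id), ]
  validate_reads(reads)
  stopifnot(nrow(reads) == sum(config$n_reads),
            !anyDuplicated(truth$read_id))
  list(reads = reads, truth = truth)
}
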