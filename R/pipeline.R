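ROP_STEPS <- c("qc", "lost_human", "hyper_edit", "lost_repeat", "ncl",
               "immune", "microbial")

#' Pipeline configuration
#'
#' @param step_order Permutation of the seven unmapped-read steps.  The
#'   default is the protocol order; altering it reproduces the
#'   order-sensitivity experiment.
#' @param aligner,qc,hyper,ncl,vj,microbial Module configurations.
#' @param deep_distance Intergenic vs deep-intergenic threshold (bases).
#' @param repeat_min_overlap Repeat assignment threshold (fraction of
#'   read).
#' @param lowq_mode `"exclude"` removes low-quality reads at QC (the
#'   main accounting); `"mark"` passes them downstream, as later protocol
#'   releases do.
#' @param intermediates_dir When set, per-step FASTQ snapshots of the
#'   reads each step claims (and the final residue) are written there,
#'   mirroring the protocol's file handoffs.
#' @param sample_id Sample label for the profile.
#' @param seed Seed (recorded; the pipeline itself is deterministic).
#' @return A list of class `rop_config`.
#' @export
rop_config <- function(step_order = ROP_STEPS,
                       aligner = aligner_config(),
                       qc = qc_config(),
                       hyper = hyper_config(),
                       ncl = ncl_config(),
                       vj = vj_config(),
                       microbial = microbial_config(),
                       deep_distance = 10000,
                       repeat_min_overlap = 0.5,
                       lowq_mode = c("exclude", "mark"),
                       intermediates_dir = NULL,
                       sample_id = "sample1",
                       seed = 1) {
  if (!setequal(step_order, ROP_STEPS) ||
      length(step_order) != length(ROP_STEPS)) {
    stop("step_order must be a permutation of: ",
         paste(ROP_STEPS, collapse = ", "))
  }
  structure(list(
    step_order = step_order, aligner = aligner, qc = qc, hyper = hyper,
    ncl = ncl, vj = vj, microbial = microbial,
    deep_distance = deep_distance,
    repeat_min_overlap = repeat_min_overlap,
    lowq_mode = match.arg(lowq_mode),
    intermediates_dir = intermediates_dir,
    sample_id = sample_id, seed = as.integer(seed)
  ), class = "rop_config")
}

# genomic block table from host alignments; transcript-space hits
# (references named "tx|<transcript_id>") are mapped back to genomic
# blocks, junction hits yielding more than one block
host_alignment_blocks <- function(aln, bundle) {
  if (nrow(aln) == 0) {
    return(tibble::tibble(read_id = character(), aln_id = integer(),
                          chrom = character(), start = integer(),
                          end = integer(), block = integer(),
                          n_blocks = integer(), edit_distance = integer(),
                          read_length = integer()))
  }
  aln$aln_id <- seq_len(nrow(aln))
  is_tx <- startsWith(aln$ref_id, "tx|")
  gen <- aln[!is_tx, ]
  out <- list()
  if (nrow(gen)) {
    out$gen <- tibble::tibble(
      read_id = gen$read_id, aln_id = gen$aln_id, chrom = gen$ref_id,
      start = gen$ref_start, end = gen$ref_end, block = 1L, n_blocks = 1L,
      edit_distance = gen$edit_distance, read_length = gen$read_length)
  }
  tx <- aln[is_tx, ]
  if (nrow(tx)) {
    models <- bundle$transcripts
    model_of <- stats::setNames(seq_len(nrow(models)),
                                models$transcript_id)
    rid <- list(); aid <- list(); chm <- list(); st <- list(); en <- list()
    blk <- list(); nb <- list(); ed <- list(); rl <- list()
    tids <- substring(tx$ref_id, 4)
    for (i in seq_len(nrow(tx))) {
      m <- models[model_of[[tids[i]]], ]
      b <- tx_to_genomic(m, tx$ref_start[i], tx$ref_end[i])
      k <- nrow(b)
      rid[[i]] <- rep(tx$read_id[i], k); aid[[i]] <- rep(tx$aln_id[i], k)
      chm[[i]] <- b$chrom; st[[i]] <- b$start; en[[i]] <- b$end
      blk[[i]] <- seq_len(k); nb[[i]] <- rep(k, k)
      ed[[i]] <- rep(tx$edit_distance[i], k)
      rl[[i]] <- rep(tx$read_length[i], k)
    }
    out$tx <- tibble::tibble(
      read_id = unlist(rid), aln_id = unlist(aid), chrom = unlist(chm),
      start = unlist(st), end = unlist(en), block = unlist(blk),
      n_blocks = unlist(nb), edit_distance = unlist(ed),
      read_length = unlist(rl))
  }
  dplyr::bind_rows(out)
}

# optional per-step FASTQ handoff snapshots
snapshot_step <- function(reads, si, step, config) {
  dir <- config$intermediates_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(reads, file.path(dir, sprintf("step%d_%s.fastq", si, step)))
}

assignment_row <- function(read_id, category, step_index, step,
                           subcategory = NA_character_,
                           detail = NA_character_) {
  tibble::tibble(read_id = read_id, category = category,
                 step_index = as.integer(step_index), step = step,
                 subcategory = subcategory, detail = detail)
}

#' Run the full read origin protocol
#'
#' Stage 0 aligns all reads to the host transcriptome and genome at the
#' primary budget and profiles mapped reads into genomic, repeat, and
#' immune-locus categories.  Unmapped reads then pass through the seven
#' sequential steps in `config$step_order`, each step consuming its
#' matches so later steps never see them; the residue is `unaccounted`.
#' Fully deterministic for a given configuration and input.
#'
#' @param reads Read tibble.
#' @param bundle Reference bundle.
#' @param config Pipeline configuration.
#' @return An object of class `rop_result`: `assignments` (one row per
#'   read), `profile` (an `rop_profile`), `ncl_events`, `vj_events`,
#'   `taxon_profile`, `repeat_counts`, `immune_locus_counts`,
#'   `genomic_subcategories`, plus the configuration.
#' @export
rop_run <- function(reads, bundle, config = rop_config()) {
  stopifnot(inherits(bundle, "rop_bundle"))
  validate_reads(reads)
  acfg <- config$aligner
  steps <- config$step_order
  if ("microbial" %in% steps && length(bundle$microbial_genomes) == 0) {
    stop("microbial step enabled but bundle has no microbial genomes")
  }
  if ("immune" %in% steps &&
      (nrow(bundle$v_segments) == 0 || nrow(bundle$j_segments) == 0)) {
    stop("immune step enabled but bundle has no V/J segments")
  }
  if ("qc" %in% steps && !nzchar(bundle$rdna_unit %||% "")) {
    stop("qc step enabled but bundle has no rDNA unit")
  }

  n_total <- nrow(reads)
  assignments <- list()
  if (n_total == 0) {
    return(finalize_result(reads, dplyr::bind_rows(assignment_row(
      character(), character(), integer(), character())[0, ]),
      NULL, config))
  }

  host_refs <- c(bundle$host_genome,
                 stats::setNames(bundle$transcript_seqs,
                                 paste0("tx|", names(bundle$transcript_seqs))))
  host_idx <- build_index(host_refs, acfg$k)
  genome_idx <- build_index(bundle$host_genome, acfg$k)
  rdna_idx <- build_index(c(rdna = bundle$rdna_unit), acfg$k)
  repeat_idx <- build_index(
    stats::setNames(bundle$repeat_consensus$sequence,
                    bundle$repeat_consensus$name), acfg$k)
  microbial_idx <- if (length(bundle$microbial_genomes)) {
    build_index(bundle$microbial_genomes, acfg$k)
  } else NULL

  ## ---- stage 0: primary mapping + mapped-read profiling --------------
  aln <- align_reads(reads, host_idx, acfg$max_edit_distance_primary, acfg)
  # only best-distance alignments matter from here on (multi-mapping is
  # judged within the best stratum)
  aln <- aln |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$edit_distance == min(.data$edit_distance)) |>
    dplyr::ungroup()
  blocks <- host_alignment_blocks(aln, bundle)
  gcat <- categorize_mapped(blocks, bundle$host_annotation,
                            config$deep_distance)
  # representative (deterministically best) alignment blocks per read for
  # overlap profiling; aln_id follows the aligner's ranked order
  first_aln <- blocks |>
    dplyr::distinct(.data$read_id, .data$aln_id) |>
    dplyr::arrange(.data$aln_id) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  rep_blocks <- dplyr::semi_join(blocks, first_aln,
                                 by = c("read_id", "aln_id"))
  single_locus <- gcat$read_id[gcat$category != "multi_mapped"]
  rp <- repeat_profile(rep_blocks[rep_blocks$read_id %in% single_locus, ],
                       bundle$repeat_annotation, config$repeat_min_overlap)
  imm <- immune_locus_reads(
    rep_blocks[rep_blocks$read_id %in% single_locus, ], bundle$immune_loci)

  mapped_ids <- gcat$read_id
  cat_top <- rep("mapped_genomic", length(mapped_ids))
  subcat <- gcat$category
  detail <- rep(NA_character_, length(mapped_ids))
  is_imm <- mapped_ids %in% imm$read_id
  cat_top[is_imm] <- "mapped_immune_locus"
  detail[is_imm] <- imm$name[match(mapped_ids[is_imm], imm$read_id)]
  is_rep <- !is_imm & mapped_ids %in% rp$assignments$read_id
  cat_top[is_rep] <- "mapped_repeat"
  detail[is_rep] <- rp$assignments$name[
    match(mapped_ids[is_rep], rp$assignments$read_id)]
  assignments$mapped <- assignment_row(mapped_ids, cat_top, 0L, "mapping",
                                       subcat, detail)

  remaining <- reads[!reads$read_id %in% mapped_ids, ]
  ncl_classified <- NULL
  vj_events <- NULL
  microbial_result <- NULL
  lost_repeat_hits <- NULL
  marked_lowq <- character()

  ## ---- the seven sequential unmapped-read steps ----------------------
  for (si in seq_along(steps)) {
    step <- steps[si]
    if (nrow(remaining) == 0) break
    claimed <- NULL
    if (step == "qc") {
      part <- run_qc(remaining, rdna_idx, config$qc, acfg)
      if (config$lowq_mode == "exclude") {
        a_lq <- assignment_row(part$low_quality$read_id, "low_quality", si,
                               step)
      } else {
        marked_lowq <- part$low_quality$read_id
        a_lq <- assignment_row(character(), character(), integer(),
                               character())[0, ]
      }
      assignments[[paste0(si, "_qc")]] <- dplyr::bind_rows(
        a_lq,
        assignment_row(part$low_complexity$read_id, "low_complexity", si,
                       step),
        assignment_row(part$rdna$read_id, "rdna", si, step))
      keep_ids <- c(part$passed$read_id,
                    if (config$lowq_mode == "mark") marked_lowq)
      snapshot_step(remaining[!remaining$read_id %in% keep_ids, ],
                    si, step, config)
      remaining <- remaining[remaining$read_id %in% keep_ids, ]
      next
    } else if (step == "lost_human") {
      sb <- sensitive_budget(acfg, max(nchar(remaining$sequence)))
      hits <- align_reads(remaining, host_idx, sb, acfg)
      best <- dplyr::distinct(hits, .data$read_id, .keep_all = TRUE)
      claimed <- assignment_row(
        best$read_id, "lost_human", si, step,
        detail = sprintf("%s:%d:nm%d", best$ref_id, best$ref_start,
                         best$edit_distance))
    } else if (step == "hyper_edit") {
      # transformed realignment against genome AND spliced transcripts, so
      # minus-strand genes and exon-junction reads are recovered in
      # transcribed orientation
      hits <- detect_hyper_editing(remaining, host_refs,
                                   "A", "G", config$hyper, acfg)
      claimed <- assignment_row(
        hits$read_id, "hyper_edited", si, step,
        detail = sprintf("%s:%d:%s:n%d", hits$ref_id, hits$ref_start,
                         hits$strand, hits$n_sub))
    } else if (step == "lost_repeat") {
      sb <- sensitive_budget(acfg, max(nchar(remaining$sequence)))
      hits <- align_reads(remaining, repeat_idx, sb, acfg)
      best <- dplyr::distinct(hits, .data$read_id, .keep_all = TRUE)
      lost_repeat_hits <- dplyr::left_join(
        best, bundle$repeat_consensus[, c("name", "class", "family")],
        by = c(ref_id = "name"))
      claimed <- assignment_row(best$read_id, "lost_repeat", si, step,
                                detail = best$ref_id)
    } else if (step == "ncl") {
      sb <- sensitive_budget(acfg, max(nchar(remaining$sequence)))
      segs <- split_align_reads(remaining, genome_idx, sb, acfg)
      cls <- classify_split(segs, bundle$host_annotation, config$ncl)
      cls <- cls[cls$subtype != "none", ]
      ncl_classified <- cls
      claimed <- assignment_row(
        cls$read_id, "ncl", si, step, subcategory = cls$subtype,
        detail = sprintf("%s:%d|%s:%d", cls$chrom_a, cls$pos_a,
                         cls$chrom_b, cls$pos_b))
    } else if (step == "immune") {
      ev <- detect_vj(remaining, bundle$v_segments, bundle$j_segments,
                      config$vj)
      vj_events <- ev
      claimed <- assignment_row(
        ev$read_id, "immune_vj", si, step, subcategory = ev$locus,
        detail = paste0(ev$v_gene, "|", ev$j_gene))
    } else if (step == "microbial") {
      am <- assign_microbial(remaining, microbial_idx,
                             bundle$microbial_taxa, config$microbial, acfg)
      microbial_result <- am
      claimed <- assignment_row(
        am$assignments$read_id, "microbial", si, step,
        detail = ifelse(is.na(am$assignments$genome),
                        paste0("lca:", am$assignments$lca),
                        am$assignments$genome))
    }
    if (!is.null(claimed) && nrow(claimed)) {
      assignments[[paste0(si, "_", step)]] <- claimed
      snapshot_step(remaining[remaining$read_id %in% claimed$read_id, ],
                    si, step, config)
      remaining <- remaining[!remaining$read_id %in% claimed$read_id, ]
    }
  }
  snapshot_step(remaining, length(steps), "residual", config)
  if (nrow(remaining)) {
    lab <- if (config$lowq_mode == "mark") {
      ifelse(remaining$read_id %in% marked_lowq, "low_quality",
             "unaccounted")
    } else "unaccounted"
    assignments$residual <- assignment_row(remaining$read_id, lab,
                                           length(steps), "residual")
  }

  assign_tbl <- dplyr::bind_rows(assignments)
  assign_tbl <- assign_tbl[match(reads$read_id, assign_tbl$read_id), ]
  stopifnot(nrow(assign_tbl) == n_total, !anyDuplicated(assign_tbl$read_id))

  extras <- list(
    genomic_subcategories = dplyr::count(
      assign_tbl[assign_tbl$category == "mapped_genomic", ],
      .data$subcategory, name = "count"),
    repeat_counts = combine_repeat_counts(rp, lost_repeat_hits),
    immune_locus_counts = dplyr::count(imm, .data$locus,
                                       .data$segment_type, .data$name,
                                       name = "count"),
    ncl_events = aggregate_ncl_events(
      ncl_classified %||% classify_split(
        split_align_reads(reads[0, ], genome_idx, 1, acfg),
        bundle$host_annotation, config$ncl),
      config$ncl),
    ncl_reads = ncl_classified,
    vj_events = vj_events %||% detect_vj(reads[0, ], bundle$v_segments,
                                         bundle$j_segments, config$vj),
    taxon_profile = if (!is.null(microbial_result)) {
      microbial_result$profile
    } else NULL,
    microbial_assignments = if (!is.null(microbial_result)) {
      microbial_result$assignments
    } else NULL
  )
  finalize_result(reads, assign_tbl, extras, config)
}

combine_repeat_counts <- function(rp, lost_repeat_hits) {
  mapped <- rp$counts
  mapped$origin <- rep("mapped_repeat", nrow(mapped))
  lost <- NULL
  if (!is.null(lost_repeat_hits) && nrow(lost_repeat_hits)) {
    lost <- lost_repeat_hits |>
      dplyr::count(.data$class, .data$family, .data$ref_id, name = "count") |>
      dplyr::rename(name = "ref_id") |>
      dplyr::mutate(origin = "lost_repeat")
  }
  dplyr::bind_rows(mapped, lost)
}

finalize_result <- function(reads, assign_tbl, extras, config) {
  n_total <- nrow(reads)
  counts <- table(factor(assign_tbl$category, levels = ROP_CATEGORIES))
  categories <- tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    percentage = if (n_total > 0) 100 * as.integer(counts) / n_total else 0)
  profile <- structure(list(
    sample_id = config$sample_id,
    total_reads = n_total,
    categories = categories,
    genomic_subcategories = extras$genomic_subcategories %||%
      tibble::tibble(subcategory = character(), count = integer()),
    repeat_counts = extras$repeat_counts %||%
      tibble::tibble(class = character(), family = character(),
                     name = character(), count = integer(),
                     origin = character()),
    immune_locus_counts = extras$immune_locus_counts %||%
      tibble::tibble(locus = character(), segment_type = character(),
                     name = character(), count = integer()),
    ncl_subtype_counts = if (!is.null(extras$ncl_reads) &&
                               nrow(extras$ncl_reads)) {
      dplyr::count(extras$ncl_reads, .data$subtype, name = "count")
    } else tibble::tibble(subtype = character(), count = integer()),
    vj_matrix = vj_matrix(extras$vj_events %||%
                            tibble::tibble(read_id = character(),
                                           locus = character(),
                                           v_gene = character(),
                                           j_gene = character())),
    taxon_profile = extras$taxon_profile %||%
      tibble::tibble(rank = character(), taxon = character(),
                     count = integer(), relative_abundance = numeric())
  ), class = "rop_profile")
  structure(list(
    assignments = assign_tbl, profile = profile,
    ncl_events = extras$ncl_events, vj_events = extras$vj_events,
    taxon_profile = extras$taxon_profile,
    microbial_assignments = extras$microbial_assignments,
    config = config
  ), class = "rop_result")
}

#' Step-order permutation experiment
#'
#' Runs the protocol twice on identical input with two step orders and
#' cross-tabulates the per-read categories, exposing reclassifications
#' caused by cross-compartment homology (identical orders, or any order on
#' a fully separable bundle, give a diagonal matrix).
#'
#' @param reads Read tibble.
#' @param bundle Reference bundle.
#' @param config Pipeline configuration (order 1 = `config$step_order`).
#' @param swapped_order Alternative step order.
#' @return List with `flow` (category flow matrix, rows = order 1), and
#'   the two `rop_result`s.
#' @export
order_experiment <- function(reads, bundle, config = rop_config(),
                             swapped_order) {
  cfg2 <- config
  cfg2$step_order <- swapped_order
  if (!setequal(swapped_order, ROP_STEPS)) {
    stop("swapped_order must be a permutation of the seven steps")
  }
  r1 <- rop_run(reads, bundle, config)
  r2 <- rop_run(reads, bundle, cfg2)
  f1 <- factor(r1$assignments$category, levels = ROP_CATEGORIES)
  f2 <- factor(r2$assignments$category[
    match(r1$assignments$read_id, r2$assignments$read_id)],
    levels = ROP_CATEGORIES)
  list(flow = unclass(table(order1 = f1, order2 = f2)),
       result1 = r1, result2 = r2)
}
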