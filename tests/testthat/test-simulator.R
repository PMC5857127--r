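test_that("identical configurations give byte-identical bundles and reads", {
  cfg <- sim_config(seed = 9, n_reads = c(transcriptomic = 30,
                                          microbial = 20, immune_vj = 10))
  b1 <- build_references(cfg)
  b2 <- build_references(cfg)
  expect_identical(b1$host_genome, b2$host_genome)
  expect_identical(b1$microbial_genomes, b2$microbial_genomes)
  expect_identical(b1$rdna_unit, b2$rdna_unit)
  s1 <- simulate_reads(b1, cfg)
  s2 <- simulate_reads(b2, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("read counts and truth labels are conserved", {
  cfg <- fx_config()
  sim <- fx_sim()
  expect_equal(nrow(sim$reads), sum(cfg$n_reads))
  expect_equal(nrow(sim$truth), nrow(sim$reads))
  expect_false(anyDuplicated(sim$truth$read_id) > 0)
  expect_equal(as.list(table(sim$truth$class)[names(cfg$n_reads)]),
               as.list(cfg$n_reads[names(cfg$n_reads)]),
               ignore_attr = TRUE)
  expect_true(all(nchar(sim$reads$sequence) == cfg$read_length))
  expect_true(all(nchar(sim$reads$quality) == cfg$read_length))
})

test_that("bundle construction honours its contracts", {
  b <- fx_bundle()
  ann <- b$host_annotation
  genes <- ann[ann$kind == "gene", ]
  expect_equal(nrow(genes), 10)
  for (g in genes$gene_id) {
    expect_gte(sum(ann$kind == "CDS" & ann$gene_id == g), 1)
  }
  # planted repeat copies are annotated and inside chromosomes
  expect_true(all(b$repeat_annotation$end <=
                    nchar(b$host_genome[b$repeat_annotation$chrom])))
  # one repeat family stays out of the host genome
  expect_true("SVASim" %in% b$repeat_consensus$name)
  expect_false("SVASim" %in% b$repeat_annotation$name)
})

test_that("microbial genomes share no seed k-mer with host compartments", {
  b <- fx_bundle()
  k <- fx_config()$k_reject
  # brute-force k-mer set intersection, independent of the index code
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  host_k <- unique(c(unlist(lapply(b$host_genome, kmers)),
                     kmers(b$rdna_unit)))
  host_k <- unique(c(host_k, vapply(host_k, function(x)
    readorigin::revcomp(x), character(1), USE.NAMES = FALSE)))
  for (g in b$microbial_genomes) {
    expect_equal(length(intersect(kmers(g), host_k)), 0)
  }
})

test_that("error-free transcriptomic reads are exact transcript substrings", {
  cfg <- sim_config(seed = 9, base_error_rate = 0,
                    n_reads = c(transcriptomic = 40))
  b <- build_references(cfg)
  sim <- simulate_reads(b, cfg)
  for (i in seq_len(nrow(sim$reads))) {
    tx <- b$transcript_seqs[[sim$truth$source_ref[i]]]
    expect_true(grepl(sim$reads$sequence[i], tx, fixed = TRUE))
  }
})

test_that("hyper-edited construction records every converted position", {
  cfg <- sim_config(seed = 9, base_error_rate = 0,
                    n_reads = c(hyper_edited = 20))
  b <- build_references(cfg)
  sim <- simulate_reads(b, cfg)
  sensitive <- sensitive_budget(aligner_config(), cfg$read_length)
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    pos <- as.integer(strsplit(tr$edited_positions, ",")[[1]])
    expect_equal(length(pos), tr$n_edits)
    # dense enough to exceed the sensitive remap budget, as hyper-edited
    # reads must be
    expect_gt(tr$n_edits, sensitive)
    read <- sim$reads$sequence[i]
    seq5p <- if (tr$orientation == "-") revcomp(read) else read
    src <- substring(b$transcript_seqs[[tr$source_ref]],
                     tr$source_pos + 1, tr$source_pos + cfg$read_length)
    mm <- alignment_mismatches(seq5p, src)
    expect_true(all(mm$ref_base == "A" & mm$read_base == "G"))
    expect_equal(nrow(mm), tr$n_edits)
  }
})

test_that("requesting a class without substrate is an error", {
  cfg <- fx_config()
  b <- fx_bundle()
  b_no_vj <- b
  b_no_vj$v_segments <- b$v_segments[0, ]
  cfg_vj <- sim_config(seed = 1, n_reads = c(immune_vj = 5))
  expect_error(simulate_reads(b_no_vj, cfg_vj))
  expect_error(sim_config(n_reads = c(bogus_class = 5)), "unknown")
})

test_that("the homology-stress bundle embeds the absent repeat consensus", {
  cfg <- sim_config(seed = 4, homology_stress = TRUE,
                    n_reads = c(microbial = 5))
  b <- build_references(cfg)
  sva <- b$repeat_consensus$sequence[b$repeat_consensus$name == "SVASim"]
  expect_true(grepl(sva, b$microbial_genomes[[1]], fixed = TRUE))
  # the separable bundle does not
  cfg2 <- sim_config(seed = 4, n_reads = c(microbial = 5))
  b2 <- build_references(cfg2)
  sva2 <- b2$repeat_consensus$sequence[b2$repeat_consensus$name == "SVASim"]
  expect_false(grepl(sva2, b2$microbial_genomes[[1]], fixed = TRUE))
})
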