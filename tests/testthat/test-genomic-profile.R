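mk_blocks <- function(read_id, chrom, start, end, aln_id = 1L, block = 1L,
                      n_blocks = 1L, nm = 0L, len = 100L) {
  tibble::tibble(read_id = read_id, aln_id = aln_id, chrom = chrom,
                 start = start, end = end, block = block,
                 n_blocks = n_blocks, edit_distance = nm, read_length = len)
}

toy_annotation <- function() {
  dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 1000L, end = 2400L, strand = "+",
                   kind = "gene", gene_id = "g1",
                   transcript_id = NA_character_),
    tibble::tibble(chrom = "chr1", start = 1000L, end = 1060L, strand = "+",
                   kind = "UTR5", gene_id = "g1", transcript_id = "t1"),
    tibble::tibble(chrom = "chr1", start = 1060L, end = 1200L, strand = "+",
                   kind = "CDS", gene_id = "g1", transcript_id = "t1"),
    tibble::tibble(chrom = "chr1", start = 1200L, end = 1600L, strand = "+",
                   kind = "intron", gene_id = "g1", transcript_id = "t1"),
    tibble::tibble(chrom = "chr1", start = 2300L, end = 2400L, strand = "+",
                   kind = "UTR3", gene_id = "g1", transcript_id = "t1"),
    tibble::tibble(chrom = "chrM", start = 0L, end = 3000L, strand = "+",
                   kind = "mitochondrial_contig",
                   gene_id = NA_character_, transcript_id = NA_character_))
}

test_that("feature priority resolves overlaps CDS > UTR5 > UTR3 > intron", {
  ann <- toy_annotation()
  # wholly inside CDS
  expect_equal(categorize_mapped(
    mk_blocks("r1", "chr1", 1100L, 1200L), ann)$category, "CDS")
  # straddling UTR5 and CDS -> CDS wins
  expect_equal(categorize_mapped(
    mk_blocks("r2", "chr1", 1010L, 1110L), ann)$category, "CDS")
  # UTR5 only
  expect_equal(categorize_mapped(
    mk_blocks("r3", "chr1", 1000L, 1050L), ann)$category, "UTR5")
  # UTR3 vs intron: UTR3 wins
  expect_equal(categorize_mapped(
    mk_blocks("r4", "chr1", 2250L, 2350L), ann)$category, "UTR3")
  # intron only
  expect_equal(categorize_mapped(
    mk_blocks("r5", "chr1", 1300L, 1400L), ann)$category, "intron")
})

test_that("distance rules separate intergenic from deep intergenic", {
  ann <- toy_annotation()
  near <- mk_blocks("r1", "chr1", 5000L, 5100L)    # 2.6 kb from gene
  far <- mk_blocks("r2", "chr1", 150000L, 150100L) # ~148 kb away
  expect_equal(categorize_mapped(near, ann, deep_distance = 10000)$category,
               "intergenic")
  expect_equal(categorize_mapped(far, ann, deep_distance = 10000)$category,
               "deep_intergenic")
})

test_that("multi-mapped, mitochondrial, and junction outrank features", {
  ann <- toy_annotation()
  multi <- dplyr::bind_rows(
    mk_blocks("r1", "chr1", 1100L, 1200L, aln_id = 1L),
    mk_blocks("r1", "chr1", 5000L, 5100L, aln_id = 2L))
  expect_equal(categorize_mapped(multi, ann)$category, "multi_mapped")
  expect_equal(categorize_mapped(multi, ann)$n_loci, 2L)

  mito <- mk_blocks("r2", "chrM", 100L, 200L)
  expect_equal(categorize_mapped(mito, ann)$category, "mitochondrial")

  junc <- dplyr::bind_rows(
    mk_blocks("r3", "chr1", 1150L, 1200L, block = 1L, n_blocks = 2L),
    mk_blocks("r3", "chr1", 1600L, 1650L, block = 2L, n_blocks = 2L))
  expect_equal(categorize_mapped(junc, ann)$category, "junction")
})

test_that("repeat profile uses the 50%-of-read overlap rule", {
  rep_ann <- tibble::tibble(chrom = "chr1", start = 500L, end = 800L,
                            strand = "+", name = "AluY", class = "SINE",
                            family = "Alu")
  inside <- mk_blocks("r1", "chr1", 550L, 650L)
  edge <- mk_blocks("r2", "chr1", 760L, 860L)   # 40% overlap
  none <- mk_blocks("r3", "chr1", 2000L, 2100L)
  rp <- repeat_profile(dplyr::bind_rows(inside, edge, none), rep_ann)
  expect_equal(rp$assignments$read_id, "r1")
  expect_equal(rp$counts$name, "AluY")
  expect_equal(rp$counts$count, 1L)
})

test_that("class relative abundance reproduces the 33% worked form", {
  rep_ann <- tibble::tibble(
    chrom = "chr1", start = c(0L, 10000L), end = c(5000L, 15000L),
    strand = "+", name = c("AluY", "L1HS"), class = c("SINE", "LINE"),
    family = c("Alu", "L1"))
  blocks <- dplyr::bind_rows(
    mk_blocks(sprintf("a%02d", 1:33), "chr1", 100L, 200L),
    mk_blocks(sprintf("l%02d", 1:67), "chr1", 10100L, 10200L))
  rp <- repeat_profile(blocks, rep_ann)
  ab <- rp$class_abundance
  expect_equal(ab$relative_abundance[ab$class == "SINE"], 33)
  expect_equal(sum(ab$relative_abundance), 100)
})

test_that("immune segment counting drops ambiguous reads", {
  loci <- tibble::tibble(
    chrom = "chr2", start = c(1000L, 1100L), end = c(1090L, 1200L),
    strand = "+", segment_type = c("V", "J"), name = c("IGKV1", "IGKJ1"),
    locus = "IGK")
  inside <- mk_blocks("r1", "chr2", 1010L, 1080L)
  spanning <- mk_blocks("r2", "chr2", 1050L, 1150L)  # touches V and J
  away <- mk_blocks("r3", "chr2", 5000L, 5100L)
  cnt <- count_immune_locus_overlap(
    dplyr::bind_rows(inside, spanning, away), loci)
  expect_equal(cnt$name, "IGKV1")
  expect_equal(cnt$count, 1L)
})
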