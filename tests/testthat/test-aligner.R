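test_that("k-mer index reports positions and rejects degenerate input", {
  idx <- build_index(c(s = "ACGTACGT"), 4)
  hits <- .cpp_kmer_hit_positions(idx$ptr, "ACGT")
  expect_equal(hits, 0L)  # query has one k-mer, present
  expect_equal(shared_kmer_count(idx, "ACGTACGT"), 5L)
  expect_equal(shared_kmer_count(idx, "TTTTTTTT"), 0L)

  expect_error(build_index(c(s = "NNNNNNNNNN"), 4), NA)
  idx_n <- build_index(c(s = "NNNNNNNNNN"), 4)
  expect_equal(shared_kmer_count(idx_n, "ACGT"), 0L)

  expect_error(build_index(c(s = "ACG"), 16), "length")
})

test_that("exact reads align with zero edit distance at the planted locus", {
  ref <- random_seq(1500, seed = 1)
  read <- substring(ref, 301, 400)
  idx <- build_index(c(r = ref), 16)
  hits <- align_reads(read, idx, 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$ref_start, 300)
  expect_equal(hits$edit_distance, 0)
  expect_equal(hits$cigar, "100M")
  expect_equal(hits$score, 100)
})

test_that("edit budget is a hard boundary", {
  ref <- random_seq(1500, seed = 2)
  read <- mutate_positions(substring(ref, 501, 600), c(10, 50, 90), seed = 3)
  idx <- build_index(c(r = ref), 16)
  expect_equal(nrow(align_reads(read, idx, 2)), 0)
  hits <- align_reads(read, idx, 3)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$edit_distance[1], 3)
  expect_equal(hits$ref_start[1], 500)
})

test_that("identical repeated loci are both reported with deterministic order", {
  unit <- random_seq(120, seed = 4)
  ref <- paste0(random_seq(200, seed = 5), unit, random_seq(200, seed = 6),
                unit, random_seq(100, seed = 7))
  idx <- build_index(c(r = ref), 16)
  read <- substring(unit, 11, 110)
  hits <- align_reads(read, idx, 0)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$ref_start, c(210, 530))
  expect_identical(align_reads(read, idx, 0), hits)  # repeat call identical
})

test_that("alignment set equals the exhaustive DP oracle on planted cases", {
  set.seed(11)
  for (case in 1:6) {
    ref <- random_seq(800 + 200 * case)
    start <- sample(200:400, 1)
    read <- substring(ref, start, start + 99)
    budget <- case %% 4
    if (budget > 0) {
      read <- mutate_positions(read, sample(100, budget))
    }
    if (case %% 2 == 0) read <- revcomp(read)
    expect_matches_oracle(read, ref, budget)
  }
  # random unrelated read: both sides empty
  expect_matches_oracle(random_seq(100), random_seq(1000), 3)
})

test_that("seed pigeonhole bound guarantees discovery of adversarial edits", {
  # e edits spread to break long exact stretches; L >= (e+1)k + e
  ref <- random_seq(2000, seed = 20)
  k <- 16
  for (e in 1:3) {
    len <- (e + 1) * k + e + 10
    read <- substring(ref, 701, 700 + len)
    pos <- round(seq(len / (e + 1), len, length.out = e))  # evenly spread
    read <- mutate_positions(read, pos, seed = 30 + e)
    idx <- build_index(c(r = ref), k)
    hits <- align_reads(read, idx, e)
    expect_true(700 %in% hits$ref_start)
    expect_equal(min(hits$edit_distance), e)
  }
})

test_that("split alignment recovers two-segment chimeras with coordinates", {
  chrA <- random_seq(3000, seed = 40)
  chrB <- random_seq(3000, seed = 41)
  idx <- build_index(c(chrA = chrA, chrB = chrB), 16)
  read <- paste0(substring(chrA, 1001, 1050), substring(chrB, 2001, 2050))
  seg <- split_align_reads(read, idx, 10)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$ref_id, c("chrA", "chrB"))
  expect_equal(seg$ref_start, c(1000, 2000))
  expect_equal(seg$ref_end, c(1050, 2050))
  expect_equal(seg$read_start, c(0, 50))
  expect_equal(seg$read_end, c(50, 100))
  expect_equal(seg$total_edit_distance, c(0, 0))
})

test_that("head-to-tail split places the second segment upstream", {
  chr <- random_seq(5000, seed = 50)
  idx <- build_index(c(chr = chr), 16)
  # downstream block first on the read (back-splice geometry)
  read <- paste0(substring(chr, 2951, 3000), substring(chr, 1001, 1050))
  seg <- split_align_reads(read, idx, 10)
  expect_equal(nrow(seg), 2)
  expect_lt(seg$ref_end[2], seg$ref_start[1])
  expect_equal(seg$ref_start, c(2950, 1000))
})

test_that("contiguously alignable reads are not the split caller's concern", {
  # precondition in the pipeline: split alignment is only invoked on reads
  # failing contiguous alignment; a split of a contiguous read, if any,
  # reconstructs the contiguous placement
  chr <- random_seq(3000, seed = 60)
  idx <- build_index(c(chr = chr), 16)
  read <- substring(chr, 501, 600)
  seg <- split_align_reads(read, idx, 5)
  if (nrow(seg)) {
    expect_equal(seg$ref_start[1], 500)
    expect_equal(seg$ref_end[2], 600)
  }
  expect_equal(nrow(align_reads(read, idx, 0)), 1)
})

test_that("reverse-complement reads are found on the minus strand", {
  ref <- random_seq(1500, seed = 70)
  read <- revcomp(substring(ref, 401, 500))
  idx <- build_index(c(r = ref), 16)
  hits <- align_reads(read, idx, 0)
  expect_equal(hits$strand, "-")
  expect_equal(hits$ref_start, 400)
})
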