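test_that("low-quality rule is inclusive at the 75% boundary", {
  # 75 of 100 bases below Q30 -> excluded ("at least" is inclusive)
  q <- int_to_phred(c(rep(20L, 75), rep(40L, 25)))
  expect_true(is_low_quality(q))
  expect_false(is_low_quality(int_to_phred(rep(40L, 100))))
  # 74 low bases stays in
  expect_false(is_low_quality(int_to_phred(c(rep(20L, 74), rep(40L, 26)))))
  # short read: 3/4 = 75% exactly
  expect_true(is_low_quality(int_to_phred(c(29L, 29L, 29L, 40L))))
  # Q29 counts as low, Q30 does not
  expect_true(is_low_quality(int_to_phred(rep(29L, 4))))
  expect_false(is_low_quality(int_to_phred(rep(30L, 4))))
})

test_that("raising base qualities never creates a low-quality call", {
  set.seed(77)
  for (i in 1:20) {
    q <- sample(2:41, 60, replace = TRUE)
    base <- is_low_quality(int_to_phred(q))
    bump <- q
    up <- sample(60, 10)
    bump[up] <- pmin(bump[up] + sample(1:20, 10, replace = TRUE), 41L)
    if (!base) expect_false(is_low_quality(int_to_phred(bump)))
  }
})

test_that("low-complexity rule catches repetitive runs, spares random reads", {
  expect_true(is_low_complexity(strrep("A", 10)))
  expect_true(is_low_complexity(strrep("AC", 50)))
  set.seed(5)
  for (i in 1:10) expect_false(is_low_complexity(random_seq(100)))
  # entropy of an alternating dinucleotide read is just under 1 bit
  ent <- readorigin:::dinucleotide_entropy(strrep("AC", 50))
  expect_lt(ent, 1)
  expect_gt(ent, 0.99)
})

test_that("rDNA filter partitions reads by identity to the unit", {
  b <- fx_bundle()
  idx <- build_index(c(rdna = b$rdna_unit), 16)
  exact <- tibble::tibble(read_id = "rd1",
                          sequence = substring(b$rdna_unit, 101, 200),
                          quality = strrep("I", 100))
  micro <- tibble::tibble(read_id = "mb1",
                          sequence = substring(b$microbial_genomes[1], 1001,
                                               1100),
                          quality = strrep("I", 100))
  # ~50% identity: half rDNA, half random
  half <- tibble::tibble(read_id = "h1",
                         sequence = paste0(substring(b$rdna_unit, 1, 50),
                                           random_seq(50, seed = 8)),
                         quality = strrep("I", 100))
  part <- filter_rdna(dplyr::bind_rows(exact, micro, half), idx)
  expect_equal(part$rdna$read_id, "rd1")
  expect_setequal(part$passed$read_id, c("mb1", "h1"))
})

test_that("QC yields an exact partition in fixed evaluation order", {
  reads <- fx_sim()$reads
  b <- fx_bundle()
  idx <- build_index(c(rdna = b$rdna_unit), 16)
  part <- run_qc(reads, idx)
  ids <- c(part$low_quality$read_id, part$low_complexity$read_id,
           part$rdna$read_id, part$passed$read_id)
  expect_setequal(ids, reads$read_id)
  expect_equal(length(ids), nrow(reads))  # disjoint
  # planted low-quality reads are all caught (the rule is definitional)
  lq_truth <- fx_sim()$truth$read_id[fx_sim()$truth$class == "low_quality"]
  expect_true(all(lq_truth %in% part$low_quality$read_id))
  # no clean planted class is called low-quality
  expect_equal(setdiff(part$low_quality$read_id, lq_truth), character())
})
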