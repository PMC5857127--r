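test_that("base transformation is a total idempotent map", {
  expect_equal(transform_bases("ACAGA", "A", "G"), "GCGGG")
  expect_equal(transform_bases("CCTT", "A", "G"), "CCTT")
  x <- random_seq(200, seed = 1)
  expect_equal(transform_bases(transform_bases(x)), transform_bases(x))
  expect_equal(nchar(transform_bases(x)), 200)
})

# genome + read with exactly n clustered A->G conversions
planted_case <- function(n_edit, seed = 2, len = 100) {
  set.seed(seed)
  repeat {
    genome <- c(chr = random_seq(4000))
    frag <- substring(genome[["chr"]], 1001, 1000 + len)
    a_pos <- which(strsplit(frag, "")[[1]] == "A")
    a_in <- a_pos[a_pos >= 10 & a_pos <= 70]  # clustered window
    if (length(a_in) >= n_edit) break
  }
  edited <- sort(sample(a_in, n_edit))
  ch <- strsplit(frag, "")[[1]]
  ch[edited] <- "G"
  list(genome = genome,
       reads = tibble::tibble(read_id = "r1",
                              sequence = paste(ch, collapse = ""),
                              quality = strrep("I", len)),
       edited = edited)
}

test_that("the >5%-of-length threshold is strict at the boundary", {
  five <- planted_case(5)
  expect_equal(nrow(detect_hyper_editing(five$reads, five$genome)), 0)
  six <- planted_case(6)
  hit <- detect_hyper_editing(six$reads, six$genome)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_sub, 6L)
  expect_equal(hit$mismatch_fraction, 0.06)
  expect_equal(as.integer(strsplit(hit$positions, ",")[[1]]), six$edited)
})

test_that("clean reads and reverse-orientation edits behave correctly", {
  case <- planted_case(10, seed = 3)
  clean <- tibble::tibble(read_id = "c1",
                          sequence = substring(case$genome[["chr"]], 2001,
                                               2100),
                          quality = strrep("I", 100))
  expect_equal(nrow(detect_hyper_editing(clean, case$genome)), 0)
  # the same edited fragment sampled from the opposite strand
  rc <- case$reads
  rc$sequence <- revcomp(rc$sequence)
  hit <- detect_hyper_editing(rc, case$genome)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "-")
  expect_equal(hit$n_sub, 10L)
})

test_that("recovered mismatches self-check against direct comparison", {
  case <- planted_case(8, seed = 4)
  hit <- detect_hyper_editing(case$reads, case$genome)
  win <- substring(case$genome[["chr"]], hit$ref_start + 1,
                   hit$ref_start + 100)
  mm <- alignment_mismatches(case$reads$sequence, win)
  expect_equal(sum(mm$ref_base == "A" & mm$read_base == "G"), hit$n_sub)
  expect_equal(nrow(mm), hit$n_sub + hit$n_other)
})

test_that("detection is invariant under read order", {
  sim <- fx_sim()
  he <- sim$reads[sim$reads$truth_label == "hyper_edited", ][1:10, ]
  b <- fx_bundle()
  refs <- c(b$host_genome,
            stats::setNames(b$transcript_seqs,
                            paste0("tx|", names(b$transcript_seqs))))
  h1 <- detect_hyper_editing(he, refs)
  h2 <- detect_hyper_editing(he[rev(seq_len(nrow(he))), ], refs)
  expect_setequal(h1$read_id, h2$read_id)
  expect_equal(dplyr::arrange(h1, .data$read_id),
               dplyr::arrange(h2, .data$read_id))
})

test_that("planted clustered edits are recalled on simulator output", {
  sim <- fx_sim()
  truth <- sim$truth
  b <- fx_bundle()
  refs <- c(b$host_genome,
            stats::setNames(b$transcript_seqs,
                            paste0("tx|", names(b$transcript_seqs))))
  he_ids <- truth$read_id[truth$class == "hyper_edited"]
  hits <- detect_hyper_editing(sim$reads[sim$reads$read_id %in% he_ids, ],
                               refs)
  expect_gte(nrow(hits) / length(he_ids), 0.95)
  # no false positives on clean (unedited, host-mappable) reads
  clean_ids <- truth$read_id[truth$class == "transcriptomic"][1:100]
  fp <- detect_hyper_editing(sim$reads[sim$reads$read_id %in% clean_ids, ],
                             refs)
  expect_equal(nrow(fp), 0)
})

test_that("control table is dominated by the planted substitution type", {
  # symmetric check with planted C->T editing on a toy genome
  set.seed(9)
  genome <- c(chr = random_seq(6000))
  reads <- list()
  for (i in 1:12) {
    repeat {
      s <- sample(5000, 1)
      frag <- substring(genome[["chr"]], s, s + 99)
      cpos <- which(strsplit(frag, "")[[1]] == "C")
      cin <- cpos[cpos >= 10 & cpos <= 75]
      if (length(cin) >= 8) break
    }
    ch <- strsplit(frag, "")[[1]]
    ch[sort(sample(cin, 8))] <- "T"
    reads[[i]] <- tibble::tibble(read_id = paste0("e", i),
                                 sequence = paste(ch, collapse = ""),
                                 quality = strrep("I", 100))
  }
  ctrl <- hyper_editing_controls(dplyr::bind_rows(reads), genome)
  ua <- ctrl$unique_assignment
  expect_equal(ua$from[which.max(ua$unique_hits)], "C")
  expect_equal(ua$to[which.max(ua$unique_hits)], "T")
  expect_gte(ua$fraction[ua$from == "C" & ua$to == "T"], 0.95)
  # no edits planted -> empty control table
  none <- tibble::tibble(read_id = "n1", sequence = random_seq(100),
                         quality = strrep("I", 100))
  ctrl0 <- hyper_editing_controls(none, genome)
  expect_equal(sum(ctrl0$directed$hits), 0)
})
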