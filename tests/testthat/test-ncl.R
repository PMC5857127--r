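mk_segments <- function(read_id, ref1, s1, e1, ref2, s2, e2,
                        strand = c("+", "+")) {
  tibble::tibble(read_id = read_id, segment = 1:2,
                 ref_id = c(ref1, ref2), strand = strand,
                 ref_start = c(s1, s2), ref_end = c(e1, e2),
                 read_start = c(0L, 50L), read_end = c(50L, 100L),
                 total_edit_distance = 0L)
}

ncl_ann <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 2000000L, 5000L),
    end = c(3000L, 2002000L, 7000L),
    strand = "+", kind = "gene", gene_id = c("gA", "gB", "gC"),
    transcript_id = NA_character_)
}

test_that("split geometry maps onto the three NCL subtypes", {
  ann <- ncl_ann()
  # different chromosomes -> fusion
  fus <- classify_split(mk_segments("r1", "chr1", 1500L, 1550L,
                                    "chr2", 5500L, 5550L), ann)
  expect_equal(fus$subtype, "fusion")
  # head-to-tail within one gene -> circRNA
  circ <- classify_split(mk_segments("r2", "chr1", 2500L, 2550L,
                                     "chr1", 1200L, 1250L), ann)
  expect_equal(circ$subtype, "circRNA")
  expect_equal(circ$pos_a, 2550L)
  expect_equal(circ$pos_b, 1200L)
  # co-linear, different genes, ~2 Mb apart -> trans-splicing
  tr <- classify_split(mk_segments("r3", "chr1", 1500L, 1550L,
                                   "chr1", 2000100L, 2000150L), ann)
  expect_equal(tr$subtype, "trans_splicing")
  # co-linear short-range within one gene -> none (ordinary splicing)
  none <- classify_split(mk_segments("r4", "chr1", 1200L, 1250L,
                                     "chr1", 1800L, 1850L), ann)
  expect_equal(none$subtype, "none")
})

test_that("classification is total over geometric configurations", {
  ann <- ncl_ann()
  combos <- expand.grid(
    chrom2 = c("chr1", "chr2"),
    order = c("colinear", "reversed"),
    strand2 = c("+", "-"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    s2 <- if (combos$order[i] == "colinear") 2500L else 1100L
    seg <- mk_segments("r", "chr1", 2000L, 2050L,
                       combos$chrom2[i], s2, s2 + 50L,
                       strand = c("+", combos$strand2[i]))
    got <- classify_split(seg, ann)
    expect_equal(nrow(got), 1)
    expect_true(got$subtype %in% c("fusion", "circRNA", "trans_splicing",
                                   "none"))
  }
})

test_that("minus-strand split reads normalise to the same junction", {
  ann <- ncl_ann()
  plus <- mk_segments("p", "chr1", 2500L, 2550L, "chr1", 1200L, 1250L)
  minus <- mk_segments("m", "chr1", 1200L, 1250L, "chr1", 2500L, 2550L,
                       strand = c("-", "-"))
  cp <- classify_split(plus, ann)
  cm <- classify_split(minus, ann)
  expect_equal(cm$subtype, "circRNA")
  expect_equal(cm$pos_a, cp$pos_a)
  expect_equal(cm$pos_b, cp$pos_b)
})

test_that("event aggregation applies the strict >1-read filter", {
  ann <- ncl_ann()
  reads <- dplyr::bind_rows(
    mk_segments("r1", "chr1", 2500L, 2550L, "chr1", 1200L, 1250L),
    mk_segments("r2", "chr1", 2497L, 2550L, "chr1", 1202L, 1252L),
    mk_segments("r3", "chr1", 2500L, 2553L, "chr1", 1200L, 1250L),
    mk_segments("s1", "chr1", 2700L, 2750L, "chr1", 1400L, 1450L))
  cl <- classify_split(reads, ann)
  ev <- aggregate_ncl_events(cl)
  expect_equal(nrow(ev), 2)
  three <- ev[ev$support == 3, ]
  expect_true(three$reported)
  one <- ev[ev$support == 1, ]
  expect_false(one$reported)  # 1 > 1 is false: strict threshold
  # breakpoints 100 bp apart are never merged
  expect_equal(sort(ev$pos_a), c(2550L, 2750L))
})

test_that("aggregation is invariant under read order", {
  ann <- ncl_ann()
  reads <- dplyr::bind_rows(lapply(1:6, function(i)
    mk_segments(paste0("r", i), "chr1", 2500L, 2550L,
                "chr1", 1200L, 1250L)))
  cl <- classify_split(reads, ann)
  e1 <- aggregate_ncl_events(cl)
  e2 <- aggregate_ncl_events(cl[rev(seq_len(nrow(cl))), ])
  expect_equal(e1, e2)
  expect_equal(e1$support, 6L)
})
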