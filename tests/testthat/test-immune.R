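toy_segments <- function() {
  set.seed(31)
  v <- tibble::tibble(
    name = c("IGKV1", "IGKV2", "IGLV1"),
    locus = c("IGK", "IGK", "IGL"),
    sequence = vapply(c(280, 280, 280), random_seq, character(1)))
  j <- tibble::tibble(
    name = c("IGKJ1", "IGLJ1"),
    locus = c("IGK", "IGL"),
    sequence = vapply(c(60, 60), random_seq, character(1)))
  list(v = v, j = j)
}

vj_read <- function(segs, v = "IGKV1", j = "IGKJ1", vo = 40, ins = 10,
                    id = "r1", rc = FALSE) {
  vs <- segs$v$sequence[segs$v$name == v]
  js <- segs$j$sequence[segs$j$name == j]
  seq <- paste0(substring(vs, nchar(vs) - vo + 1),
                paste(rep("A", ins), collapse = ""),
                substring(js, 1, 100 - vo - ins))
  if (rc) seq <- readorigin::revcomp(seq)
  tibble::tibble(read_id = id, sequence = seq, quality = strrep("I", 100))
}

test_that("junction-spanning reads are detected with the right (V, J)", {
  segs <- toy_segments()
  ev <- detect_vj(vj_read(segs), segs$v, segs$j)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$locus, "IGK")
  expect_equal(ev$v_gene, "IGKV1")
  expect_equal(ev$j_gene, "IGKJ1")
  expect_equal(ev$v_overlap, 40L)
  expect_equal(ev$j_overlap, 50L)
  expect_equal(ev$insert_length, 10L)
  expect_equal(ev$orientation, "+")
})

test_that("insufficient segment overlap is a miss, as in real short reads", {
  segs <- toy_segments()
  short <- vj_read(segs, vo = 12, ins = 10)  # V side below 20 bp
  expect_equal(nrow(detect_vj(short, segs$v, segs$j)), 0)
})

test_that("V and J must come from the same locus", {
  segs <- toy_segments()
  cross <- vj_read(segs, v = "IGKV1", j = "IGLJ1")
  expect_equal(nrow(detect_vj(cross, segs$v, segs$j)), 0)
})

test_that("reverse-complement junction reads are reported in V-J orientation", {
  segs <- toy_segments()
  ev <- detect_vj(vj_read(segs, rc = TRUE), segs$v, segs$j)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$v_gene, "IGKV1")
  expect_equal(ev$orientation, "-")
})

test_that("mismatch tolerance admits hypermutated segments up to the rate", {
  segs <- toy_segments()
  rd <- vj_read(segs, vo = 40, ins = 10)
  # 3 mismatches in the 40-bp V portion: 7.5% <= 10%
  rd$sequence <- mutate_positions(rd$sequence, c(5, 15, 25), seed = 7)
  ev <- detect_vj(rd, segs$v, segs$j)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$v_mismatch, 3L)
  # 6 mismatches: 15% > 10% on the full overlap; a shorter overlap cannot
  # rescue it below min_segment_overlap
  rd2 <- vj_read(segs, vo = 30, ins = 20)
  rd2$sequence <- mutate_positions(rd2$sequence, c(2, 7, 12, 17, 22, 27),
                                   seed = 8)
  expect_equal(nrow(detect_vj(rd2, segs$v, segs$j)), 0)
})

test_that("VJ matrices count combinations and cross-sample support", {
  ev <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    read_id = paste0("r", 1:4),
    locus = "IGK",
    v_gene = c("V1", "V1", "V2", "V9"),
    j_gene = c("J1", "J1", "J1", "J9"))
  m <- vj_matrix(ev)
  expect_equal(sum(m$counts$count), 4)
  expect_equal(m$counts$count[m$counts$v_gene == "V1"], 2L)
  # V1-J1 seen in 1 of 2 samples
  expect_equal(m$sample_support$support[m$sample_support$v_gene == "V1"],
               0.5)
  empty <- vj_matrix(ev[0, ])
  expect_equal(nrow(empty$counts), 0)
})
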