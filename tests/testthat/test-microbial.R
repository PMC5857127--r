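test_that("exact microbial reads count at the genome and along its path", {
  b <- fx_bundle()
  idx <- build_index(b$microbial_genomes, 16)
  rd <- tibble::tibble(read_id = "m1",
                       sequence = substring(b$microbial_genomes[[1]], 501,
                                            600),
                       quality = strrep("I", 100))
  res <- assign_microbial(rd, idx, b$microbial_taxa)
  expect_equal(res$assignments$genome, names(b$microbial_genomes)[1])
  expect_equal(res$microbial_load, 1L)
  path <- strsplit(b$microbial_taxa$taxon_path[1], ";")[[1]]
  expect_true(all(path %in% res$profile$taxon))
  expect_equal(res$profile$relative_abundance,
               rep(100, nrow(res$profile)))
})

test_that("equal ties across species resolve to their common ancestor", {
  set.seed(21)
  shared <- random_seq(400)
  g <- c(sp1 = paste0(shared, random_seq(600)),
         sp2 = paste0(shared, random_seq(600)))
  taxa <- tibble::tibble(
    genome = c("sp1", "sp2"),
    taxon_path = c("Bacteria;PhyX;ClsX;OrdX;FamX;GenX;SpX1",
                   "Bacteria;PhyX;ClsX;OrdX;FamX;GenX;SpX2"))
  idx <- build_index(g, 16)
  rd <- tibble::tibble(read_id = "t1", sequence = substring(shared, 101, 200),
                       quality = strrep("I", 100))
  res <- assign_microbial(rd, idx, taxa)
  expect_true(is.na(res$assignments$genome))
  expect_equal(res$assignments$lca, "Bacteria;PhyX;ClsX;OrdX;FamX;GenX")
  # counted at the LCA rank (genus) and above, not at species
  expect_false("species" %in% res$profile$rank)
  expect_equal(res$profile$count[res$profile$rank == "genus"], 1L)
})

test_that("host reads stay unassigned on the separable bundle", {
  b <- fx_bundle()
  idx <- build_index(b$microbial_genomes, 16)
  host <- tibble::tibble(
    read_id = c("h1", "h2"),
    sequence = c(substring(b$host_genome[["chr1"]], 2001, 2100),
                 b$transcript_seqs[[1]] |> substring(101, 200)),
    quality = strrep("I", 100))
  res <- assign_microbial(host, idx, b$microbial_taxa)
  expect_equal(res$microbial_load, 0L)
})

test_that("rank sums never exceed the microbial load", {
  b <- fx_bundle()
  idx <- build_index(b$microbial_genomes, 16)
  sim <- fx_sim()
  mb <- sim$reads[sim$reads$truth_label == "microbial", ]
  res <- assign_microbial(mb, idx, b$microbial_taxa)
  sums <- tapply(res$profile$count, res$profile$rank, sum)
  expect_true(all(sums <= res$microbial_load))
  # every path reaches species here, so equality holds at each rank
  expect_true(all(sums == res$microbial_load))
})

test_that("coverage breadth reflects placed reads only", {
  a <- tibble::tibble(read_id = "r1", genome = "g", lca = NA_character_,
                      ref_start = 0L, ref_end = 100L, edit_distance = 0L)
  cov <- coverage_profile(a, "g", 1000L)
  expect_equal(cov$breadth, 0.1)
  expect_equal(coverage_profile(a[0, ], "g", 1000L)$breadth, 0)
  tiling <- tibble::tibble(read_id = paste0("r", 1:10), genome = "g",
                           lca = NA_character_,
                           ref_start = seq(0L, 900L, 100L),
                           ref_end = seq(100L, 1000L, 100L),
                           edit_distance = 0L)
  expect_equal(coverage_profile(tiling, "g", 1000L)$breadth, 1)
})

test_that("an empty microbial reference set is an error", {
  rd <- tibble::tibble(read_id = "r", sequence = random_seq(100),
                       quality = strrep("I", 100))
  fake_idx <- list(names = character(), k = 16L, lengths = integer())
  expect_error(assign_microbial(rd, fake_idx, tibble::tibble()), "empty")
})
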