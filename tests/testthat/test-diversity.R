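test_that("richness counts distinct events", {
  expect_equal(richness(c(a = 5, b = 1)), 2)
  expect_equal(richness(numeric()), 0)
  expect_equal(richness(c(a = 1000)), 1)
})

test_that("Shannon index matches closed forms and hand evaluation", {
  expect_equal(shannon_index(rep(5, 4)), 2)          # log2(4)
  expect_equal(shannon_index(c(a = 7)), 0)
  expect_equal(shannon_index(numeric()), 0)
  expect_equal(shannon_index(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(shannon_index(c(3, 1)), 0.8112781, tolerance = 1e-7)
})

test_that("Shannon agrees with vegan and is bounded by log2 richness", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:10) {
    counts <- sample(1:50, sample(2:12, 1), replace = TRUE)
    expect_equal(shannon_index(counts),
                 unname(vegan::diversity(counts, index = "shannon")) /
                   log(2),
                 tolerance = 1e-10)
    expect_lte(shannon_index(counts), log2(length(counts)) + 1e-12)
    # scale invariance
    expect_equal(shannon_index(counts), shannon_index(counts * 7))
    # permutation invariance
    expect_equal(shannon_index(counts), shannon_index(rev(counts)))
  }
  expect_equal(shannon_index(rep(3, 8)), log2(8))
})

test_that("Sorensen-Dice matches the formula and its semimetric laws", {
  expect_equal(sorensen_dice(c("x", "y"), c("x", "y")), 0)
  expect_equal(sorensen_dice(c("x"), c("y")), 1)
  expect_equal(sorensen_dice(c("x", "y", "z"), c("x", "y", "w")), 1 / 3)
  expect_equal(sorensen_dice(character(), character()), 0)
  set.seed(17)
  for (i in 1:10) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    expect_equal(sorensen_dice(a, b), sorensen_dice(b, a))
    expect_gte(sorensen_dice(a, b), 0)
    expect_lte(sorensen_dice(a, b), 1)
  }
})

test_that("Sorensen-Dice agrees with vegan's binary Bray-Curtis", {
  skip_if_not_installed("vegan")
  set.seed(19)
  events <- letters[1:12]
  a <- sample(events, 7); b <- sample(events, 5)
  m <- rbind(as.integer(events %in% a), as.integer(events %in% b))
  expect_equal(sorensen_dice(a, b),
               as.numeric(vegan::vegdist(m, method = "bray",
                                         binary = TRUE)))
})

test_that("beta matrix is symmetric with zero diagonal", {
  ev <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), times = c(3, 3, 2)),
    event = c("a", "b", "c", "a", "b", "d", "e", "f"))
  m <- beta_diversity_matrix(ev)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(m["s1", "s2"],
               sorensen_dice(c("a", "b", "c"), c("a", "b", "d")))
  expect_equal(m["s1", "s3"], 1)
  ident <- beta_diversity_matrix(tibble::tibble(
    sample_id = c("x", "x", "y", "y"), event = c("a", "b", "a", "b")))
  expect_true(all(ident == 0))
})

test_that("alpha diversity table combines richness and Shannon per sample", {
  ev <- tibble::tibble(sample_id = c("s1", "s1", "s1", "s2"),
                       event = c("a", "a", "b", "c"))
  a <- alpha_diversity(ev)
  expect_equal(a$richness, c(2L, 1L))
  expect_equal(a$shannon[1], shannon_index(c(2, 1)))
  expect_equal(a$shannon[2], 0)
})

test_that("subsampling equalises sample sizes deterministically", {
  samples <- list(s1 = 1:100, s2 = 1:40, s3 = 1:70)
  sub <- subsample_to_min(samples, seed = 3)
  expect_equal(unname(lengths(sub)), c(40L, 40L, 40L))
  expect_identical(sub, subsample_to_min(samples, seed = 3))
  expect_true(all(sub$s1 %in% samples$s1))
  # already equal sizes: same multisets
  eq <- subsample_to_min(list(a = 5:1, b = 11:15), seed = 1)
  expect_setequal(eq$a, 1:5)
  expect_setequal(eq$b, 11:15)
})
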