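# CNA metrics: genotype filter, the similarity metric and its oracle,
# recurrence testing, UPGMA.

test_that("genotype filter applies the copy-number bands", {
  seg <- data.frame(
    chrom = c("7", "7", "7", "X", "8"),
    start = c(0, 2e6, 4e6, 0, 5e6),
    end = c(1e6, 3e6, 5e6, 1e6, 4e6), # last row malformed (start > end)
    tumor_cn = c(3.1, 1.0, 2.15, 3.0, 3.0),
    normal_cn = c(2.0, 1.5, 2.0, 2.0, 2.0))
  expect_message(p <- genotype_filter(seg, "s1"), "malformed")
  # Kept: only the first row (dup). Dropped: normal outside (1.75,2.25);
  # |diff| <= 0.2; chromosome X; malformed coordinates.
  expect_identical(nrow(p$segments), 1L)
  expect_identical(p$segments$state, "dup")
  expect_identical(p$segments$chrom, "7")
  # Deletions are tumor below normal.
  del <- genotype_filter(data.frame(chrom = "5", start = 0, end = 1e6,
                                    tumor_cn = 1.2, normal_cn = 2.0), "s2")
  expect_identical(del$segments$state, "del")
  # 1-based input is shifted at the boundary.
  one <- genotype_filter(data.frame(chrom = "5", start = 1, end = 1e6,
                                    tumor_cn = 3, normal_cn = 2), "s3",
                         one_based = TRUE)
  expect_identical(one$segments$start, 0)
})

test_that("chromosome similarity is the per-state Jaccard score", {
  mkprof <- function(id, chrom, start, end, state)
    cna_profile(id, data.frame(chrom = chrom, start = start, end = end,
                               state = state))
  a <- mkprof("a", "1", 0, 100, "dup")
  expect_equal(chromosome_similarity(a, a, "1"), 1)
  b <- mkprof("b", "1", 50, 150, "dup")
  expect_equal(chromosome_similarity(a, b, "1"), 1 / 3)
  expect_equal(chromosome_similarity(b, a, "1"),
               chromosome_similarity(a, b, "1"))
  # Cross-state overlap counts only toward the denominator.
  d <- mkprof("d", "1", 0, 100, "del")
  expect_equal(chromosome_similarity(a, d, "1"), 0)
  # No events on the chromosome: defined as 0.
  expect_equal(chromosome_similarity(a, b, "2"), 0)
  # Splitting an interval into adjacent pieces changes nothing.
  split <- mkprof("s", c("1", "1"), c(0, 40), c(40, 100), c("dup", "dup"))
  expect_equal(chromosome_similarity(split, b, "1"),
               chromosome_similarity(a, b, "1"))
  expect_true(chromosome_similarity(a, b, "1") >= 0 &&
                chromosome_similarity(a, b, "1") <= 1)
})

test_that("genome similarity M matches the bitmap Jaccard oracle", {
  ident <- simulate_cna_profiles("polyp", 4, seed = 11)
  expect_equal(genome_similarity(ident$polyp, ident$cancer),
               length(unique(ident$cancer$segments$chrom)))
  disj <- list(
    cna_profile("x", data.frame(chrom = "1", start = 0, end = 1e6,
                                state = "dup")),
    cna_profile("y", data.frame(chrom = "2", start = 0, end = 1e6,
                                state = "dup")))
  expect_equal(genome_similarity(disj[[1]], disj[[2]]), 0)

  set.seed(12)
  for (i in 1:25) {
    p1 <- random_cna_profile("p1")
    p2 <- random_cna_profile("p2")
    expect_equal(genome_similarity(p1, p2),
                 bitmap_genome_similarity(p1, p2), tolerance = 1e-12)
  }
})

test_that("similarity matrices are symmetric with saturated diagonal", {
  set.seed(13)
  profs <- lapply(1:4, function(i) random_cna_profile(paste0("s", i)))
  sm <- similarity_matrix(profs)
  expect_true(isSymmetric(sm$M))
  # Diagonal per-chromosome score is 1 wherever the sample has events.
  for (i in 1:4) {
    with_events <- unique(profs[[i]]$segments$chrom)
    expect_true(all(sm$per_chromosome[i, i, with_events] == 1))
  }
})

test_that("recurrence test flags an engineered chromosome", {
  g <- autosome_lengths()
  set.seed(14)
  profs <- lapply(1:8, function(i) {
    extra_chrom <- sample(setdiff(names(g), "7"), 1)
    cna_profile(paste0("s", i), data.frame(
      chrom = c("7", extra_chrom),
      start = 0,
      end = c(g[["7"]], floor(0.3 * g[[extra_chrom]])),
      state = c("dup", sample(c("del", "dup"), 1))))
  })
  res <- recurrence_test(profs)
  expect_lt(res$p_value[res$chrom == "7"], 0.01)
  expect_true(all(res$p_value[res$chrom != "7"] > 0.05))
  # Identical event sets on every chromosome: nothing stands out.
  same <- lapply(1:5, function(i) {
    cna_profile(paste0("t", i), data.frame(
      chrom = names(g), start = 0, end = floor(0.5 * unname(g)),
      state = "dup"))
  })
  res2 <- recurrence_test(same)
  expect_true(all(res2$p_value >= 0.5))
  expect_error(recurrence_test(same[1:2]), "at least 5")
  # The per-sample unit agrees on the engineered chromosome.
  res3 <- recurrence_test(profs, unit = "sample")
  expect_lt(res3$p_value[res3$chrom == "7"], 0.01)
})

test_that("UPGMA merges match a brute-force average-linkage oracle", {
  # Two identical samples merge first, at height 0.
  m <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  hc <- upgma_cluster(m, type = "distance")
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  # Random 6-leaf distance matrices against the oracle.
  set.seed(15)
  for (i in 1:10) {
    d <- matrix(0, 6, 6)
    d[upper.tri(d)] <- runif(15, 0.1, 2)
    d <- d + t(d)
    hc <- upgma_cluster(d, type = "distance")
    expect_equal(sort(hc$height), upgma_oracle_heights(d),
                 tolerance = 1e-12)
  }
  # Similarities are converted monotonically: same topology as distances.
  s <- 2 - d
  hc_s <- upgma_cluster(s, type = "similarity")
  expect_equal(hc_s$merge, upgma_cluster(d, type = "distance")$merge)
  expect_error(upgma_cluster(matrix(1:9, 3, 3)), "symmetric")
})
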