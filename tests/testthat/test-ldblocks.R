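test_that("fixed windows tile every chromosome with a short tail", {
  map <- tiny_map(100)
  bp <- fixed_blocks(map, 20)
  expect_identical(nrow(bp$blocks), 5L)
  expect_true(all(bp$blocks$end_idx - bp$blocks$start_idx + 1 == 20))

  map2 <- tiny_map(11)
  bp2 <- fixed_blocks(map2, 5)
  expect_identical(bp2$blocks$end_idx - bp2$blocks$start_idx + 1L, c(5L, 5L, 1L))

  # window 1: one block per SNP; blocks never span chromosomes
  map3 <- rbind(tiny_map(7), tiny_map(6, chrom = "chr2"))
  bp3 <- fixed_blocks(map3, 1)
  expect_identical(nrow(bp3$blocks), 13L)
  bp4 <- fixed_blocks(map3, 5)
  expect_identical(bp4$blocks$chrom, c("chr1", "chr1", "chr2", "chr2"))
  # coverage: block lengths sum to the SNP count
  expect_identical(sum(bp4$blocks$end_idx - bp4$blocks$start_idx + 1L), 13L)
  expect_error(fixed_blocks(map, 0))
})

test_that("pair LD matches hand values and the brute-force oracle", {
  expect_equal(pair_ld_from_counts(50, 0, 0, 50)$Dprime, 1)
  eq <- pair_ld_from_counts(25, 25, 25, 25)
  expect_equal(eq$D, 0)
  expect_equal(eq$Dprime, 0)
  h <- pair_ld_from_counts(40, 10, 10, 40)
  expect_equal(h$D, 0.15)
  expect_equal(h$Dmax, 0.25)
  expect_equal(h$Dprime, 0.6)
  expect_error(pair_ld_from_counts(10, 10, 0, 0), "monomorphic")

  set.seed(80)
  for (i in 1:1000) {
    cts <- as.vector(stats::rmultinom(1, sample(8:200, 1), runif(4, 0.05, 1)))
    pA <- (cts[1] + cts[2]) / sum(cts); pB <- (cts[1] + cts[3]) / sum(cts)
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
    got <- pair_ld_from_counts(cts[1], cts[2], cts[3], cts[4])
    oracle <- pair_ld_oracle(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got$D, oracle$D, tolerance = 1e-12)
    expect_equal(got$Dprime, oracle$Dprime, tolerance = 1e-12)
  }
})

test_that("D' confidence bounds behave at the extremes", {
  strong <- dprime_ci(pair_ld_from_counts(500, 0, 0, 500))
  expect_gte(strong["lower"], 0.98)
  weak <- dprime_ci(pair_ld_from_counts(3, 3, 3, 3))
  expect_lt(weak["lower"], 0.7)
  expect_gt(weak["upper"] - weak["lower"], 0.3)
  # mass 0 collapses both bounds onto the maximum-likelihood grid point
  ml <- dprime_ci(pair_ld_from_counts(40, 10, 10, 40), mass = 0)
  expect_identical(unname(ml["lower"]), unname(ml["upper"]))
  expect_equal(unname(ml["lower"]), 0.6, tolerance = 0.01)
})

test_that("D'-CI blocks recover planted cluster structure", {
  X <- ld_cluster_matrix(200, c(5, 1, 5), seed = 81)
  gs <- gs_from_matrix(X, tiny_map(11))
  bp <- gabriel_blocks(gs)
  expect_identical(nrow(bp$blocks), 2L)
  expect_identical(bp$blocks$start_idx, c(1L, 7L))
  expect_identical(bp$blocks$end_idx, c(5L, 11L))

  # independent SNPs: no blocks at all
  set.seed(82)
  Xi <- matrix(rbinom(400 * 8, 1, 0.5), 400, 8)
  expect_identical(nrow(gabriel_blocks(gs_from_matrix(Xi, tiny_map(8)))$blocks), 0L)

  # minimal 2-SNP chromosome in perfect LD
  v <- rbinom(500, 1, 0.5)
  bp2 <- gabriel_blocks(gs_from_matrix(cbind(v, v), tiny_map(2)))
  expect_identical(nrow(bp2$blocks), 1L)
  expect_identical(bp2$blocks$end_idx - bp2$blocks$start_idx + 1L, 2L)
})

test_that("four-gamete blocks split where all four gametes are seen", {
  # two whole-chromosome founder haplotypes: at most 2 distinct gametes,
  # so a zero-frequency class exists everywhere -> one block per chromosome
  set.seed(83)
  v1 <- rbinom(12, 1, 0.5); v2 <- 1 - v1
  X <- rbind(matrix(v1, 6, 12, byrow = TRUE), matrix(v2, 6, 12, byrow = TRUE))
  gs <- gs_from_matrix(X, tiny_map(12))
  bp <- four_gamete_blocks(gs)
  expect_identical(nrow(bp$blocks), 1L)
  expect_identical(c(bp$blocks$start_idx, bp$blocks$end_idx), c(1L, 12L))

  # all four gamete classes at 0.25 at one adjacency -> boundary there
  q <- rep(c(0L, 1L), each = 2)          # SNP a
  r <- rep(c(0L, 1L, 0L, 1L), 1)         # SNP b: all 4 combos seen
  Xb <- cbind(q, q, r, r)
  bpb <- four_gamete_blocks(gs_from_matrix(Xb, tiny_map(4)))
  expect_identical(bpb$blocks$start_idx, c(1L, 3L))
  expect_identical(bpb$blocks$end_idx, c(2L, 4L))

  # cutoff 1 links every adjacency
  bp1 <- four_gamete_blocks(gs, cutoff = 1)
  expect_identical(nrow(bp1$blocks), 1L)
})

test_that("solid-spine blocks extend while the end pair stays in strong LD", {
  # SNPs 1..6 identical, SNP 7 independent: spine stops at 6
  set.seed(84)
  v <- rbinom(300, 1, 0.5); w <- rbinom(300, 1, 0.5)
  X <- cbind(v, v, v, v, v, v, w)
  bp <- spine_blocks(gs_from_matrix(X, tiny_map(7)))
  expect_identical(bp$blocks$start_idx[1], 1L)
  expect_identical(bp$blocks$end_idx[1], 6L)

  # no strong LD anywhere: no blocks
  Xi <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6)
  expect_identical(nrow(spine_blocks(gs_from_matrix(Xi, tiny_map(6)))$blocks), 0L)

  # perfect-LD chromosome: single spanning block
  Xp <- matrix(rep(v, 5), ncol = 5)
  bpp <- spine_blocks(gs_from_matrix(Xp, tiny_map(5)))
  expect_identical(nrow(bpp$blocks), 1L)
  expect_identical(bpp$blocks$end_idx, 5L)
})

test_that("LD statistics and blocks are invariant under gamete duplication", {
  X <- ld_cluster_matrix(100, c(4, 1, 3), seed = 85)
  X2 <- rbind(X, X)
  for (j in 1:2) for (k in 3:4) {
    expect_equal(pair_ld(X, j, k)$Dprime, pair_ld(X2, j, k)$Dprime)
  }
  b1 <- four_gamete_blocks(gs_from_matrix(X, tiny_map(8)))
  b2 <- four_gamete_blocks(gs_from_matrix(X2, tiny_map(8)))
  expect_identical(b1$blocks, b2$blocks)
  g1 <- gabriel_blocks(gs_from_matrix(X, tiny_map(8)))
  g2 <- gabriel_blocks(gs_from_matrix(X2, tiny_map(8)))
  expect_identical(g1$blocks, g2$blocks)
})
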