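test_that("pseudo-marker encoding counts gametes per haplotype allele", {
  map <- tiny_map(2)
  # individuals: AA|AA, AB|AB, AA|AB over one 2-SNP block
  X <- rbind(c(0L, 0L), c(0L, 0L),   # ind1: two "00" gametes
             c(0L, 1L), c(0L, 1L),   # ind2: two "01"
             c(0L, 0L), c(0L, 1L))   # ind3: one of each
  gs <- gs_from_matrix(X, map)
  pm <- encode_alleles(fixed_blocks(map, 2), gs)
  expect_identical(ncol(pm$M), 2L)
  a00 <- which(pm$info$allele == "00"); a01 <- which(pm$info$allele == "01")
  expect_equal(unname(pm$M[, a00]), c(2, 0, 1))
  expect_equal(unname(pm$M[, a01]), c(0, 2, 1))
  # partition row sums per locus are always 2
  expect_true(all(rowSums(pm$M) == 2))

  # window-1 partition: per SNP the two allele columns sum to 2n
  pm1 <- encode_alleles(fixed_blocks(map, 1), gs)
  expect_true(all(tapply(colSums(pm1$M), pm1$info$block, sum) == 2 * 3))

  # library mode: dosage equals carrier-gamete count per individual
  blk <- list(chrom = "chr1", start_idx = 1, end_idx = 2,
              alleles = c(0L, 0L), carriers = c("ind001_a", "ind001_b", "ind003_a"))
  lib <- hap_library(list(blk), list(), n_gametes(gs), 2, rownames(gs$alleles))
  pml <- encode_alleles(lib, gs)
  expect_equal(unname(pml$M[, 1]), c(2, 0, 1))
})

test_that("singleton haplotype alleles are dropped per the carrier rule", {
  M <- cbind(one_carrier_d2 = c(2, 0, 0), two_carriers = c(1, 1, 0),
             common = c(2, 1, 1))
  rownames(M) <- paste0("i", 1:3)
  info <- data.frame(block = 1:3, allele = "x", chrom = "chr1",
                     start_idx = 1, end_idx = 1, n_snps = 1,
                     cM_span = 0, n_genes = NA)
  pm <- pseudo_markers(M, info)
  out <- drop_singletons(pm)
  expect_identical(colnames(out$M), c("two_carriers", "common"))
  # restricting the defined population changes the count
  out2 <- drop_singletons(pm, population = c("i1", "i2"))
  expect_identical(colnames(out2$M), c("two_carriers", "common"))
  # within {i2,i3}: two_carriers has 1 carrier -> dropped; one_carrier_d2
  # has 0 carriers there -> kept (not a singleton); common has 2 -> kept
  out3 <- drop_singletons(pm, population = c("i2", "i3"))
  expect_identical(colnames(out3$M), c("one_carrier_d2", "common"))
})

test_that("VanRaden GRM matches the hand-computed 2x2 case", {
  X <- rbind(i1 = c(2, 0), i2 = c(0, 2))
  G <- grm_vanraden(X)
  expect_equal(unname(G), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated individuals give identical rows
  X2 <- rbind(X, i3 = c(2, 0))
  G2 <- grm_vanraden(X2)
  expect_equal(G2["i1", ], G2["i3", ])
  expect_error(grm_vanraden(rbind(c(2, 2), c(2, 2))), "monomorphic")
})

test_that("window-1 haplotype GRM is exactly the SNP GRM", {
  dh <- keep_polymorphic(sim_small_dh(seed = 100, n_lines = 30, n_snp = 150))
  G_snp <- grm_vanraden(dosage_matrix(dh))
  G_h1 <- grm_vanraden(encode_alleles(fixed_blocks(dh$map, 1), dh))
  expect_lt(max(abs(G_snp - G_h1)), 1e-10)
})

test_that("GRMs are symmetric PSD and order-invariant", {
  dh <- keep_polymorphic(sim_small_dh(seed = 101, n_lines = 25, n_snp = 120))
  D <- dosage_matrix(dh)
  G <- grm_vanraden(D)
  expect_equal(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(G)) / nrow(G))
  # column order cannot matter; individual order permutes the GRM
  p <- sample(ncol(D)); q <- sample(nrow(D))
  expect_equal(grm_vanraden(D[, p]), G, tolerance = 1e-12)
  expect_equal(grm_vanraden(D[q, ]), G[q, q], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weighted GRM reduces to unweighted and honours zero weights", {
  dh <- keep_polymorphic(sim_small_dh(seed = 102, n_lines = 20, n_snp = 100))
  pm <- encode_alleles(fixed_blocks(dh$map, 10), dh)
  G0 <- grm_vanraden(pm)
  Gw <- grm_weighted(pm, rep(3.7, ncol(pm$M)))
  expect_equal(unname(Gw), unname(G0), tolerance = 1e-12, ignore_attr = TRUE)
  # a zero-weight column has no influence
  w <- rep(1, ncol(pm$M)); w[5] <- 0
  M_no5 <- pm$M[, -5]
  expect_equal(unname(grm_weighted(pm, w)),
               unname(grm_weighted(M_no5, w[-5])), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(grm_weighted(pm, -w), "negative")

  # SNP-count weights on a tail-free fixed partition equal the unweighted GRM
  dh2 <- keep_polymorphic(sim_small_dh(seed = 103, n_lines = 20, n_snp = 100))
  pm2 <- encode_alleles(fixed_blocks(dh2$map, 10), dh2)
  w2 <- haplotype_weights(pm2$info, "n_snps")
  if (all(w2 == w2[1]))
    expect_equal(unname(grm_weighted(pm2, w2)), unname(grm_vanraden(pm2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("haplotype weights follow the metadata modes", {
  map <- tiny_map(30)
  gene_track <- data.frame(chrom = "chr1",
                           start = c(1000, 9000), end = c(3500, 12000))
  dh <- sim_small_dh(seed = 104, n_lines = 10, n_snp = 30)
  pm <- encode_alleles(fixed_blocks(dh$map, 10), dh, gene_track = NULL)
  expect_identical(haplotype_weights(pm$info, "n_snps"),
                   as.numeric(pm$info$n_snps))
  expect_error(haplotype_weights(pm$info, "n_genes"), "gene track")
  w <- haplotype_weights(pm$info, "cM_length")
  expect_true(all(w > 0))
  expect_equal(w, pm$info$cM_span, tolerance = 1e-12)
  # gene counting uses half-open bp overlap
  gs <- gs_from_matrix(matrix(rep(0:1, 30), 2, 30), map)
  gs$alleles[1, ] <- 0L; gs$alleles[2, ] <- 1L
  pmg <- encode_alleles(fixed_blocks(map, 10), gs, gene_track = gene_track)
  # block 1 spans bp 1..10000 -> overlaps both genes; block 2: 11..20000 -> one
  counts <- tapply(pmg$info$n_genes, pmg$info$block, unique)
  expect_identical(as.numeric(counts), c(2, 1, 0))
})
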