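test_that("window clusters group identical window haplotypes", {
  map <- tiny_map(4)
  X <- matrix(rep(c(0L, 1L, 0L, 1L), 4), 4, 4, byrow = TRUE)
  gs <- gs_from_matrix(X, map)
  cl <- window_clusters(gs, 2)
  expect_identical(length(cl), 2L)  # 2 windows x 1 cluster
  expect_true(all(vapply(cl, function(b) length(b$carriers), 1L) == 4L))

  # two gametes differing everywhere: singleton clusters per window
  Y <- rbind(rep(0L, 4), rep(1L, 4), rep(0L, 4), rep(1L, 4))
  cl2 <- window_clusters(gs_from_matrix(Y, map), 2)
  expect_identical(length(cl2), 4L)
  expect_true(all(vapply(cl2, function(b) length(b$carriers), 1L) == 2L))

  # w >= n_snp: one window per chromosome
  cl3 <- window_clusters(gs, 10)
  expect_identical(length(cl3), 1L)
})

test_that("block extension follows exact carrier agreement to breakpoints", {
  # two founder haplotypes; a crossover at the midpoint in some carriers
  m <- 20
  map <- tiny_map(m)
  set.seed(90)
  h1 <- rbinom(m, 1, 0.5); h2 <- 1 - h1   # differ everywhere
  rec <- c(h1[1:10], h2[11:20])
  X <- rbind(matrix(h1, 4, m, byrow = TRUE),
             matrix(h2, 4, m, byrow = TRUE),
             matrix(rec, 2, m, byrow = TRUE))
  gs <- gs_from_matrix(X, map)
  blocks <- extend_blocks(window_clusters(gs, 5), gs)
  spans <- data.frame(s = vapply(blocks, `[[`, 1, "start_idx"),
                      e = vapply(blocks, `[[`, 1, "end_idx"),
                      nc = vapply(blocks, function(b) length(b$carriers), 1))
  # carriers of h1 including recombinants share exactly [1,10]
  expect_true(any(spans$s == 1 & spans$e == 10 & spans$nc == 6))
  # carriers of h2 including recombinants share exactly [11,20]
  expect_true(any(spans$s == 11 & spans$e == 20 & spans$nc == 6))
  # pure founder groups span the whole chromosome
  expect_true(any(spans$s == 1 & spans$e == 20 & spans$nc == 4))

  # identical gametes collapse into one whole-chromosome block
  Xi <- matrix(rep(h1, 4), 4, m, byrow = TRUE)
  gsi <- gs_from_matrix(Xi, map)
  bi <- extend_blocks(window_clusters(gsi, 7), gsi)
  expect_identical(length(bi), 1L)
  expect_identical(c(bi[[1]]$start_idx, bi[[1]]$end_idx), c(1L, 20L))
  expect_identical(length(bi[[1]]$carriers), 4L)

  expect_error(extend_blocks(window_clusters(gs, 5), gs, merging_error = 0.1),
               "unsupported")
})

test_that("every carrier matches its block's allele sequence exactly", {
  dh <- sim_small_dh(seed = 91, n_lines = 25, n_snp = 120)
  lib <- build_library(dh, w = 10, mcmb = 50)
  for (b in lib$blocks) {
    seg <- dh$alleles[b$carriers, b$start_idx:b$end_idx, drop = FALSE]
    expect_true(all(sweep(seg, 2, b$alleles, `==`)))
    # DH-duplicated gametes give even carrier counts
    expect_identical(length(b$carriers) %% 2L, 0L)
  }
})

test_that("cell-count and subgroup filters prune as specified", {
  dh <- sim_small_dh(seed = 92, n_lines = 20, n_snp = 100)
  cand <- extend_blocks(window_clusters(dh, 10), dh)
  lib_all <- filter_mcmb(cand, 1, gametes = dh)
  expect_identical(length(lib_all$blocks), length(cand))
  # a 10x5 block (50 cells) dies under the default 5000
  small <- list(chrom = "chr1", start_idx = 1, end_idx = 10,
                alleles = dh$alleles[1, 1:10], carriers = rownames(dh$alleles)[1:5])
  expect_identical(length(filter_mcmb(list(small), 5000, gametes = dh)$blocks), 0L)
  # threshold above the largest block empties the library
  maxcells <- max(vapply(cand, function(b)
    (b$end_idx - b$start_idx + 1) * length(b$carriers), 1))
  lib0 <- filter_mcmb(cand, maxcells + 1, gametes = dh)
  expect_identical(length(lib0$blocks), 0L)
  expect_identical(lib0$coverage, 0)

  # subgroup filter
  labs <- stats::setNames(rep(c("A", "B"), each = n_gametes(dh) / 2),
                          rownames(dh$alleles))
  expect_identical(filter_min_subgroup(lib_all, labs, 0), lib_all)
  lib_t <- filter_min_subgroup(lib_all, labs, 2)
  for (b in lib_t$blocks) {
    expect_gte(sum(labs[b$carriers] == "A"), 2)
    expect_gte(sum(labs[b$carriers] == "B"), 2)
  }
  big <- filter_min_subgroup(lib_all, labs, n_gametes(dh))
  expect_identical(length(big$blocks), 0L)
})

test_that("coverage is monotone in both filters", {
  dh <- sim_small_dh(seed = 93, n_lines = 25, n_snp = 150)
  cand <- extend_blocks(window_clusters(dh, 10), dh)
  covs <- vapply(c(1, 50, 200, 1000, 5000),
                 function(mc) filter_mcmb(cand, mc, gametes = dh)$coverage,
                 numeric(1))
  expect_true(all(diff(covs) <= 0))
  labs <- stats::setNames(rep(c("A", "B"), n_gametes(dh) / 2),
                          rownames(dh$alleles))
  lib1 <- filter_mcmb(cand, 1, gametes = dh)
  covs2 <- vapply(c(0, 2, 4, 8, 16),
                  function(t) filter_min_subgroup(lib1, labs, t)$coverage,
                  numeric(1))
  expect_true(all(diff(covs2) <= 0))
})

test_that("target coverage picks the largest threshold still reaching it", {
  dh <- sim_small_dh(seed = 94, n_lines = 25, n_snp = 150)
  lib <- build_library(dh, w = 10, target_coverage = 0.9)
  expect_gte(lib$coverage, 0.9)
  # the next larger distinct cell count must fall below the target
  cand <- extend_blocks(window_clusters(dh, 10), dh)
  cells <- sort(unique(vapply(cand, function(b)
    (b$end_idx - b$start_idx + 1) * length(b$carriers), 1)))
  nxt <- cells[cells > lib$params$mcmb][1]
  if (!is.na(nxt))
    expect_lt(filter_mcmb(cand, nxt, gametes = dh)$coverage, 0.9)
  expect_false(lib$params$unreachable)
})

test_that("library construction is order-invariant and founder-faithful", {
  # 8 founder gametes duplicated as DH lines: one block per founder pair,
  # full coverage
  m <- 60
  map <- tiny_map(m)
  set.seed(95)
  H <- matrix(rbinom(8 * m, 1, 0.5), 8, m)
  X <- H[rep(1:8, each = 2), ]
  gs <- gs_from_matrix(X, map)
  lib <- build_library(gs, w = 20, mcmb = 1)
  expect_identical(lib$coverage, 1)
  expect_identical(length(lib$blocks), 8L)
  expect_true(all(vapply(lib$blocks, function(b) length(b$carriers), 1L) == 2L))

  dh1 <- sim_small_dh(seed = 96, n_lines = 10, n_snp = 80, label = "A")
  dh2 <- sim_small_dh(seed = 97, n_lines = 10, n_snp = 80, label = "B")
  a2 <- dh2$alleles
  rownames(a2) <- NULL
  dh2 <- gamete_set(a2, dh1$map, gsub("DH", "XH", dh2$gamete_individual),
                    stats::setNames(rep("B", 10),
                                    gsub("DH", "XH", individuals(dh2))))
  libAB <- build_library(merge_gamete_sets(dh1, dh2), w = 10, mcmb = 1)
  libBA <- build_library(merge_gamete_sets(dh2, dh1), w = 10, mcmb = 1)
  tabAB <- library_to_table(libAB)
  tabBA <- library_to_table(libBA)
  expect_identical(tabAB, tabBA)
  expect_identical(libAB$coverage, libBA$coverage)
})
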