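test_that("Mantel r is the lower-triangle Pearson correlation", {
  set.seed(120)
  A <- crossprod(matrix(rnorm(49), 7)); B <- crossprod(matrix(rnorm(49), 7))
  mt <- mantel_test(A, B, n_perm = 99, seed = 1)
  lt <- lower.tri(A)
  expect_equal(mt$r, cor(A[lt], B[lt]), tolerance = 1e-12)
  # independent implementation (vegan) agrees on the statistic
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(max(A) - A), as.dist(max(B) - B), permutations = 0)
  expect_equal(mantel_test(max(A) - A, max(B) - B, n_perm = 9, seed = 1)$r,
               unname(vg$statistic), tolerance = 1e-10)
})

test_that("Mantel permutation p matches exhaustive enumeration", {
  set.seed(121)
  for (c_dim in 4:5) {
    A <- crossprod(matrix(rnorm(c_dim^2), c_dim))
    B <- A + crossprod(matrix(rnorm(c_dim^2, sd = 0.6), c_dim))
    oracle <- mantel_oracle(A, B)
    mt <- mantel_test(A, B, n_perm = 10000, seed = 2)
    expect_lt(abs(mt$p - oracle$p), 0.02)
  }
  # identical matrices: r = 1 and p at the sampling floor (only the
  # identity permutation reattains r = 1)
  G <- crossprod(matrix(rnorm(36), 6))
  mt1 <- mantel_test(G, G, n_perm = 999, seed = 3)
  expect_equal(mt1$r, 1)
  expect_lt(mt1$p, 0.01)
  # sign flip of the off-diagonal gives r = -1
  G2 <- -G
  diag(G2) <- diag(G)
  expect_equal(mantel_test(G2, G, n_perm = 99, seed = 4)$r, -1)
})

test_that("Wilcoxon signed-rank p is exact for small n", {
  # six all-positive differences: two-sided p = 2/64
  a <- c(2, 3, 4, 5, 6, 7); b <- c(1, 1, 1, 1, 1, 1)
  expect_equal(as.numeric(wilcoxon_signed_rank(a, b)), 2 / 64)
  # equal vectors: p = 1 by convention
  expect_equal(as.numeric(wilcoxon_signed_rank(a, a)), 1)
  # symmetric +/- differences of equal magnitude: p = 1
  d <- c(1, -1, 2, -2, 3, -3)
  expect_equal(as.numeric(wilcoxon_signed_rank(d, rep(0, 6))), 1)
  # statistic and p match full enumeration for n <= 10 (ties included)
  set.seed(122)
  for (i in 1:100) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, sd = 2), sample(0:1, 1))
    d[d == 0] <- 1
    got <- wilcoxon_signed_rank(d, rep(0, n))
    oracle <- wilcoxon_oracle(d)
    expect_equal(unname(attr(got, "statistic")), oracle$W)
    expect_equal(as.numeric(got), oracle$p, tolerance = 1e-12)
  }
  # and against R's exact test when there are no ties
  set.seed(123)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(as.numeric(wilcoxon_signed_rank(x, y)),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Bonferroni caps scaled p values at 1", {
  expect_equal(bonferroni(rep(0.01, 20))[1], 0.2)
  expect_equal(bonferroni(rep(0.2, 20))[1], 1)
  expect_equal(bonferroni(0.37), 0.37)
})

test_that("within-population CV partitions folds and is reproducible", {
  dh <- keep_polymorphic(sim_small_dh(seed = 130, n_lines = 50, n_snp = 150))
  qm <- sim_qtl_model(dh, 10, "additive_snp", seed = 131)
  ph <- sim_phenotypes(dh, qm, 0.7, seed = 132)
  methods <- list(snp = gp_method_snp(), fb = gp_method_fixed(10))
  rec <- run_scenario1(dh, ph, methods, k = 5, iters = 2, seed = 133)
  # 2 iterations x 5 folds per method and trait
  expect_identical(nrow(rec), 2L * 5L * 2L)
  expect_true(all(table(rec$method) == 10))
  rec2 <- run_scenario1(dh, ph, methods, k = 5, iters = 2, seed = 133)
  expect_identical(rec, rec2)
  expect_error(run_scenario1(dh, ph, methods, k = 51), "folds")
})

test_that("across-population runs sample disjoint TS/PS and are paired", {
  f <- sim_founders(n_founders_per_landrace = 12, n_snp = 120, seed = 140)
  fke <- subset_individuals(f, grep("^KE", individuals(f), value = TRUE))
  dh <- sim_dh_population(fke, 40, label = "DH_KE", prefix = "DHKE", seed = 141)
  fv2 <- make_inbred_line(rbinom(120, 1, 0.5), f$map)
  gc <- sim_gc_population(fke, fv2, 30, label = "GC_KE", prefix = "GCKE", seed = 142)
  qm <- sim_qtl_model(dh, 8, "additive_snp", seed = 143)
  ph_dh <- sim_phenotypes(dh, qm, 0.6, seed = 144)
  ph_gc <- sim_phenotypes(gc, qm, 0.6, seed = 145)
  methods <- list(snp = gp_method_snp(),
                  lib = gp_method_library(w = 10, mcmb = 1, min_subgroup = 2))
  rec <- run_scenario_across(dh, gc, ph_dh, ph_gc, methods, scenario = 2,
                             n_ts = 30, n_ps = 15, reps = 3, seed = 146,
                             fv2 = fv2, gc_side = "ps")
  expect_identical(nrow(rec), 3L * 2L)
  expect_identical(unique(rec$scenario), 2L)
  rec2 <- run_scenario_across(dh, gc, ph_dh, ph_gc, methods, scenario = 2,
                              n_ts = 30, n_ps = 15, reps = 3, seed = 146,
                              fv2 = fv2, gc_side = "ps")
  expect_identical(rec, rec2)
  expect_error(run_scenario_across(dh, gc, ph_dh, ph_gc, methods,
                                   n_ts = 200, n_ps = 15, reps = 1),
               "insufficient")

  base_acc <- rec$accuracy[rec$method == "SNP"]
  rec_cmp <- data.frame(
    scenario = 2L, method = rep(c("SNP", "better"), each = 6),
    trait = "trait1", repeat_id = rep(1:6, 2),
    accuracy = c(rep(base_acc, 2), rep(base_acc, 2) + 0.01))
  cmp <- compare_to_baseline(rec_cmp)
  expect_identical(nrow(cmp), 1L)
  expect_equal(cmp$mean_accuracy - cmp$mean_accuracy_baseline, 0.01)
  expect_equal(cmp$p_value, 2 / 64)
})

test_that("capture-line composition counts shared haplotype alleles", {
  # library of 3 whole-chromosome alleles; FV2 carries 2, one also in DH
  mk_block <- function(carriers) list(chrom = "chr1", start_idx = 1,
                                      end_idx = 5, alleles = rep(0L, 5),
                                      carriers = carriers)
  gam_ids <- c("DH1_a", "DH1_b", "DH2_a", "DH2_b", "GC1_a", "GC1_b",
               "FV2_a", "FV2_b")
  lib <- hap_library(list(mk_block(c("DH1_a", "DH1_b", "FV2_a")),
                          mk_block(c("GC1_a", "FV2_b")),
                          mk_block(c("DH2_a", "DH2_b"))),
                     list(), 8, 5, gam_ids)
  comp <- fv2_composition(lib, "FV2", c("DH1", "DH2"))
  expect_equal(as.numeric(comp), 1 / 3)
  cts <- attr(comp, "counts")
  expect_identical(unname(cts), c(3L, 2L, 1L))

  # pseudo-marker route agrees
  M <- cbind(a1 = c(2, 0, 0, 1), a2 = c(0, 0, 1, 1), a3 = c(0, 2, 0, 0))
  rownames(M) <- c("DH1", "DH2", "GC1", "FV2")
  pm <- pseudo_markers(M, data.frame(block = 1:3))
  expect_equal(as.numeric(fv2_composition(pm, "FV2", c("DH1", "DH2"))), 1 / 3)
})

test_that("minimum-subgroup tuning finds the planted threshold", {
  # whole-chromosome haplotypes with known subgroup counts:
  #   H_shared: 24 DH + 22 GC gametes, never carried by FV2
  #   H_fv2:     8 DH +  6 GC gametes + both FV2 gametes (GC side)
  m <- 10
  map <- tiny_map(m)
  set.seed(150)
  h_shared <- rbinom(m, 1, 0.5)
  h_fv2 <- 1 - h_shared
  X <- rbind(matrix(h_shared, 24, m, byrow = TRUE),
             matrix(h_fv2, 8, m, byrow = TRUE),       # DH gametes
             matrix(h_shared, 22, m, byrow = TRUE),
             matrix(h_fv2, 6, m, byrow = TRUE),       # GC gametes
             matrix(h_fv2, 2, m, byrow = TRUE))       # FV2
  ids <- c(paste0("DH", sprintf("%02d", rep(1:16, each = 2))),
           paste0("GC", sprintf("%02d", rep(1:14, each = 2))), "FV2", "FV2")
  gam_ids <- paste0(ids, c("_a", "_b"))
  gs <- gamete_set(X, map, ids,
                   stats::setNames(c(rep("DH", 16), rep("GC", 14), "FV2"),
                                   c(paste0("DH", sprintf("%02d", 1:16)),
                                     paste0("GC", sprintf("%02d", 1:14)), "FV2")))
  rownames(gs$alleles) <- gam_ids
  subgroups <- stats::setNames(c(rep("DH", 32), rep("GC", 30)), gam_ids)
  dh_ids <- paste0("DH", sprintf("%02d", 1:16))
  res <- tune_min_subgroup(gs, subgroups, "FV2", dh_ids,
                           candidates = c(5, 10, 20), mcmb = 1, w = 5)
  # at 5 both alleles survive (composition 1/2); at 8+ H_fv2 dies (0); ties
  # between 10 and 20 resolve to the smaller threshold
  expect_identical(res$best, 10)
  expect_equal(res$sweep$composition[res$sweep$threshold == 5], 0.5)
  expect_equal(res$sweep$composition[res$sweep$threshold == 10], 0)
  # the sweep table reports both counts for the alternative reading
  expect_true(all(c("n_fv2", "n_fv2_and_dh") %in% names(res$sweep)))
})
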