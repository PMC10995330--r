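#!/usr/bin/env Rscript
# Compares SNP-based and haplotype-based genomic relationship matrices per
# population: Mantel correlations of the lower triangles (with permutation
# p values) and the number of explanatory variables each method feeds into
# GBLUP. Also evaluates map-length / gene-count / SNP-count weighting of
# the library GRM.

source(file.path("analysis", "_common.R"))

methods <- list(
  snp = gp_method_snp(),
  fixedhb20 = gp_method_fixed(20),
  gab = gp_method_ld("gab"),
  haploblocker = gp_method_library(w = 20, target_coverage = 0.99))

mantel_rows <- list(); nvar_rows <- list()
for (p in names(DATA$pops)) {
  gs <- keep_polymorphic(DATA$pops[[p]])
  grms <- lapply(methods, build_method_grm, gametes = gs,
                 analysis_ids = individuals(gs), gene_track = DATA$genes)
  for (m in setdiff(names(methods), "snp")) {
    mt <- mantel_test(grms[[m]]$G, grms$snp$G, n_perm = 199,
                      seed = SEED + 30)
    mantel_rows[[length(mantel_rows) + 1]] <- data.frame(
      population = p, method = m, mantel_r = mt$r, p_value = mt$p)
  }
  nvar_rows[[length(nvar_rows) + 1]] <- data.frame(
    population = p,
    snp = grms$snp$n_columns, fixedhb20 = grms$fixedhb20$n_columns,
    gab = grms$gab$n_columns, haploblocker = grms$haploblocker$n_columns)
}
mantel_tab <- do.call(rbind, mantel_rows)
nvar_tab <- do.call(rbind, nvar_rows)
utils::write.csv(mantel_tab, file.path(RESULTS_DIR, "grm_mantel.csv"),
                 row.names = FALSE)
utils::write.csv(nvar_tab, file.path(RESULTS_DIR, "explanatory_variables.csv"),
                 row.names = FALSE)
message("Mantel correlations of haplotype GRMs with the SNP GRM:")
print(mantel_tab, row.names = FALSE, digits = 3)
message("explanatory variables per method:")
print(nvar_tab, row.names = FALSE)

## weighted library GRM: how much does weighting move the kernel?
gs <- keep_polymorphic(DATA$pops$DH_KE)
lib <- build_library(gs, w = 20, target_coverage = 0.99)
pm <- drop_singletons(encode_alleles(lib, gs, gene_track = DATA$genes))
G0 <- grm_vanraden(pm)
wt_rows <- lapply(c("cM_length", "n_genes", "n_snps"), function(mode) {
  Gw <- grm_weighted(pm, haplotype_weights(pm$info, mode))
  data.frame(weighting = mode,
             frobenius_rel = norm(Gw - G0, "F") / norm(G0, "F"),
             mantel_r_vs_unweighted = mantel_test(Gw, G0, n_perm = 99,
                                                  seed = SEED + 31)$r)
})
wt_tab <- do.call(rbind, wt_rows)
utils::write.csv(wt_tab, file.path(RESULTS_DIR, "grm_weighting.csv"),
                 row.names = FALSE)
message("weighted vs unweighted library GRM (DH_KE):")
print(wt_tab, row.names = FALSE, digits = 3)
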