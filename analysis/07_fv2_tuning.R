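#!/usr/bin/env Rscript
# Phenotype-free tuning of the minimum-subgroup threshold in scenario 2:
# the capture line's genotypes are included in the GC subgroup during
# library construction, and the threshold is chosen to minimize the
# share of library alleles that FV2 shares with the DH population (those
# can be alike in state across population types yet carry different QTL
# effects). The sweep also reports the raw counts so the alternative
# numerator (all FV2-carried alleles) is recoverable.

source(file.path("analysis", "_common.R"))

merged <- merge_gamete_sets(DATA$pops$DH_KE, DATA$pops$GC_KE, DATA$fv2)
subgroups <- stats::setNames(
  ifelse(grepl("^DHKE", rownames(merged$alleles)), "DH", "GC"),
  rownames(merged$alleles))

tuned <- tune_min_subgroup(merged, subgroups, "FV2",
                           individuals(DATA$pops$DH_KE),
                           candidates = c(1, 2, 4, 8), mcmb = 100, w = 20)
utils::write.csv(tuned$sweep, file.path(RESULTS_DIR, "fv2_tuning_sweep.csv"),
                 row.names = FALSE)
message("FV2-composition sweep over the minimum-subgroup threshold:")
print(tuned$sweep, row.names = FALSE, digits = 3)
message("chosen threshold (smallest composition, ties to the smaller ",
        "value): ", tuned$best)
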