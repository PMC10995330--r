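#!/usr/bin/env Rscript
# Sweeps the four library-construction parameters on merged DH+GC data
# from one landrace: window size, MCMB (minimum cells per block), target
# coverage, and the minimum-subgroup threshold. Coverage must fall
# monotonically in MCMB and in the subgroup threshold.

source(file.path("analysis", "_common.R"))

merged <- merge_gamete_sets(DATA$pops$DH_KE, DATA$pops$GC_KE, DATA$fv2)
subgroups <- stats::setNames(
  ifelse(grepl("^DHKE", rownames(merged$alleles)), "DH", "GC"),
  rownames(merged$alleles))

## window size
win <- do.call(rbind, lapply(c(5, 10, 20, 50), function(w) {
  lib <- build_library(merged, w = w, mcmb = 1)
  tabl <- library_to_table(lib)
  data.frame(window = w, n_blocks = nrow(tabl),
             mean_len = mean(tabl$end_idx - tabl$start_idx + 1),
             coverage = lib$coverage)
}))
mw <- build_library(merged, multi_window = TRUE, mcmb = 1)
win <- rbind(win, data.frame(window = NA, n_blocks = length(mw$blocks),
                             mean_len = mean(library_to_table(mw)$end_idx -
                                               library_to_table(mw)$start_idx + 1),
                             coverage = mw$coverage))
utils::write.csv(win, file.path(RESULTS_DIR, "sweep_window.csv"), row.names = FALSE)
message("window-size sweep (last row: multi-window mode):")
print(win, row.names = FALSE, digits = 3)

## MCMB, on the shared candidate set
cand <- extend_blocks(window_clusters(merged, 20), merged)
mc_grid <- c(1, 500, 1250, 5000, 20000, 80000)
mc <- do.call(rbind, lapply(mc_grid, function(m) {
  lib <- filter_mcmb(cand, m, gametes = merged)
  data.frame(mcmb = m, n_blocks = length(lib$blocks), coverage = lib$coverage)
}))
utils::write.csv(mc, file.path(RESULTS_DIR, "sweep_mcmb.csv"), row.names = FALSE)
stopifnot(all(diff(mc$coverage) <= 0))
message("MCMB sweep (coverage is monotone non-increasing):")
print(mc, row.names = FALSE, digits = 3)

## minimum subgroup
lib1 <- filter_mcmb(cand, 1, gametes = merged)
ms_grid <- c(0, 2, 5, 10, 20, 40)
ms <- do.call(rbind, lapply(ms_grid, function(t) {
  lib <- filter_min_subgroup(lib1, subgroups, t)
  data.frame(min_subgroup = t, n_blocks = length(lib$blocks),
             coverage = lib$coverage)
}))
utils::write.csv(ms, file.path(RESULTS_DIR, "sweep_min_subgroup.csv"),
                 row.names = FALSE)
stopifnot(all(diff(ms$coverage) <= 0))
message("minimum-subgroup sweep (desk-scale grid; thresholds are carrier ",
        "counts, so they scale with gamete numbers):")
print(ms, row.names = FALSE, digits = 3)

## target coverage
tc <- do.call(rbind, lapply(c(0.80, 0.85, 0.90, 0.95, 0.99), function(t) {
  lib <- build_library(merged, w = 20, target_coverage = t)
  data.frame(target = t, achieved = lib$coverage, mcmb_used = lib$params$mcmb,
             unreachable = lib$params$unreachable)
}))
utils::write.csv(tc, file.path(RESULTS_DIR, "sweep_target_coverage.csv"),
                 row.names = FALSE)
message("target-coverage sweep:")
print(tc, row.names = FALSE, digits = 4)
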