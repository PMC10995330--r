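# Shared setup for the numbered analysis scripts: one deterministic
# synthetic dataset emulating the four landrace-derived populations
# (DH and gamete-capture lines from two divergent landraces plus the
# capture line FV2), at desk scale. Sourced by every script so each can
# be run on its own.

library(haplopred)

RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

SEED <- 20260926
N_SNP <- 400

make_dataset <- function() {
  founders <- sim_founders(n_founders_per_landrace = 35, n_snp = N_SNP,
                           divergence = 0.15, ld_decay = 1,
                           labels = c("KE", "PE"), seed = SEED)
  f_ke <- subset_individuals(founders, grep("^KE", individuals(founders), value = TRUE))
  f_pe <- subset_individuals(founders, grep("^PE", individuals(founders), value = TRUE))
  # the capture line shares ancestry with the KE landrace (it is an
  # inbred fixed from one founder meiosis), so some of its haplotypes
  # are alike in state with DH haplotypes - the feature the FV2
  # composition diagnostic is about
  set.seed(SEED + 1)
  f0 <- sample(individuals(f_ke), 1)
  rows <- which(f_ke$gamete_individual == f0)
  fv2 <- make_inbred_line(meiosis(f_ke$alleles[rows[1], ],
                                  f_ke$alleles[rows[2], ], founders$map),
                          founders$map)

  pops <- list(
    DH_KE = sim_dh_population(f_ke, 120, label = "DH_KE", prefix = "DHKE",
                              seed = SEED + 2),
    DH_PE = sim_dh_population(f_pe, 100, label = "DH_PE", prefix = "DHPE",
                              seed = SEED + 3),
    GC_KE = sim_gc_population(f_ke, fv2, 90, label = "GC_KE", prefix = "GCKE",
                              seed = SEED + 4),
    GC_PE = sim_gc_population(f_pe, fv2, 90, label = "GC_PE", prefix = "GCPE",
                              seed = SEED + 5))

  # one polymorphism filter across all populations keeps every set on a
  # single shared map
  A <- do.call(rbind, lapply(pops, `[[`, "alleles"))
  poly <- colSums(A == 0) > 0 & colSums(A == 1) > 0
  pops <- lapply(pops, subset_markers, keep = poly)
  fv2 <- subset_markers(fv2, poly)

  # two traits: an additive-SNP architecture and a founder-origin
  # architecture (the latter is where haplotypes can outperform SNPs)
  merged_ke <- merge_gamete_sets(pops$DH_KE, pops$GC_KE)
  merged_pe <- merge_gamete_sets(pops$DH_PE, pops$GC_PE)
  qtl_add <- sim_qtl_model(merged_ke, 20, "additive_snp", seed = SEED + 6)
  phen <- list()
  for (p in names(pops)) {
    m <- pops[[p]]
    qtl_fnd <- sim_qtl_model(if (grepl("KE", p)) merged_ke else merged_pe,
                             20, "founder_haplotype", seed = SEED + 7)
    phen[[p]] <- rbind(
      sim_phenotypes(m, qtl_add, h2 = 0.7, trait = "trait_additive",
                     seed = SEED + 10 + match(p, names(pops))),
      sim_phenotypes(m, qtl_fnd, h2 = 0.7, trait = "trait_founder",
                     seed = SEED + 20 + match(p, names(pops))))
  }
  genes <- sim_gene_track(pops$DH_KE$map, 60, seed = SEED + 8)
  list(pops = pops, fv2 = fv2, phen = phen, genes = genes,
       map = pops$DH_KE$map)
}

message("building the shared synthetic dataset ...")
DATA <- make_dataset()
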