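# Shared fixture builders and independent oracles. Everything is built in
# code; no data files.

# minimal strictly increasing map
tiny_map <- function(m, chrom = "chr1", cM_per_snp = 1, bp_per_snp = 1000L) {
  data.frame(chrom = chrom, bp = seq_len(m) * bp_per_snp,
             cM = seq_len(m) * cM_per_snp)
}

# a gamete_set from an explicit gamete matrix; individuals own consecutive
# gamete pairs
gs_from_matrix <- function(X, map = NULL, pop = "P1", prefix = "ind") {
  n <- nrow(X)
  stopifnot(n %% 2 == 0)
  if (is.null(map)) map <- tiny_map(ncol(X))
  ids <- paste0(prefix, sprintf("%03d", seq_len(n / 2)))
  gam_ind <- rep(ids, each = 2)
  rownames(X) <- paste0(gam_ind, c("_a", "_b"))
  gamete_set(X, map, gam_ind, stats::setNames(rep(pop, n / 2), ids))
}

# standard small simulated DH population used across tests
sim_small_dh <- function(seed = 1, n_founders = 12, n_snp = 200,
                         n_lines = 40, ld_decay = 1, label = "DH_KE") {
  f <- sim_founders(n_founders_per_landrace = n_founders, n_snp = n_snp,
                    ld_decay = ld_decay, seed = seed)
  fke <- subset_individuals(f, grep("^KE", individuals(f), value = TRUE))
  sim_dh_population(fke, n_lines, label = label, seed = seed + 1)
}

# brute-force D'/Dmax oracle: enumerate all two-locus tables with the
# observed margins and take the extreme D in the observed direction
pair_ld_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  nA <- n11 + n10; nB <- n11 + n01
  pA <- nA / n; pB <- nB / n
  D <- n11 / n - pA * pB
  k_range <- max(0, nA + nB - n):min(nA, nB)
  Ds <- k_range / n - pA * pB
  Dmax <- if (D >= 0) max(Ds) else abs(min(Ds))
  list(D = D, Dprime = abs(D) / Dmax)
}

# exhaustive Wilcoxon signed-rank oracle over all 2^n sign patterns
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(rk[s]))
  p_ge <- mean(Ws >= W); p_le <- mean(Ws <= W)
  list(W = W, p = min(1, 2 * min(p_ge, p_le)))
}

# exhaustive Mantel oracle: upper one-sided p over all permutations
mantel_oracle <- function(G1, G2) {
  n <- nrow(G1)
  lt <- lower.tri(G1)
  r_obs <- stats::cor(G1[lt], G2[lt])
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  rs <- apply(perms, 1, function(p) stats::cor(G1[p, p][lt], G2[lt]))
  list(r = r_obs, p = mean(rs >= r_obs))
}

# perfect-LD cluster fixture: groups of identical SNP columns separated by
# independent columns; returns the gamete matrix
ld_cluster_matrix <- function(n_gam, cluster_sizes, seed = 1) {
  set.seed(seed)
  cols <- list()
  for (sz in cluster_sizes) {
    v <- rbinom(n_gam, 1, 0.5)
    while (length(unique(v)) < 2 || min(table(v)) < n_gam / 4)
      v <- rbinom(n_gam, 1, 0.5)
    for (i in seq_len(sz)) cols[[length(cols) + 1]] <- v
  }
  do.call(cbind, cols)
}
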