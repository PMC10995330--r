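#' Mantel test between two relationship matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' symmetric matrices in the same id order; significance by simultaneous
#' row/column permutation of the first matrix with the second held fixed.
#' The p value is one-sided upper with the add-one correction,
#' `p = (1 + #{perm r >= observed}) / (1 + n_perm)`.
#'
#' @param G1,G2 symmetric matrices of equal dimension (c >= 4) and id
#'   order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `r` (observed correlation) and `p`.
#' @export
mantel_test <- function(G1, G2, n_perm = 999, seed = 1) {
  stopifnot(all(dim(G1) == dim(G2)), nrow(G1) >= 4)
  withr_seed(seed)
  lt <- lower.tri(G1)
  v1 <- G1[lt]; v2 <- G2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("Mantel r undefined: constant off-diagonal entries")
  r_obs <- stats::cor(v1, v2)
  n <- nrow(G1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pi <- sample.int(n)
    rp <- stats::cor(G1[pi, pi][lt], v2)
    if (rp >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm))
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Zero differences are dropped. For up to 25 non-zero differences the
#' null distribution of the signed-rank statistic is enumerated exactly
#' (by dynamic programming over doubled midranks, so ties are handled
#' exactly too); beyond that a normal approximation with tie correction
#' is used. All differences zero gives p = 1 by convention.
#'
#' @param paired_a,paired_b paired numeric vectors.
#' @return two-sided p value, with the signed-rank statistic `W` (sum of
#'   ranks of positive differences) as attribute `statistic`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(structure(1, statistic = NA_real_))
  if (n < 5) stop("need at least 5 non-zero paired differences")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= 25) {
    # exact: distribution of W over the 2^n equiprobable sign patterns,
    # via the generating polynomial in doubled ranks (integers even with
    # midranks)
    r2 <- as.integer(round(2 * rk))
    probs <- 1
    for (r in r2) {
      new <- numeric(length(probs) + r)
      new[seq_along(probs)] <- probs / 2
      new[seq_along(probs) + r] <- new[seq_along(probs) + r] + probs / 2
      probs <- new
    }
    # probs[k + 1] = P(2W = k)
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p_le <- sum(probs[1:(w2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(p, statistic = W)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p value (delegated to [stats::p.adjust()]); the
#' family is the full vector supplied.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Capture-line haplotype composition
#'
#' Ratio of the capture line's haplotype alleles that also occur in at
#' least one DH individual, divided by the total number of haplotype
#' alleles in the library. Low values mean the library carries few
#' haplotypes that are shared between the capture line and the DH
#' population (such alleles can be alike in state but carry different
#' QTL effects across population types, which harms across-population
#' prediction).
#'
#' @param x a [hap_library()] built with the capture line's gametes in
#'   the construction set, or a [pseudo_markers()] matrix whose rows
#'   include the capture line.
#' @param fv2_id individual id of the capture line.
#' @param dh_ids individual ids of the DH population.
#' @param gamete_individual for a library: named vector mapping gamete id
#'   to individual id (defaults to stripping a trailing `_a`/`_b`).
#' @return the ratio in `[0, 1]`, with attribute `counts` =
#'   `c(total, fv2, fv2_and_dh)` so the alternative reading (all of the
#'   capture line's alleles, regardless of DH occurrence) is recoverable.
#' @export
fv2_composition <- function(x, fv2_id, dh_ids, gamete_individual = NULL) {
  if (inherits(x, "hap_library")) {
    if (!length(x$blocks)) stop("empty haplotype library")
    g2i <- gamete_individual %||%
      stats::setNames(sub("_[ab]$", "", x$gamete_ids), x$gamete_ids)
    carried_by <- function(b, ids) any(g2i[b$carriers] %in% ids)
    fv2_c <- vapply(x$blocks, carried_by, logical(1), ids = fv2_id)
    dh_c <- vapply(x$blocks, carried_by, logical(1), ids = dh_ids)
    total <- length(x$blocks)
  } else if (inherits(x, "pseudo_markers")) {
    if (ncol(x$M) == 0) stop("empty haplotype allele set")
    fv2_c <- x$M[fv2_id, ] > 0
    dh_c <- colSums(x$M[dh_ids, , drop = FALSE] > 0) > 0
    total <- ncol(x$M)
  } else stop("x must be a hap_library or pseudo_markers")
  structure(sum(fv2_c & dh_c) / total,
            counts = c(total = total, fv2 = sum(fv2_c),
                       fv2_and_dh = sum(fv2_c & dh_c)))
}

#' Tune the minimum-subgroup threshold by capture-line composition
#'
#' Builds one haplotype library per candidate threshold (default MCMB
#' 5000), computes the capture-line composition of each, and returns the
#' candidate minimizing it (ties broken by the smallest threshold),
#' together with the full sweep table. Candidates yielding an empty
#' library are skipped with a warning.
#'
#' @param gametes a [gamete_set()] including the capture line's gametes.
#' @param subgroups named character vector, subgroup per gamete id.
#' @param fv2_id capture-line individual id.
#' @param dh_ids DH individual ids.
#' @param candidates thresholds to sweep (default 10, 20, 40, 80, 160).
#' @param mcmb cell-count filter used for every candidate.
#' @param w window size passed to [build_library()].
#' @return list with `best` (the chosen threshold) and `sweep`
#'   (data.frame: `threshold`, `n_blocks`, `coverage`, `n_fv2`,
#'   `n_fv2_and_dh`, `composition`).
#' @export
tune_min_subgroup <- function(gametes, subgroups, fv2_id, dh_ids,
                              candidates = c(10, 20, 40, 80, 160),
                              mcmb = 5000, w = 20) {
  stopifnot(length(candidates) >= 1)
  rows <- list()
  for (t in candidates) {
    lib <- build_library(gametes, w = w, mcmb = mcmb,
                         subgroups = subgroups, min_subgroup = t)
    if (!length(lib$blocks)) {
      warning("min_subgroup = ", t, " yields an empty library; skipped")
      next
    }
    comp <- fv2_composition(lib, fv2_id, dh_ids)
    cts <- attr(comp, "counts")
    rows[[length(rows) + 1]] <- data.frame(
      threshold = t, n_blocks = cts["total"], coverage = lib$coverage,
      n_fv2 = cts["fv2"], n_fv2_and_dh = cts["fv2_and_dh"],
      composition = as.numeric(comp), row.names = NULL)
  }
  if (!length(rows)) stop("every candidate yielded an empty library")
  sweep <- do.call(rbind, rows)
  best <- sweep$threshold[order(sweep$composition, sweep$threshold)][1]
  list(best = best, sweep = sweep)
}
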