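#' Haplotype block partition
#'
#' An ordered set of non-overlapping SNP-index intervals per chromosome.
#' Indices are 1-based inclusive (`start_idx`, `end_idx`) into the global
#' marker order of the map the partition was built on. Fixed-window
#' partitions cover every SNP; LD-based methods may leave SNPs
#' unassigned.
#'
#' @param blocks data.frame with columns `chrom`, `start_idx`, `end_idx`.
#' @param method method tag.
#' @param params list of the parameters used.
#' @param map the map the indices refer to.
#' @return an object of class `block_partition`.
#' @export
block_partition <- function(blocks, method, params = list(), map = NULL) {
  stopifnot(all(c("chrom", "start_idx", "end_idx") %in% names(blocks)))
  blocks <- blocks[order(blocks$start_idx), , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks) > 1) {
    same <- blocks$chrom[-1] == blocks$chrom[-nrow(blocks)]
    overl <- blocks$start_idx[-1] <= blocks$end_idx[-nrow(blocks)]
    if (any(same & overl)) stop("blocks overlap")
  }
  if (any(blocks$end_idx < blocks$start_idx)) stop("empty block interval")
  structure(list(blocks = blocks, method = method, params = params, map = map),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  len <- x$blocks$end_idx - x$blocks$start_idx + 1
  cat("<block_partition> method=", x$method, ": ", nrow(x$blocks),
      " blocks, mean length ", signif(mean(len), 3), " SNPs\n", sep = "")
  invisible(x)
}

#' Fixed-window haplotype blocks
#'
#' Consecutive non-overlapping windows of exactly `window_size` adjacent
#' SNPs per chromosome, from the first to the last SNP; the final window
#' of a chromosome may be shorter. Blocks never span chromosomes.
#'
#' @param map marker map.
#' @param window_size SNPs per block (>= 1).
#' @return a [block_partition()] covering every SNP.
#' @export
fixed_blocks <- function(map, window_size) {
  stopifnot(window_size >= 1)
  window_size <- as.integer(window_size)
  validate_map(map)
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    starts <- as.integer(seq(idx[1], idx[length(idx)], by = window_size))
    data.frame(chrom = ch, start_idx = starts,
               end_idx = pmin(starts + window_size - 1L, idx[length(idx)]))
  })
  block_partition(do.call(rbind, out), "FixedHB",
                  list(window_size = window_size), map)
}

#' Two-locus linkage disequilibrium from phased gametes
#'
#' Counts the four two-locus gamete classes directly (data are phased, so
#' no EM is needed) and computes `D = p11 - pA pB` and its normalization
#' `D' = |D| / Dmax`, where `Dmax` is the largest |D| attainable at the
#' observed allele frequencies in the direction of the observed D.
#'
#' @param gametes a [gamete_set()] or 0/1 gamete matrix.
#' @param i,j marker column indices.
#' @return an object of class `pair_ld` with fields `n11`, `n10`, `n01`,
#'   `n00`, `pA`, `pB`, `D`, `Dmax`, `Dprime`.
#' @export
pair_ld <- function(gametes, i, j) {
  X <- if (inherits(gametes, "gamete_set")) gametes$alleles else gametes
  a <- X[, i]; b <- X[, j]
  if (anyNA(a) || anyNA(b)) stop("pair_ld requires complete data")
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  pair_ld_from_counts(n11, n10, n01, n00)
}

#' @rdname pair_ld
#' @param n11,n10,n01,n00 two-locus gamete counts (allele 1 at the first
#'   locus listed first).
#' @export
pair_ld_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n == 0) stop("zero total count")
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("D' undefined: monomorphic locus")
  D <- n11 / n - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 pA = pA, pB = pB, D = D, Dmax = Dmax,
                 Dprime = abs(D) / Dmax),
            class = "pair_ld")
}

#' Likelihood-based confidence bounds for D'
#'
#' Profiles a multinomial likelihood over a grid of D' values in `[0, 1]`
#' with the observed allele frequencies held fixed (each grid D' maps to
#' the four haplotype probabilities in the direction of the observed D),
#' normalizes it to unit mass, and reports the grid points bounding the
#' central `mass` interval. With `mass = 0` both bounds collapse to the
#' maximum-likelihood grid point.
#'
#' @param pl a [pair_ld()] object.
#' @param grid_step grid resolution on D'.
#' @param mass central probability mass of the interval (default 0.90,
#'   i.e. 5th and 95th percentile bounds).
#' @return numeric `c(lower, upper)`.
#' @export
dprime_ci <- function(pl, grid_step = 0.001, mass = 0.90) {
  stopifnot(inherits(pl, "pair_ld"), mass >= 0, mass < 1)
  b <- ci_bounds_batch(pl$n11, pl$n10, pl$n01, pl$n00,
                       grid_step = grid_step, mass = mass)
  c(lower = b$lower, upper = b$upper)
}

# Vectorized D' CI bounds for many pairs at once. All count vectors have
# one entry per pair. Returns list(lower, upper) vectors.
ci_bounds_batch <- function(n11, n10, n01, n00, grid_step = 0.001,
                            mass = 0.90, chunk = 512L) {
  n <- n11 + n10 + n01 + n00
  if (any(n == 0)) stop("zero total count")
  np <- length(n11)
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  s <- ifelse(D >= 0, 1, -1)
  Dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  if (any(Dmax <= 0)) stop("D' undefined: monomorphic locus")
  grid <- seq(0, 1, by = grid_step)
  ng <- length(grid)
  lower <- numeric(np); upper <- numeric(np)
  lo_tail <- (1 - mass) / 2
  hi_tail <- 1 - lo_tail
  for (start in seq(1, np, by = chunk)) {
    sel <- start:min(start + chunk - 1, np)
    k <- length(sel)
    dgrid <- (s[sel] * Dmax[sel]) %o% grid          # k x ng signed D values
    P11 <- pA[sel] * pB[sel] + dgrid
    P10 <- pA[sel] - P11
    P01 <- pB[sel] - P11
    P00 <- 1 - P11 - P10 - P01
    eps <- 1e-300
    ll <- n11[sel] * log(pmax(P11, eps)) + n10[sel] * log(pmax(P10, eps)) +
      n01[sel] * log(pmax(P01, eps)) + n00[sel] * log(pmax(P00, eps))
    ll <- ll - apply(ll, 1, max)
    w <- exp(ll)
    w <- w / rowSums(w)
    if (mass == 0) {
      mle <- max.col(w, ties.method = "first")
      lower[sel] <- grid[mle]; upper[sel] <- grid[mle]
    } else {
      cw <- t(apply(w, 1, cumsum))
      lower[sel] <- grid[max.col(cw >= lo_tail, ties.method = "first")]
      upper[sel] <- grid[max.col(cw >= hi_tail, ties.method = "first")]
    }
  }
  list(lower = lower, upper = upper)
}

# Strong-LD classification of all pairs (within max_span) on one
# chromosome's gamete matrix. Returns a logical n x n matrix (NA outside
# span or where D' is undefined).
strong_ld_matrix <- function(X, ci_lower = 0.70, ci_upper = 0.98,
                             grid_step = 0.001, mass = 0.90,
                             max_span = Inf) {
  m <- ncol(X)
  poly <- colSums(X == 1) > 0 & colSums(X == 0) > 0
  N11 <- crossprod(X)
  cs <- colSums(X)
  n <- nrow(X)
  S <- matrix(NA, m, m)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  if (is.finite(max_span))
    pairs <- pairs[pairs[, 2] - pairs[, 1] < max_span, , drop = FALSE]
  ok <- poly[pairs[, 1]] & poly[pairs[, 2]]
  pr <- pairs[ok, , drop = FALSE]
  if (nrow(pr)) {
    n11 <- N11[pr]
    n10 <- cs[pr[, 1]] - n11
    n01 <- cs[pr[, 2]] - n11
    n00 <- n - n11 - n10 - n01
    b <- ci_bounds_batch(n11, n10, n01, n00, grid_step = grid_step, mass = mass)
    strong <- b$upper >= ci_upper & b$lower >= ci_lower
    S[pr] <- strong
    S[pr[, 2:1, drop = FALSE]] <- strong
  }
  S
}

#' D'-confidence-interval haplotype blocks
#'
#' A SNP pair is in "strong LD" when the confidence bounds of D' satisfy
#' upper >= `ci_upper` and lower >= `ci_lower`. A candidate interval
#' qualifies when at least `frac` of all its within-interval pairs are in
#' strong LD. Qualifying intervals are emitted greedily from longest to
#' shortest (ties broken by leftmost start), skipping any that overlap an
#' accepted block.
#'
#' @param gametes a [gamete_set()] (phased, complete).
#' @param map marker map (defaults to the set's map).
#' @param ci_lower,ci_upper strong-LD thresholds on the D' bounds.
#' @param frac minimum fraction of strong-LD pairs in a block.
#' @param min_block minimum block length in SNPs.
#' @param max_span optional cap on block length in SNPs (uncapped by
#'   default; set for large chromosomes to bound the pair computation).
#' @param mass central mass of the D' interval (see [dprime_ci()]).
#' @return a [block_partition()]; SNPs outside all blocks are unassigned.
#' @export
gabriel_blocks <- function(gametes, map = NULL, ci_lower = 0.70,
                           ci_upper = 0.98, frac = 0.95, min_block = 2,
                           max_span = Inf, mass = 0.90) {
  stopifnot(min_block >= 2)
  X <- if (inherits(gametes, "gamete_set")) gametes$alleles else gametes
  if (is.null(map)) map <- gametes$map
  if (anyNA(X)) stop("gabriel_blocks requires complete data")
  res <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < min_block)
      return(data.frame(chrom = character(), start_idx = integer(),
                        end_idx = integer()))
    S <- strong_ld_matrix(X[, idx, drop = FALSE], ci_lower, ci_upper,
                          mass = mass, max_span = max_span)
    # prefix sums of the strong indicator for O(1) interval queries
    S0 <- S; S0[is.na(S0)] <- 0; diag(S0) <- 0
    P <- apply(apply(S0, 1, cumsum), 1, cumsum)  # P[i,j] = sum S0[1:i,1:j]
    pair_sum <- function(a, b) {
      tot <- P[b, b] - (if (a > 1) P[a - 1, b] else 0) -
        (if (a > 1) P[b, a - 1] else 0) + (if (a > 1) P[a - 1, a - 1] else 0)
      tot / 2
    }
    cand <- list()
    span_cap <- min(m, if (is.finite(max_span)) max_span else m)
    for (len in span_cap:min_block) {
      for (a in 1:(m - len + 1)) {
        b2 <- a + len - 1
        npair <- len * (len - 1) / 2
        if (pair_sum(a, b2) / npair >= frac)
          cand[[length(cand) + 1]] <- c(a, b2)
      }
    }
    if (!length(cand))
      return(data.frame(chrom = character(), start_idx = integer(),
                        end_idx = integer()))
    cand <- do.call(rbind, cand)
    # already ordered longest-first, leftmost within a length
    taken <- logical(m)
    keep <- list()
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b2 <- cand[r, 2]
      if (!any(taken[a:b2])) {
        taken[a:b2] <- TRUE
        keep[[length(keep) + 1]] <- c(a, b2)
      }
    }
    keep <- do.call(rbind, keep)
    data.frame(chrom = ch, start_idx = idx[keep[, 1]], end_idx = idx[keep[, 2]])
  })
  block_partition(do.call(rbind, res), "GAB",
                  list(ci_lower = ci_lower, ci_upper = ci_upper, frac = frac,
                       min_block = min_block, max_span = max_span), map)
}

#' Four-gamete-rule haplotype blocks
#'
#' An adjacent SNP pair is "in LD" when the rarest of its four two-locus
#' gamete classes has frequency below `cutoff` (i.e. recombination need
#' not be invoked). Maximal runs of consecutive in-LD adjacencies form
#' blocks; isolated SNPs stay unassigned.
#'
#' @param gametes a [gamete_set()] (phased, complete).
#' @param map marker map (defaults to the set's map).
#' @param cutoff frequency threshold for the rarest gamete class.
#' @return a [block_partition()].
#' @export
four_gamete_blocks <- function(gametes, map = NULL, cutoff = 0.01) {
  X <- if (inherits(gametes, "gamete_set")) gametes$alleles else gametes
  if (is.null(map)) map <- gametes$map
  if (anyNA(X)) stop("four_gamete_blocks requires complete data")
  n <- nrow(X)
  res <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < 2)
      return(data.frame(chrom = character(), start_idx = integer(),
                        end_idx = integer()))
    A <- X[, idx, drop = FALSE]
    a <- A[, -m, drop = FALSE]; b <- A[, -1, drop = FALSE]
    n11 <- colSums(a == 1 & b == 1); n10 <- colSums(a == 1 & b == 0)
    n01 <- colSums(a == 0 & b == 1); n00 <- colSums(a == 0 & b == 0)
    in_ld <- pmin(n11, n10, n01, n00) / n < cutoff
    r <- rle(in_ld)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs))
      return(data.frame(chrom = character(), start_idx = integer(),
                        end_idx = integer()))
    data.frame(chrom = ch, start_idx = idx[starts[runs]],
               end_idx = idx[ends[runs] + 1])
  })
  block_partition(do.call(rbind, res), "4GAM", list(cutoff = cutoff), map)
}

#' Solid-spine-of-LD haplotype blocks
#'
#' Scanning left to right, a block's right edge is extended while the
#' (first, last) SNP pair of the extended block is in strong LD (same
#' D'-bound criterion as [gabriel_blocks()]); intermediate SNPs are
#' included regardless of their pairwise LD.
#'
#' @inheritParams gabriel_blocks
#' @return a [block_partition()].
#' @export
spine_blocks <- function(gametes, map = NULL, ci_lower = 0.70,
                         ci_upper = 0.98, max_span = Inf, mass = 0.90) {
  X <- if (inherits(gametes, "gamete_set")) gametes$alleles else gametes
  if (is.null(map)) map <- gametes$map
  if (anyNA(X)) stop("spine_blocks requires complete data")
  res <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    S <- strong_ld_matrix(X[, idx, drop = FALSE], ci_lower, ci_upper,
                          mass = mass, max_span = max_span)
    m <- length(idx)
    out <- list()
    a <- 1
    while (a < m) {
      b <- a
      while (b < m && isTRUE(S[a, b + 1]) &&
             (!is.finite(max_span) || b + 1 - a < max_span)) b <- b + 1
      if (b > a) {
        out[[length(out) + 1]] <- c(a, b)
        a <- b + 1
      } else a <- a + 1
    }
    if (!length(out))
      return(data.frame(chrom = character(), start_idx = integer(),
                        end_idx = integer()))
    ab <- do.call(rbind, out)
    data.frame(chrom = ch, start_idx = idx[ab[, 1]], end_idx = idx[ab[, 2]])
  })
  block_partition(do.call(rbind, res), "SPINE",
                  list(ci_lower = ci_lower, ci_upper = ci_upper,
                       max_span = max_span), map)
}

#' Export a block partition as a BED-like table
#'
#' @param bp a [block_partition()] built with a map.
#' @param path optional path to write a TSV; when `NULL` the table is
#'   returned only.
#' @return data.frame with `chrom`, `start_bp` (0-based), `end_bp`
#'   (exclusive), `start_idx`, `end_idx`, `method`.
#' @export
blocks_to_bed <- function(bp, path = NULL) {
  stopifnot(inherits(bp, "block_partition"), !is.null(bp$map))
  b <- bp$blocks
  out <- data.frame(chrom = b$chrom,
                    start_bp = bp$map$bp[b$start_idx] - 1L,
                    end_bp = bp$map$bp[b$end_idx],
                    start_idx = b$start_idx, end_idx = b$end_idx,
                    method = bp$method)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
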