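#' Pseudo-marker matrix of haplotype alleles
#'
#' Individuals x haplotype-allele count matrix with entries 0/1/2 (the
#' number of the individual's two gametes carrying the allele), plus
#' per-column metadata. For partition-based loci every individual's row
#' sums to 2 within one locus' columns; library blocks may overlap, so no
#' such constraint holds there.
#'
#' @param M numeric matrix individuals x columns.
#' @param info data.frame of column metadata (one row per column).
#' @return object of class `pseudo_markers`.
#' @export
pseudo_markers <- function(M, info) {
  stopifnot(ncol(M) == nrow(info))
  structure(list(M = M, info = info), class = "pseudo_markers")
}

#' @export
print.pseudo_markers <- function(x, ...) {
  cat("<pseudo_markers> ", nrow(x$M), " individuals x ", ncol(x$M),
      " haplotype alleles\n", sep = "")
  invisible(x)
}

# metadata for a block interval: map span and gene overlap
block_meta <- function(chrom, s, e, map, gene_track) {
  n_genes <- NA_real_
  if (!is.null(gene_track)) {
    g <- gene_track[gene_track$chrom == chrom, , drop = FALSE]
    # block bp span, half-open [bp_start - 1, bp_end)
    bs <- map$bp[s] - 1L; be <- map$bp[e]
    n_genes <- sum(g$start < be & g$end > bs)
  }
  data.frame(chrom = chrom, start_idx = s, end_idx = e,
             n_snps = e - s + 1,
             cM_span = map$cM[e] - map$cM[s],
             n_genes = n_genes)
}

#' Encode haplotype alleles as pseudo-markers
#'
#' Partition mode (a [block_partition()]): one column per distinct
#' observed allele sequence per block; the entry is the count of the
#' individual's gametes carrying that sequence. Library mode (a
#' [hap_library()]): one column per block; the entry is the number of the
#' individual's gametes in the block's carrier set.
#'
#' @param x a [block_partition()] or [hap_library()].
#' @param gametes a [gamete_set()] (complete over the blocks).
#' @param individuals individual ids to encode (default: all in
#'   `gametes`). Gametes of other individuals still define library
#'   carrier sets but get no row.
#' @param gene_track optional BED-style gene intervals (`chrom`, `start`,
#'   `end`, half-open) used to fill the per-column gene counts.
#' @return a [pseudo_markers()] object.
#' @export
encode_alleles <- function(x, gametes, individuals = NULL, gene_track = NULL) {
  UseMethod("encode_alleles")
}

#' @export
encode_alleles.block_partition <- function(x, gametes, individuals = NULL,
                                           gene_track = NULL) {
  X <- gametes$alleles
  if (anyNA(X)) stop("encode_alleles requires complete data")
  ids <- individuals %||% individuals(gametes)
  keep <- gametes$gamete_individual %in% ids
  X <- X[keep, , drop = FALSE]
  gind <- gametes$gamete_individual[keep]
  map <- gametes$map
  cols <- list(); meta <- list()
  bl <- x$blocks
  for (r in seq_len(nrow(bl))) {
    s <- bl$start_idx[r]; e <- bl$end_idx[r]
    key <- apply(X[, s:e, drop = FALSE], 1, paste, collapse = "")
    key_f <- factor(key)
    # count gametes per individual per allele
    counts <- table(factor(gind, levels = ids), key_f)
    m <- block_meta(bl$chrom[r], s, e, map, gene_track)
    for (a in seq_along(levels(key_f))) {
      cols[[length(cols) + 1]] <- as.numeric(counts[, a])
      meta[[length(meta) + 1]] <- cbind(
        block = r, allele = levels(key_f)[a], m, row.names = NULL)
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- ids
  info <- do.call(rbind, meta)
  colnames(M) <- paste0("b", info$block, "_", info$allele)
  pseudo_markers(M, info)
}

#' @export
encode_alleles.hap_library <- function(x, gametes, individuals = NULL,
                                       gene_track = NULL) {
  ids <- individuals %||% individuals(gametes)
  gid <- rownames(gametes$alleles)
  gind <- stats::setNames(gametes$gamete_individual, gid)
  map <- gametes$map
  nb <- length(x$blocks)
  M <- matrix(0, length(ids), nb, dimnames = list(ids, NULL))
  meta <- vector("list", nb)
  for (k in seq_len(nb)) {
    b <- x$blocks[[k]]
    carr_ind <- gind[intersect(b$carriers, gid)]
    tab <- table(factor(carr_ind, levels = ids))
    M[, k] <- as.numeric(tab)
    meta[[k]] <- cbind(block = k,
                       allele = paste(b$alleles, collapse = ""),
                       block_meta(b$chrom, b$start_idx, b$end_idx, map,
                                  gene_track), row.names = NULL)
  }
  info <- do.call(rbind, meta)
  colnames(M) <- paste0("hb", seq_len(nb))
  pseudo_markers(M, info)
}

#' Drop singleton haplotype alleles
#'
#' Removes columns carried by exactly one individual within the defined
#' analysis population (entry > 0 counts as carrying, so one individual
#' at dosage 2 is still a singleton, while two individuals at dosage 1
#' are not).
#'
#' @param pm a [pseudo_markers()] object.
#' @param population individual ids defining the population in which
#'   singletons are counted (default: all rows). Individuals outside
#'   this set (e.g. a capture line included only for construction) do
#'   not rescue a column.
#' @return the filtered `pseudo_markers`.
#' @export
drop_singletons <- function(pm, population = NULL) {
  stopifnot(inherits(pm, "pseudo_markers"))
  pop <- population %||% rownames(pm$M)
  carriers <- colSums(pm$M[pop, , drop = FALSE] > 0)
  keep <- carriers != 1
  pseudo_markers(pm$M[, keep, drop = FALSE], pm$info[keep, , drop = FALSE])
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = (X - 2P)(X - 2P)' / (2 sum_j p_j (1 - p_j))` with `p_j` the
#' observed allele (or haplotype-allele) frequency, i.e. half the column
#' mean of the 0/1/2 dosage matrix. Monomorphic columns contribute
#' nothing to either numerator or denominator.
#'
#' @param X dosage matrix (individuals x markers, entries 0/1/2) or a
#'   [pseudo_markers()] object.
#' @param kind tag stored on the result (`"SNP"`, `"haplotype"`, ...).
#' @return symmetric n x n matrix with attribute `kind`.
#' @export
grm_vanraden <- function(X, kind = "SNP") {
  if (inherits(X, "pseudo_markers")) X <- X$M
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 individuals")
  if (ncol(X) < 1) stop("no marker columns")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all columns monomorphic: GRM denominator is zero")
  Z <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly])
  G <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(G) <- list(rownames(X), rownames(X))
  attr(G, "kind") <- kind
  G
}

#' Weighted haplotype genomic relationship matrix
#'
#' `G = (X - 2P) W (X - 2P)' / (2 sum_j w_j p_j (1 - p_j))` with `W` the
#' diagonal of the column weights normalized to mean 1. With equal
#' weights this reduces exactly to [grm_vanraden()].
#'
#' @param X dosage matrix or [pseudo_markers()].
#' @param weights non-negative weight per column, not all zero.
#' @param kind tag stored on the result.
#' @return symmetric n x n matrix.
#' @export
grm_weighted <- function(X, weights, kind = "weighted") {
  if (inherits(X, "pseudo_markers")) X <- X$M
  X <- as.matrix(X)
  stopifnot(length(weights) == ncol(X))
  if (any(weights < 0)) stop("negative weight")
  if (all(weights == 0)) stop("all weights zero")
  w <- weights / mean(weights)
  p <- colMeans(X) / 2
  use <- p > 0 & p < 1 & w > 0
  if (!any(use)) stop("no informative weighted columns")
  denom <- 2 * sum(w[use] * p[use] * (1 - p[use]))
  Z <- sweep(X[, use, drop = FALSE], 2, 2 * p[use])
  G <- Z %*% (w[use] * t(Z)) / denom
  dimnames(G) <- list(rownames(X), rownames(X))
  attr(G, "kind") <- kind
  G
}

#' Column weights from haplotype metadata
#'
#' Weights each haplotype-allele column by its length on the linkage map
#' (`cM_length`), the number of genes its block overlaps (`n_genes`) or
#' its SNP count (`n_snps`). Zero cM spans (single-SNP blocks) are
#' floored at the minimum positive observed span so no column drops out
#' by accident of map resolution.
#'
#' @param info the `info` metadata of a [pseudo_markers()] object.
#' @param mode one of `"cM_length"`, `"n_genes"`, `"n_snps"`.
#' @return numeric weight vector, one per column.
#' @export
haplotype_weights <- function(info, mode = c("cM_length", "n_genes", "n_snps")) {
  mode <- match.arg(mode)
  w <- switch(mode,
    cM_length = {
      v <- info$cM_span
      pos <- v[v > 0]
      if (!length(pos)) stop("all cM spans are zero")
      v[v == 0] <- min(pos)
      v
    },
    n_genes = {
      v <- info$n_genes
      if (anyNA(v)) stop("gene counts missing: encode with a gene track")
      if (all(v == 0)) stop("gene track overlaps no block: all-zero weights")
      v
    },
    n_snps = info$n_snps)
  as.numeric(w)
}
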