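#' Haplotype library (IBD-based blocks with carriers)
#'
#' A haplotype block here is a chromosome interval together with the
#' allele sequence over it and the set of gametes that carry that exact
#' sequence; its "cells" are `(SNP length) x (carrier count)`, the share
#' of the gamete-by-SNP matrix it explains. The library is a collection
#' of such blocks with coverage bookkeeping. Construction follows the
#' window-cluster / exact-match-extension scheme of IBD block finders:
#' it reproduces the parameter semantics (window size, minimum cell
#' count, target coverage, minimum subgroup occurrence) rather than any
#' particular program's internal heuristics, and only error-free (exact
#' match) merging is supported.
#'
#' @param blocks list of blocks; each a list with `chrom`, `start_idx`,
#'   `end_idx` (1-based inclusive), `alleles` (integer vector) and
#'   `carriers` (character vector of gamete ids).
#' @param params list of construction parameters.
#' @param n_gametes,n_snp dimensions of the gamete matrix the library was
#'   built on (for coverage).
#' @param gamete_ids gamete ids in matrix order.
#' @return an object of class `hap_library`.
#' @export
hap_library <- function(blocks, params, n_gametes, n_snp, gamete_ids) {
  lib <- structure(list(blocks = blocks, params = params,
                        n_gametes = n_gametes, n_snp = n_snp,
                        gamete_ids = gamete_ids),
                   class = "hap_library")
  lib$coverage <- library_coverage(lib)
  lib
}

#' @export
print.hap_library <- function(x, ...) {
  cells <- vapply(x$blocks, block_cells, numeric(1))
  cat("<hap_library> ", length(x$blocks), " blocks, coverage ",
      signif(x$coverage, 4), sep = "")
  if (length(cells)) cat(", median cells ", stats::median(cells), sep = "")
  cat("\n")
  invisible(x)
}

block_cells <- function(b) (b$end_idx - b$start_idx + 1) * length(b$carriers)

#' Genome coverage of a haplotype library
#'
#' Fraction of gamete-by-SNP cells covered by at least one block.
#'
#' @param lib a [hap_library()].
#' @return coverage in `[0, 1]`.
#' @export
library_coverage <- function(lib) {
  if (!length(lib$blocks)) return(0)
  M <- matrix(FALSE, lib$n_gametes, lib$n_snp,
              dimnames = list(lib$gamete_ids, NULL))
  for (b in lib$blocks)
    M[b$carriers, b$start_idx:b$end_idx] <- TRUE
  mean(M)
}

#' Seed clusters from identical window haplotypes
#'
#' Splits each chromosome into consecutive windows of `w` SNPs (a short
#' tail window is kept) and groups gametes by their exact allele sequence
#' within each window. Each group is a seed block.
#'
#' @param gametes a [gamete_set()] (complete).
#' @param w window size in SNPs (>= 1).
#' @return list of seed blocks (same shape as [hap_library()] blocks).
#' @export
window_clusters <- function(gametes, w) {
  stopifnot(w >= 1)
  w <- as.integer(w)
  X <- gametes$alleles
  if (anyNA(X)) stop("window_clusters requires complete data")
  map <- gametes$map
  ids <- rownames(X)
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    starts <- as.integer(seq(idx[1], idx[length(idx)], by = w))
    for (s in starts) {
      e <- min(s + w - 1L, idx[length(idx)])
      key <- apply(X[, s:e, drop = FALSE], 1, paste, collapse = "")
      for (k in unique(key)) {
        carriers <- ids[key == k]
        out[[length(out) + 1]] <- list(
          chrom = ch, start_idx = s, end_idx = e,
          alleles = X[carriers[1], s:e], carriers = carriers)
      }
    }
  }
  out
}

# extend one block over the chromosome while all carriers agree
extend_one <- function(b, X, chrom_range) {
  s <- b$start_idx; e <- b$end_idx
  rows <- b$carriers
  while (s > chrom_range[1]) {
    col <- X[rows, s - 1L]
    if (all(col == col[1])) s <- s - 1L else break
  }
  while (e < chrom_range[2]) {
    col <- X[rows, e + 1L]
    if (all(col == col[1])) e <- e + 1L else break
  }
  b$start_idx <- s; b$end_idx <- e
  b$alleles <- X[rows[1], s:e]
  b
}

#' Extend and consolidate seed blocks
#'
#' Each seed block is extended one SNP at a time to the left and right
#' while all its carriers agree on the next allele (exact matching; the
#' only supported merging error is 0). Duplicates (same interval and
#' allele sequence) are collapsed, and blocks whose carrier set equals
#' that of a strictly longer block containing them are removed.
#'
#' @param clusters seed blocks from [window_clusters()].
#' @param gametes the same [gamete_set()].
#' @param merging_error must be 0; exact matching only.
#' @return list of candidate blocks.
#' @export
extend_blocks <- function(clusters, gametes, merging_error = 0) {
  if (merging_error != 0)
    stop("unsupported parameter: only merging_error = 0 (exact match) is implemented")
  X <- gametes$alleles
  map <- gametes$map
  ranges <- lapply(unique(map$chrom), function(ch) range(which(map$chrom == ch)))
  names(ranges) <- unique(map$chrom)
  ext <- lapply(clusters, function(b) extend_one(b, X, ranges[[b$chrom]]))
  dedup_blocks(ext)
}

# collapse duplicates, then drop blocks nested inside a longer block with
# an identical carrier set
dedup_blocks <- function(blocks) {
  if (!length(blocks)) return(blocks)
  key <- vapply(blocks, function(b)
    paste(b$chrom, b$start_idx, b$end_idx,
          paste(b$alleles, collapse = ""), sep = "|"), character(1))
  blocks <- blocks[!duplicated(key)]
  ckey <- vapply(blocks, function(b)
    paste(sort(b$carriers), collapse = ","), character(1))
  len <- vapply(blocks, function(b) b$end_idx - b$start_idx + 1, numeric(1))
  keep <- rep(TRUE, length(blocks))
  for (grp in split(seq_along(blocks), ckey)) {
    if (length(grp) < 2) next
    for (i in grp) for (j in grp) {
      if (i == j || !keep[i]) next
      bi <- blocks[[i]]; bj <- blocks[[j]]
      if (bi$chrom == bj$chrom && len[j] > len[i] &&
          bj$start_idx <= bi$start_idx && bj$end_idx >= bi$end_idx)
        keep[i] <- FALSE
    }
  }
  blocks <- blocks[keep]
  ord <- order(vapply(blocks, `[[`, character(1), "chrom"),
               vapply(blocks, `[[`, numeric(1), "start_idx"),
               vapply(blocks, `[[`, numeric(1), "end_idx"),
               vapply(blocks, function(b) paste(b$alleles, collapse = ""),
                      character(1)))
  blocks[ord]
}

#' Filter blocks by minimum cell count (MCMB)
#'
#' Keeps blocks whose cells (SNP length times carrier count) reach
#' `mcmb`; lower values keep more blocks and give higher genome
#' coverage.
#'
#' @param blocks candidate blocks (or a [hap_library()]).
#' @param mcmb minimum cell count (>= 1).
#' @param gametes the gamete set the blocks were built on (for coverage
#'   bookkeeping when `blocks` is a plain list).
#' @param params parameter list stored on the result.
#' @return a [hap_library()] of the surviving blocks.
#' @export
filter_mcmb <- function(blocks, mcmb, gametes = NULL, params = list()) {
  stopifnot(mcmb >= 1)
  if (inherits(blocks, "hap_library")) {
    lib <- blocks
    keep <- vapply(lib$blocks, block_cells, numeric(1)) >= mcmb
    return(hap_library(lib$blocks[keep], utils::modifyList(lib$params, list(mcmb = mcmb)),
                       lib$n_gametes, lib$n_snp, lib$gamete_ids))
  }
  stopifnot(!is.null(gametes))
  keep <- vapply(blocks, block_cells, numeric(1)) >= mcmb
  hap_library(blocks[keep], utils::modifyList(params, list(mcmb = mcmb)),
              n_gametes(gametes), n_snps(gametes), rownames(gametes$alleles))
}

#' Filter blocks by minimum occurrence in every subgroup
#'
#' Keeps blocks whose carrier count within every predefined subgroup
#' (e.g. the training and prediction populations) is at least
#' `threshold`, retaining only haplotypes shared across subgroups.
#' `threshold = 0` leaves the library unchanged.
#'
#' @param library a [hap_library()].
#' @param subgroup_labels named character vector: subgroup per gamete id
#'   (must cover every carrier).
#' @param threshold minimum carrier count per subgroup (>= 0).
#' @return the filtered [hap_library()].
#' @export
filter_min_subgroup <- function(library, subgroup_labels, threshold) {
  stopifnot(inherits(library, "hap_library"), threshold >= 0)
  if (threshold == 0) return(library)
  groups <- unique(subgroup_labels)
  keep <- vapply(library$blocks, function(b) {
    lab <- subgroup_labels[b$carriers]
    if (anyNA(lab)) stop("unknown subgroup label for carrier gamete(s)")
    all(vapply(groups, function(g) sum(lab == g), numeric(1)) >= threshold)
  }, logical(1))
  hap_library(library$blocks[keep],
              utils::modifyList(library$params, list(min_subgroup = threshold)),
              library$n_gametes, library$n_snp, library$gamete_ids)
}

#' Build an IBD-based haplotype library
#'
#' Pipeline: [window_clusters()] then [extend_blocks()] (with
#' `multi_window = TRUE` the union of candidates over window sizes 5, 10,
#' 20 and 50, deduplicated), then the minimum-subgroup filter, then the
#' cell-count filter. Exactly one of `mcmb` and `target_coverage` drives
#' the final filtering: with a target, the cell-count threshold is found
#' by bisection over the sorted distinct cell counts so that the achieved
#' coverage is the smallest coverage at or above the target
#' (deterministic). If even a threshold of 1 cannot reach the target, the
#' threshold-1 library is returned with `unreachable = TRUE` in its
#' parameters and a warning.
#'
#' @param gametes a [gamete_set()] (phased, complete).
#' @param w window size in SNPs; ignored when `multi_window = TRUE`.
#' @param multi_window use window sizes {5, 10, 20, 50} simultaneously.
#' @param mcmb minimum cell count (default 5000); ignored when
#'   `target_coverage` is given.
#' @param target_coverage desired genome coverage in `(0, 1)`, or `NULL`.
#' @param subgroups optional named character vector (subgroup per gamete
#'   id) for the minimum-subgroup filter.
#' @param min_subgroup minimum carrier count per subgroup (default 0).
#' @return a [hap_library()].
#' @export
build_library <- function(gametes, w = 20, multi_window = FALSE,
                          mcmb = 5000, target_coverage = NULL,
                          subgroups = NULL, min_subgroup = 0) {
  if (!is.null(target_coverage))
    stopifnot(target_coverage > 0, target_coverage < 1)
  ws <- if (multi_window) c(5, 10, 20, 50) else w
  cand <- list()
  for (wi in ws)
    cand <- c(cand, extend_blocks(window_clusters(gametes, wi), gametes))
  cand <- dedup_blocks(cand)
  params <- list(w = if (multi_window) ws else w, multi_window = multi_window,
                 min_subgroup = min_subgroup)
  lib_all <- hap_library(cand, params, n_gametes(gametes), n_snps(gametes),
                         rownames(gametes$alleles))
  if (min_subgroup > 0) {
    if (is.null(subgroups))
      stop("min_subgroup > 0 needs subgroup labels")
    lib_all <- filter_min_subgroup(lib_all, subgroups, min_subgroup)
  }
  if (is.null(target_coverage))
    return(filter_mcmb(lib_all, mcmb))
  cells <- sort(unique(vapply(lib_all$blocks, block_cells, numeric(1))))
  cands <- unique(c(1, cells))
  cov_at <- function(mc) filter_mcmb(lib_all, mc)$coverage
  if (cov_at(1) < target_coverage) {
    warning("target coverage ", target_coverage,
            " unreachable; returning mcmb = 1 library")
    out <- filter_mcmb(lib_all, 1)
    out$params$unreachable <- TRUE
    out$params$target_coverage <- target_coverage
    return(out)
  }
  # coverage is non-increasing in the threshold: find the largest
  # candidate whose coverage still reaches the target
  lo <- 1; hi <- length(cands)
  while (lo < hi) {
    mid <- (lo + hi + 1) %/% 2
    if (cov_at(cands[mid]) >= target_coverage) lo <- mid else hi <- mid - 1
  }
  out <- filter_mcmb(lib_all, cands[lo])
  out$params$unreachable <- FALSE
  out$params$target_coverage <- target_coverage
  out
}

#' Export a haplotype library as a table
#'
#' @param lib a [hap_library()].
#' @param subgroups optional named character vector of subgroup labels
#'   per gamete id; adds per-subgroup carrier counts.
#' @param path optional TSV path; the parameter list is written alongside
#'   as `<path>.json` when jsonlite is available.
#' @return data.frame, one row per block.
#' @export
library_to_table <- function(lib, subgroups = NULL, path = NULL) {
  b <- lib$blocks
  out <- data.frame(
    chrom = vapply(b, `[[`, character(1), "chrom"),
    start_idx = vapply(b, `[[`, numeric(1), "start_idx"),
    end_idx = vapply(b, `[[`, numeric(1), "end_idx"),
    alleles = vapply(b, function(x) paste(x$alleles, collapse = ""), character(1)),
    n_carriers = vapply(b, function(x) length(x$carriers), numeric(1)),
    cells = vapply(b, block_cells, numeric(1)))
  if (!is.null(subgroups)) {
    for (g in unique(subgroups))
      out[[paste0("n_", g)]] <- vapply(b, function(x)
        sum(subgroups[x$carriers] == g, na.rm = TRUE), numeric(1))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(lib$params, paste0(path, ".json"), auto_unbox = TRUE)
  }
  out
}
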