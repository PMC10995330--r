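#' Phased gamete set
#'
#' The universal genotype substrate of the package: a binary gametes x SNPs
#' allele matrix together with a genetic map and the bookkeeping that ties
#' gametes to individuals and individuals to populations. Every individual
#' owns exactly two gametes (a doubled haploid line owns two identical
#' copies of its single gamete). Optionally a parallel character matrix of
#' founder origins is carried along, which the simulator fills in so that
#' identity-by-descent can be audited and founder-origin QTL models scored.
#'
#' @param alleles integer/numeric matrix, gametes in rows (rownames are
#'   gamete ids), SNPs in columns; entries 0/1 (NA allowed only for data
#'   read from files, never for simulated data).
#' @param map data.frame with columns `chrom`, `bp`, `cM`; one row per SNP
#'   column of `alleles`. Within a chromosome `bp` and `cM` must be
#'   strictly increasing.
#' @param gamete_individual character vector, the individual id owning each
#'   gamete (length `nrow(alleles)`).
#' @param individual_population named character vector mapping individual
#'   ids to population labels.
#' @param origin optional character matrix, same shape as `alleles`, giving
#'   the founder origin of every allele.
#'
#' @return An object of class `gamete_set`.
#' @export
gamete_set <- function(alleles, map, gamete_individual, individual_population,
                       origin = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  validate_map(map)
  if (ncol(alleles) != nrow(map))
    stop("allele matrix has ", ncol(alleles), " columns but map has ",
         nrow(map), " markers")
  if (length(gamete_individual) != nrow(alleles))
    stop("gamete_individual must have one entry per gamete")
  ok <- is.na(alleles) | alleles == 0L | alleles == 1L
  if (!all(ok)) stop("allele entries must be 0/1 (or NA)")
  tab <- table(gamete_individual)
  if (any(tab != 2L))
    stop("every individual must own exactly 2 gametes; offending: ",
         paste(names(tab)[tab != 2L][seq_len(min(3, sum(tab != 2L)))],
               collapse = ", "))
  inds <- unique(gamete_individual)
  missing_pop <- setdiff(inds, names(individual_population))
  if (length(missing_pop))
    stop("no population label for individual(s): ",
         paste(utils::head(missing_pop, 3), collapse = ", "))
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0(gamete_individual, c("_a", "_b"))
  if (!is.null(origin)) {
    origin <- as.matrix(origin)
    stopifnot(all(dim(origin) == dim(alleles)))
    rownames(origin) <- rownames(alleles)
  }
  structure(
    list(alleles = alleles, map = map,
         gamete_individual = as.character(gamete_individual),
         individual_population = individual_population[inds],
         origin = origin),
    class = "gamete_set")
}

validate_map <- function(map) {
  if (!is.data.frame(map) || !all(c("chrom", "bp", "cM") %in% names(map)))
    stop("map must be a data.frame with columns chrom, bp, cM")
  if (nrow(map) == 0L) stop("map is empty")
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (any(diff(m$bp) <= 0) || any(diff(m$cM) <= 0))
      stop("map positions must be strictly increasing within chromosome ", ch)
  }
  invisible(map)
}

#' @export
print.gamete_set <- function(x, ...) {
  cat("<gamete_set> ", nrow(x$alleles), " gametes (",
      length(x$individual_population), " individuals), ",
      ncol(x$alleles), " SNPs on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  pops <- table(x$individual_population)
  cat("  populations:",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Individuals of a gamete set
#' @param gs a `gamete_set`.
#' @return character vector of individual ids (in gamete order).
#' @export
individuals <- function(gs) unique(gs$gamete_individual)

#' Number of gametes / SNPs
#' @param gs a `gamete_set`.
#' @export
n_gametes <- function(gs) nrow(gs$alleles)

#' @rdname n_gametes
#' @export
n_snps <- function(gs) ncol(gs$alleles)

#' Subset a gamete set by individuals
#'
#' @param gs a `gamete_set`.
#' @param ids individual ids to keep (order preserved as given).
#' @return a `gamete_set` restricted to those individuals.
#' @export
subset_individuals <- function(gs, ids) {
  stopifnot(all(ids %in% individuals(gs)))
  keep <- which(gs$gamete_individual %in% ids)
  keep <- keep[order(match(gs$gamete_individual[keep], ids))]
  gamete_set(gs$alleles[keep, , drop = FALSE], gs$map,
             gs$gamete_individual[keep],
             gs$individual_population[ids],
             origin = if (!is.null(gs$origin)) gs$origin[keep, , drop = FALSE])
}

#' Merge gamete sets sharing a map
#'
#' Concatenates the gametes of two or more sets defined on the same map
#' (same chromosomes and positions). Individual ids must not collide.
#'
#' @param ... `gamete_set` objects.
#' @return a merged `gamete_set`.
#' @export
merge_gamete_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "gamete_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  map <- sets[[1]]$map
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$map[c("chrom", "bp", "cM")],
                          map[c("chrom", "bp", "cM")],
                          check.attributes = FALSE)))
      stop("gamete sets are defined on different maps")
  }
  ids <- unlist(lapply(sets, individuals))
  if (anyDuplicated(ids)) stop("individual ids collide across sets")
  has_origin <- all(vapply(sets, function(s) !is.null(s$origin), logical(1)))
  gamete_set(
    do.call(rbind, lapply(sets, `[[`, "alleles")), map,
    unlist(lapply(sets, `[[`, "gamete_individual")),
    do.call(c, lapply(sets, `[[`, "individual_population")),
    origin = if (has_origin) do.call(rbind, lapply(sets, `[[`, "origin")))
}

#' Subset a gamete set by marker index
#'
#' @param gs a `gamete_set`.
#' @param keep integer or logical index over markers.
#' @return a `gamete_set` restricted to those markers.
#' @export
subset_markers <- function(gs, keep) {
  gamete_set(gs$alleles[, keep, drop = FALSE], gs$map[keep, , drop = FALSE],
             gs$gamete_individual, gs$individual_population,
             origin = if (!is.null(gs$origin)) gs$origin[, keep, drop = FALSE])
}

#' Individual-level allele dosages
#'
#' Sums the two gametes of each individual into a 0/1/2 dosage matrix.
#'
#' @param gs a `gamete_set`.
#' @return numeric matrix, individuals x SNPs.
#' @export
dosage_matrix <- function(gs) {
  d <- rowsum(gs$alleles, group = gs$gamete_individual, reorder = FALSE)
  d[individuals(gs), , drop = FALSE]
}
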