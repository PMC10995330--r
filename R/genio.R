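#' Raw genotype calls
#'
#' Individual-level 0/1/2 dosage calls with missing values allowed, plus
#' the marker map. This is the substrate of the QC filters; phased data
#' enter as a [gamete_set()] and can be collapsed with
#' [as_raw_genotypes()].
#'
#' @param calls numeric matrix individuals x SNPs with entries 0, 1, 2 or
#'   NA; rownames are individual ids.
#' @param map marker map (`chrom`, `bp`, `cM`).
#' @return an object of class `raw_genotypes`.
#' @export
raw_genotypes <- function(calls, map) {
  calls <- as.matrix(calls)
  validate_map(map)
  stopifnot(ncol(calls) == nrow(map))
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) stop("calls must be 0/1/2 or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  structure(list(calls = calls, map = map), class = "raw_genotypes")
}

#' @export
print.raw_genotypes <- function(x, ...) {
  cat("<raw_genotypes> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " SNPs; missing rate ",
      signif(mean(is.na(x$calls)), 3), "\n", sep = "")
  invisible(x)
}

#' @rdname raw_genotypes
#' @param gs a `gamete_set`.
#' @export
as_raw_genotypes <- function(gs) {
  raw_genotypes(dosage_matrix(gs), gs$map)
}

#' Genotype quality filters
#'
#' Applies the study's QC rules in a fixed, documented order: (1) markers,
#' then individuals, with missing rate strictly above `max_missing` are
#' removed; (2) for doubled-haploid data (`dh = TRUE`) markers, then
#' individuals, with heterozygosity strictly above `max_het` are removed
#' and any residual heterozygous calls are set to missing. The function is
#' idempotent. Rates are always computed on the current (already filtered)
#' matrix.
#'
#' @param raw a [raw_genotypes()] object.
#' @param max_missing maximum tolerated missing rate (default 0.10).
#' @param max_het maximum tolerated heterozygosity for DH data
#'   (default 0.05).
#' @param dh logical; apply the heterozygosity rules (DH lines are
#'   expected to be fully homozygous).
#' @details The pass (missing-rate filter, then heterozygosity filter,
#'   then het-to-missing conversion) is repeated until nothing changes:
#'   converting residual het calls to missing can raise a marker's
#'   missing rate above the threshold, and iterating to the fixed point
#'   is what makes the filter idempotent.
#' @return the filtered `raw_genotypes`, with a `report` attribute: a
#'   data.frame of removed items (`item`, `dimension`, `reason`, `rate`).
#' @export
qc_filter <- function(raw, max_missing = 0.10, max_het = 0.05, dh = FALSE) {
  stopifnot(inherits(raw, "raw_genotypes"),
            max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1)
  X <- raw$calls
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  map <- raw$map
  rep_rows <- list()
  note <- function(items, dim, reason, rate) {
    if (length(items))
      rep_rows[[length(rep_rows) + 1]] <<- data.frame(
        item = items, dimension = dim, reason = reason, rate = rate)
  }
  repeat {
    changed <- FALSE
    # (1) missing rate: markers first, then individuals
    mr <- colMeans(is.na(X))
    drop <- mr > max_missing
    if (any(drop)) {
      note(colnames(X)[drop], "marker", "missing_rate", mr[drop])
      X <- X[, !drop, drop = FALSE]; map <- map[!drop, , drop = FALSE]
      changed <- TRUE
    }
    if (ncol(X) == 0) stop("all markers removed by the missing-rate filter")
    mr <- rowMeans(is.na(X))
    drop <- mr > max_missing
    if (any(drop)) {
      note(rownames(X)[drop], "individual", "missing_rate", mr[drop])
      X <- X[!drop, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(X) == 0) stop("all individuals removed by QC")
    # (2) heterozygosity (DH only): markers, then individuals, then het -> NA
    if (dh) {
      het <- colMeans(X == 1, na.rm = TRUE)
      het[is.nan(het)] <- 0
      drop <- het > max_het
      if (any(drop)) {
        note(colnames(X)[drop], "marker", "heterozygosity", het[drop])
        X <- X[, !drop, drop = FALSE]; map <- map[!drop, , drop = FALSE]
        changed <- TRUE
      }
      if (ncol(X) == 0) stop("all markers removed by the heterozygosity filter")
      het <- rowMeans(X == 1, na.rm = TRUE)
      het[is.nan(het)] <- 0
      drop <- het > max_het
      if (any(drop)) {
        note(rownames(X)[drop], "individual", "heterozygosity", het[drop])
        X <- X[!drop, , drop = FALSE]
        changed <- TRUE
      }
      if (nrow(X) == 0) stop("all individuals removed by QC")
      if (any(X == 1, na.rm = TRUE)) {
        X[X == 1] <- NA
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- raw_genotypes(X, map)
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(item = character(), dimension = character(),
               reason = character(), rate = numeric())
  attr(out, "report") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep polymorphic markers
#'
#' Removes markers at which only a single allele is observed among the
#' non-missing calls. A marker with a single carrier of the minor allele
#' is polymorphic and kept (rare-allele filtering happens at the
#' haplotype-allele level, not here).
#'
#' @param x a [raw_genotypes()] or [gamete_set()].
#' @return the same class of object with monomorphic markers dropped.
#' @export
keep_polymorphic <- function(x) UseMethod("keep_polymorphic")

#' @export
keep_polymorphic.raw_genotypes <- function(x) {
  X <- x$calls
  # a het call observes both alleles
  has0 <- colSums(X == 0, na.rm = TRUE) > 0 | colSums(X == 1, na.rm = TRUE) > 0
  has1 <- colSums(X == 2, na.rm = TRUE) > 0 | colSums(X == 1, na.rm = TRUE) > 0
  keep <- has0 & has1
  raw_genotypes(X[, keep, drop = FALSE], x$map[keep, , drop = FALSE])
}

#' @export
keep_polymorphic.gamete_set <- function(x) {
  A <- x$alleles
  keep <- colSums(A == 0, na.rm = TRUE) > 0 & colSums(A == 1, na.rm = TRUE) > 0
  gamete_set(A[, keep, drop = FALSE], x$map[keep, , drop = FALSE],
             x$gamete_individual, x$individual_population,
             origin = if (!is.null(x$origin)) x$origin[, keep, drop = FALSE])
}

#' Read a phased VCF into a gamete set
#'
#' Expects biallelic SNPs with phased GT fields (`a|b`). Homozygous
#' unphased calls (`0/0`, `1/1`) are accepted since their phase is
#' unambiguous; an unphased heterozygote is an error naming the sample
#' and site. Missing GTs become NA alleles. If the INFO field carries
#' `CM=<x>` the genetic position is recovered from it, otherwise cM
#' defaults to bp / 1e6 (1 cM per Mb).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param population optional named character vector of population labels
#'   per sample; defaults to `"unknown"` for all.
#' @return a [gamete_set()].
#' @export
read_phased_vcf <- function(path, population = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | nchar(fix[, "REF"]) != 1 | nchar(alt) != 1
  if (any(multi))
    stop("multi-allelic or non-SNP site(s): ",
         paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 3),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  m <- nrow(gt); n <- length(samples)
  a1 <- matrix(NA_integer_, n, m); a2 <- matrix(NA_integer_, n, m)
  for (s in seq_len(n)) {
    g <- gt[, s]
    miss <- is.na(g) | g %in% c(".", "./.", ".|.")
    unph <- !miss & grepl("/", g, fixed = TRUE)
    if (any(unph)) {
      ga <- substr(g[unph], 1, 1); gb <- substr(g[unph], 3, 3)
      badhet <- ga != gb
      if (any(badhet)) {
        w <- which(unph)[which(badhet)[1]]
        stop("unphased heterozygote for sample ", samples[s], " at site ",
             fix[w, "CHROM"], ":", fix[w, "POS"])
      }
    }
    a1[s, !miss] <- as.integer(substr(g[!miss], 1, 1))
    a2[s, !miss] <- as.integer(substr(g[!miss], 3, 3))
  }
  alleles <- matrix(NA_integer_, 2 * n, m)
  alleles[seq(1, 2 * n, 2), ] <- a1
  alleles[seq(2, 2 * n, 2), ] <- a2
  gam_ind <- rep(samples, each = 2)
  rownames(alleles) <- paste0(gam_ind, c("_a", "_b"))
  info <- v@fix[, "INFO"]
  cm <- suppressWarnings(as.numeric(sub("^.*CM=([0-9.eE+-]+).*$", "\\1", info)))
  bp <- as.integer(fix[, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], bp = bp,
                    cM = ifelse(is.na(cm), bp / 1e6, cm))
  if (is.null(population))
    population <- stats::setNames(rep("unknown", n), samples)
  gamete_set(alleles, map, gam_ind, population)
}

#' Write a gamete set as a phased VCF
#'
#' Emits a minimal VCFv4.2 with one sample per individual, `GT` fields
#' phased with `|`, REF/ALT fixed to A/C (the allele matrix is binary)
#' and the genetic position stored as `CM=` in INFO so that a
#' write-then-read round trip recovers the full map.
#'
#' @param gs a [gamete_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(gs, path) {
  ids <- individuals(gs)
  n <- length(ids); m <- n_snps(gs)
  rows1 <- match(ids, gs$gamete_individual)           # first gamete of each
  rows2 <- vapply(ids, function(i) which(gs$gamete_individual == i)[2], 1L)
  A1 <- gs$alleles[rows1, , drop = FALSE]
  A2 <- gs$alleles[rows2, , drop = FALSE]
  gtchr <- matrix(paste0(ifelse(is.na(A1), ".", A1), "|",
                         ifelse(is.na(A2), ".", A2)), nrow = n)
  gtchr[is.na(A1) & is.na(A2)] <- ".|."
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position (cM)\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c(gs$map$chrom[j], gs$map$bp[j], paste0("snp", j), "A", "C", ".",
            "PASS", paste0("CM=", format(gs$map$cM[j], digits = 10)), "GT",
            gtchr[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write small tabular side files
#'
#' Plain CSV readers and writers for the marker map (`chrom,bp,cM`),
#' phenotype tables (`individual,trait,value[,g_true,h2]`) and population
#' labels (`individual,population`), and BED3 for gene tracks (0-based
#' half-open intervals).
#'
#' @param x object to write.
#' @param path file path.
#' @name side_io
NULL

#' @rdname side_io
#' @export
write_map_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' @rdname side_io
#' @export
read_map_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_map(m)
  m
}

#' @rdname side_io
#' @export
write_phenotype_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' @rdname side_io
#' @export
read_phenotype_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname side_io
#' @export
write_bed <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' @rdname side_io
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(b[, 1:3], c("chrom", "start", "end"))
}
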