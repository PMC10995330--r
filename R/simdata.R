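#' Simulate a genetic map
#'
#' Marker positions are drawn once per chromosome: base-pair positions are
#' sorted draws without replacement from the physical length, centimorgan
#' positions are cumulated positive gaps rescaled to the chromosome's map
#' length, so both are strictly increasing by construction.
#'
#' @param n_chrom number of chromosomes.
#' @param n_snp total number of SNPs (split as evenly as possible).
#' @param cM_length map length per chromosome, centimorgan.
#' @param bp_length physical length per chromosome, base pairs.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `bp`, `cM`.
#' @export
sim_map <- function(n_chrom = 2, n_snp = 2000, cM_length = 150,
                    bp_length = 2e8, seed = 1) {
  stopifnot(n_chrom >= 1, n_snp >= 2)
  withr_seed(seed)
  per <- diff(round(seq(0, n_snp, length.out = n_chrom + 1)))
  maps <- lapply(seq_len(n_chrom), function(ch) {
    m <- per[ch]
    bp <- sort(sample.int(bp_length, m))
    gaps <- stats::runif(m)
    cM <- cumsum(gaps) / sum(gaps) * cM_length
    data.frame(chrom = paste0("chr", ch), bp = bp, cM = cM)
  })
  do.call(rbind, maps)
}

# Seed discipline: every user-facing sim op sets the RNG from its seed
# argument; internal helpers consume the current stream.
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate founder gametes of two divergent landraces
#'
#' Two labelled founder pools are generated. Per-landrace allele
#' frequencies follow the Balding-Nichols model around a shared ancestral
#' frequency with differentiation `divergence` (an F_ST-like parameter;
#' `divergence = 0` gives identical frequency vectors). Linkage
#' disequilibrium within chromosomes comes from a first-order Markov copy
#' process: the allele at marker j is correlated with the allele at
#' marker j-1 with correlation `exp(-ld_decay * d_cM)`, so LD decays
#' exponentially with map distance at rate `ld_decay` per cM.
#'
#' @param n_founders_per_landrace founders per landrace (>= 2); each
#'   founder is a (generally heterozygous) plant with two gametes.
#' @param n_snp number of SNPs when `map` is not supplied.
#' @param map optional marker map (see [sim_map()]); overrides `n_snp`.
#' @param divergence differentiation between the landraces, in `[0, 1)`.
#' @param ld_decay LD decay rate per cM (> 0); large values give linkage
#'   equilibrium.
#' @param labels character(2), population labels of the two landraces.
#' @param seed integer seed; same seed gives a bit-identical result.
#' @return a [gamete_set()] with both founder pools; founder origins are
#'   tracked (each founder gamete is its own origin).
#' @export
sim_founders <- function(n_founders_per_landrace = 35, n_snp = 2000,
                         map = NULL, divergence = 0.15, ld_decay = 1,
                         labels = c("KE", "PE"), seed = 1) {
  stopifnot(n_founders_per_landrace >= 2,
            divergence >= 0, divergence < 1, ld_decay > 0,
            length(labels) == 2)
  withr_seed(seed)
  if (is.null(map)) {
    if (n_snp < 2) stop("n_snp must be >= 2")
    map <- sim_map(n_snp = n_snp, seed = sample.int(2^31 - 1, 1))
  }
  validate_map(map)
  m <- nrow(map)
  anc <- stats::runif(m, 0.1, 0.9)
  freq_for <- function() {
    if (divergence == 0) return(anc)
    f <- divergence
    p <- stats::rbeta(m, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
    pmin(pmax(p, 0.01), 0.99)
  }
  draw_pool <- function(p, n_gam) {
    X <- matrix(0L, n_gam, m)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      x <- stats::rbinom(n_gam, 1L, p[idx[1]])
      X[, idx[1]] <- x
      for (k in seq_along(idx)[-1]) {
        j <- idx[k]; jm <- idx[k - 1]
        rho <- exp(-ld_decay * (map$cM[j] - map$cM[jm]))
        # conditional mean preserving marginal p_j and lag-1 correlation rho
        pj <- p[j] + rho * sqrt(p[j] * (1 - p[j]) /
                                  (p[jm] * (1 - p[jm]))) * (x - p[jm])
        x <- stats::rbinom(n_gam, 1L, pmin(pmax(pj, 0), 1))
        X[, j] <- x
      }
    }
    X
  }
  n_gam <- 2L * n_founders_per_landrace
  pools <- lapply(1:2, function(i) draw_pool(freq_for(), n_gam))
  alleles <- rbind(pools[[1]], pools[[2]])
  founder_ids <- c(paste0(labels[1], "_F", sprintf("%02d", seq_len(n_founders_per_landrace))),
                   paste0(labels[2], "_F", sprintf("%02d", seq_len(n_founders_per_landrace))))
  gam_ind <- rep(founder_ids, each = 2)
  gam_ids <- paste0(gam_ind, rep(c("_a", "_b"), length(founder_ids)))
  rownames(alleles) <- gam_ids
  origin <- matrix(rep(gam_ids, m), nrow = length(gam_ids))
  pop <- stats::setNames(rep(labels, each = n_founders_per_landrace), founder_ids)
  gamete_set(alleles, map, gam_ind, pop, origin = origin)
}

# Crossover mask for one meiosis: TRUE where the child copies parent a.
# Crossover counts are Poisson(cM length / 100) per chromosome, positions
# uniform on the map, no interference; the starting parent is fair.
crossover_mask <- function(map) {
  mask <- logical(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    lo <- map$cM[idx[1]]; hi <- map$cM[idx[length(idx)]]
    len <- hi - lo
    nx <- stats::rpois(1, len / 100)
    xpos <- sort(stats::runif(nx, lo, hi))
    start_a <- stats::runif(1) < 0.5
    nswitch <- findInterval(map$cM[idx], xpos)
    mask[idx] <- xor(start_a, nswitch %% 2 == 1)
  }
  mask
}

#' Simulate one meiosis
#'
#' Produces a recombinant gamete from two parental gametes under a
#' no-interference (Haldane) model: per chromosome the crossover count is
#' Poisson(map length / 100) with uniformly placed crossover positions on
#' the cM scale, and the starting parent is chosen with probability 1/2.
#'
#' @param gamete_a,gamete_b parental allele vectors (same length as map).
#' @param map marker map.
#' @param seed optional integer seed; `NULL` consumes the current RNG
#'   stream (used internally by the population simulators).
#' @return integer allele vector of the recombinant gamete.
#' @export
meiosis <- function(gamete_a, gamete_b, map, seed = NULL) {
  stopifnot(length(gamete_a) == nrow(map), length(gamete_b) == nrow(map))
  withr_seed(seed)
  mask <- crossover_mask(map)
  out <- ifelse(mask, gamete_a, gamete_b)
  storage.mode(out) <- storage.mode(gamete_a)
  out
}

# one meiosis applied jointly to alleles and (optional) origins
meiosis_tracked <- function(a, b, oa, ob, map) {
  mask <- crossover_mask(map)
  list(allele = as.integer(ifelse(mask, a, b)),
       origin = if (!is.null(oa)) ifelse(mask, oa, ob))
}

#' Simulate a doubled-haploid population
#'
#' Each DH line arises from one meiotic gamete of a random founder plant
#' (the S0 plant), duplicated by chromosome doubling into two identical
#' gametes, hence fully homozygous lines.
#'
#' @param founders a [gamete_set()] holding one landrace's founder pool
#'   (subset with [subset_individuals()] if needed).
#' @param n_lines number of DH lines (>= 1).
#' @param label population label of the derived lines.
#' @param prefix id prefix for the lines.
#' @param seed integer seed.
#' @return a `gamete_set` of `2 * n_lines` gametes with origins tracked
#'   when the founders carry them.
#' @export
sim_dh_population <- function(founders, n_lines, label = "DH",
                              prefix = label, seed = 1) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  withr_seed(seed)
  map <- founders$map
  f_ids <- individuals(founders)
  has_o <- !is.null(founders$origin)
  m <- nrow(map)
  alle <- matrix(0L, 2L * n_lines, m)
  orig <- if (has_o) matrix("", 2L * n_lines, m)
  for (i in seq_len(n_lines)) {
    f <- sample(f_ids, 1)
    rows <- which(founders$gamete_individual == f)
    g <- meiosis_tracked(founders$alleles[rows[1], ], founders$alleles[rows[2], ],
                         if (has_o) founders$origin[rows[1], ],
                         if (has_o) founders$origin[rows[2], ], map)
    alle[2 * i - 1, ] <- g$allele
    alle[2 * i, ] <- g$allele
    if (has_o) { orig[2 * i - 1, ] <- g$origin; orig[2 * i, ] <- g$origin }
  }
  ids <- paste0(prefix, "_", sprintf("%03d", seq_len(n_lines)))
  gam_ind <- rep(ids, each = 2)
  rownames(alle) <- paste0(gam_ind, rep(c("_a", "_b"), n_lines))
  gamete_set(alle, map, gam_ind,
             stats::setNames(rep(label, n_lines), ids), origin = orig)
}

#' Simulate a gamete-capture population
#'
#' Each GC line is produced by crossing a landrace S0 plant with the
#' inbred capture line FV2 and selfing once: F1 = (meiotic gamete of a
#' random founder pair) x (FV2 gamete); the line's phased genotype is two
#' meiotic gametes of that F1 (the S1 generation). The expected FV2
#' genome share per line is 50%.
#'
#' @param founders a [gamete_set()] with one landrace's founder pool.
#' @param fv2 a `gamete_set` holding the single inbred capture line
#'   (two identical gametes), on the same map.
#' @param n_lines number of GC lines.
#' @param label population label of the derived lines.
#' @param prefix id prefix.
#' @param seed integer seed.
#' @return a `gamete_set` of `2 * n_lines` phased gametes; origins are
#'   tracked (FV2 cells carry FV2's gamete origin labels).
#' @export
sim_gc_population <- function(founders, fv2, n_lines, label = "GC",
                              prefix = label, seed = 1) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  stopifnot(inherits(fv2, "gamete_set"))
  if (n_gametes(fv2) != 2L ||
      !identical(fv2$alleles[1, ], fv2$alleles[2, ]))
    stop("fv2 must be a single inbred line: two identical gametes")
  withr_seed(seed)
  map <- founders$map
  f_ids <- individuals(founders)
  has_o <- !is.null(founders$origin)
  fv2_gam <- fv2$alleles[1, ]
  fv2_orig <- if (has_o) {
    if (!is.null(fv2$origin)) fv2$origin[1, ] else rep("FV2", nrow(map))
  }
  m <- nrow(map)
  alle <- matrix(0L, 2L * n_lines, m)
  orig <- if (has_o) matrix("", 2L * n_lines, m)
  for (i in seq_len(n_lines)) {
    f <- sample(f_ids, 1)
    rows <- which(founders$gamete_individual == f)
    s0 <- meiosis_tracked(founders$alleles[rows[1], ], founders$alleles[rows[2], ],
                          if (has_o) founders$origin[rows[1], ],
                          if (has_o) founders$origin[rows[2], ], map)
    for (k in 1:2) {
      g <- meiosis_tracked(s0$allele, fv2_gam, s0$origin, fv2_orig, map)
      alle[2 * i - 2 + k, ] <- g$allele
      if (has_o) orig[2 * i - 2 + k, ] <- g$origin
    }
  }
  ids <- paste0(prefix, "_", sprintf("%03d", seq_len(n_lines)))
  gam_ind <- rep(ids, each = 2)
  rownames(alle) <- paste0(gam_ind, rep(c("_a", "_b"), n_lines))
  gamete_set(alle, map, gam_ind,
             stats::setNames(rep(label, n_lines), ids), origin = orig)
}

#' Build an inbred capture line from an allele vector
#'
#' @param alleles 0/1 vector over the map's markers.
#' @param map marker map.
#' @param id individual id (default `"FV2"`).
#' @return a `gamete_set` with one individual and two identical gametes;
#'   every cell's origin is the line's gamete id.
#' @export
make_inbred_line <- function(alleles, map, id = "FV2") {
  alle <- rbind(alleles, alleles)
  gam_ids <- paste0(id, c("_a", "_b"))
  rownames(alle) <- gam_ids
  origin <- matrix(rep(gam_ids[1], 2L * length(alleles)), nrow = 2)
  gamete_set(alle, map, rep(id, 2), stats::setNames(id, id), origin = origin)
}

#' Define a QTL architecture
#'
#' Two modes are supported. `additive_snp` attaches an additive effect to
#' the 0/1/2 dosage at each QTL marker. `founder_haplotype` attaches an
#' effect to the founder origin of each gamete at the QTL position, i.e.
#' the causal variable is the ancestral (IBD) segment rather than any
#' individual SNP; haplotype-based predictors can recover this signal
#' where single SNPs only tag it.
#'
#' @param positions marker indices of the QTL.
#' @param effects for `additive_snp`: numeric vector, one per QTL. For
#'   `founder_haplotype`: a list, one element per QTL, each a named
#'   numeric vector of effects keyed by founder-origin label.
#' @param mode `"additive_snp"` or `"founder_haplotype"`.
#' @return a `qtl_model` object.
#' @export
qtl_model <- function(positions, effects,
                      mode = c("additive_snp", "founder_haplotype")) {
  mode <- match.arg(mode)
  positions <- as.integer(positions)
  if (mode == "additive_snp") {
    stopifnot(is.numeric(effects), length(effects) == length(positions),
              all(is.finite(effects)))
  } else {
    stopifnot(is.list(effects), length(effects) == length(positions))
    lapply(effects, function(e) stopifnot(is.numeric(e), !is.null(names(e)),
                                          all(is.finite(e))))
  }
  structure(list(mode = mode, positions = positions, effects = effects),
            class = "qtl_model")
}

#' Draw a random QTL architecture
#'
#' QTL positions are sampled uniformly over markers; effects are standard
#' normal. In `founder_haplotype` mode one effect is drawn per founder
#' gamete origin (and, if given, the capture line's origin) per QTL.
#'
#' @param gs a `gamete_set` (for marker count and, in founder mode, the
#'   origin labels to cover).
#' @param n_qtl number of QTL.
#' @param mode QTL mode, see [qtl_model()].
#' @param seed integer seed.
#' @return a `qtl_model`.
#' @export
sim_qtl_model <- function(gs, n_qtl = 20,
                          mode = c("additive_snp", "founder_haplotype"),
                          seed = 1) {
  mode <- match.arg(mode)
  withr_seed(seed)
  pos <- sort(sample.int(n_snps(gs), n_qtl))
  if (mode == "additive_snp") {
    qtl_model(pos, stats::rnorm(n_qtl), mode)
  } else {
    if (is.null(gs$origin)) stop("founder_haplotype mode needs origin tracking")
    labs <- sort(unique(as.vector(gs$origin)))
    eff <- lapply(seq_len(n_qtl), function(i)
      stats::setNames(stats::rnorm(length(labs)), labs))
    qtl_model(pos, eff, mode)
  }
}

# true genetic values under a QTL model
genetic_values <- function(gs, qm) {
  ids <- individuals(gs)
  if (qm$mode == "additive_snp") {
    D <- dosage_matrix(gs)[, qm$positions, drop = FALSE]
    g <- as.numeric(D %*% qm$effects)
  } else {
    if (is.null(gs$origin)) stop("founder_haplotype QTL need origin tracking")
    g <- numeric(length(ids))
    for (q in seq_along(qm$positions)) {
      o <- gs$origin[, qm$positions[q]]
      unknown <- setdiff(unique(o), names(qm$effects[[q]]))
      if (length(unknown))
        stop("no effect for origin(s): ", paste(unknown, collapse = ", "))
      per_gam <- qm$effects[[q]][o]
      g <- g + rowsum(per_gam, gs$gamete_individual, reorder = FALSE)[ids, 1]
    }
  }
  stats::setNames(g, ids)
}

#' Simulate phenotypes
#'
#' Phenotypes are genetic value plus i.i.d. normal noise scaled so that
#' the realized sample gives `Var(e) = Var(g) (1 - h2) / h2`, i.e. the
#' target heritability holds in expectation on this sample.
#'
#' @param gs a `gamete_set`.
#' @param qm a [qtl_model()].
#' @param h2 heritability in `(0, 1]`.
#' @param trait trait name recorded in the table.
#' @param seed integer seed.
#' @return data.frame with columns `individual`, `trait`, `value`,
#'   `g_true`, `h2` (one row per individual).
#' @export
sim_phenotypes <- function(gs, qm, h2, trait = "trait1", seed = 1) {
  stopifnot(h2 > 0, h2 <= 1)
  withr_seed(seed)
  g <- genetic_values(gs, qm)
  vg <- stats::var(g)
  if (vg == 0 && h2 < 1)
    stop("genetic variance is zero; noise scale undefined for h2 < 1")
  e <- if (h2 == 1) 0 else stats::rnorm(length(g), 0, sqrt(vg * (1 - h2) / h2))
  data.frame(individual = names(g), trait = trait, value = as.numeric(g + e),
             g_true = as.numeric(g), h2 = h2, row.names = NULL)
}

#' Simulate a gene annotation track
#'
#' Draws `n_genes` non-overlapping intervals per the whole map, allocated
#' to chromosomes proportionally to physical length, in BED half-open
#' convention (`start` 0-based inclusive, `end` exclusive).
#'
#' @param map marker map.
#' @param n_genes number of gene intervals (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
sim_gene_track <- function(map, n_genes, seed = 1) {
  stopifnot(n_genes >= 0)
  withr_seed(seed)
  if (n_genes == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  chroms <- unique(map$chrom)
  maxbp <- vapply(chroms, function(ch) max(map$bp[map$chrom == ch]), numeric(1))
  alloc <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1)))
  out <- lapply(seq_along(chroms), function(i) {
    k <- alloc[i]
    if (k == 0)
      return(data.frame(chrom = character(), start = integer(), end = integer()))
    pts <- sort(sample.int(maxbp[i], 2L * k))
    data.frame(chrom = chroms[i],
               start = pts[seq(1, 2 * k, 2)] - 1L,  # BED 0-based
               end = pts[seq(2, 2 * k, 2)])
  })
  do.call(rbind, out)
}
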