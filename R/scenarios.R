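#' Prediction method specifications
#'
#' Small constructors describing how a relationship matrix is built for
#' genomic prediction: from SNPs directly, from fixed-window blocks,
#' from one of the three LD-based block algorithms, or from an IBD-based
#' haplotype library. The scenario runners take a named list of these.
#'
#' @param window fixed-window size in SNPs.
#' @param algorithm LD algorithm: `"gab"`, `"4gam"` or `"spine"`.
#' @param max_span optional SNP-length cap for the LD algorithms.
#' @param w,multi_window,mcmb,target_coverage,min_subgroup library
#'   parameters, see [build_library()].
#' @param weighting optional haplotype weighting mode, see
#'   [haplotype_weights()]; `NULL` for the unweighted GRM.
#' @return a `gp_method` object.
#' @name gp_methods
NULL

#' @rdname gp_methods
#' @export
gp_method_snp <- function() {
  structure(list(type = "snp"), class = "gp_method", label = "SNP")
}

#' @rdname gp_methods
#' @export
gp_method_fixed <- function(window = 20, weighting = NULL) {
  structure(list(type = "fixed", window = window, weighting = weighting),
            class = "gp_method", label = paste0("FixedHB", window))
}

#' @rdname gp_methods
#' @export
gp_method_ld <- function(algorithm = c("gab", "4gam", "spine"),
                         max_span = Inf, weighting = NULL) {
  algorithm <- match.arg(algorithm)
  structure(list(type = "ld", algorithm = algorithm, max_span = max_span,
                 weighting = weighting),
            class = "gp_method", label = toupper(algorithm))
}

#' @rdname gp_methods
#' @export
gp_method_library <- function(w = 20, multi_window = FALSE, mcmb = 5000,
                              target_coverage = NULL, min_subgroup = 0,
                              weighting = NULL) {
  structure(list(type = "library", w = w, multi_window = multi_window,
                 mcmb = mcmb, target_coverage = target_coverage,
                 min_subgroup = min_subgroup, weighting = weighting),
            class = "gp_method",
            label = paste0("HapLib_w", w,
                           if (!is.null(target_coverage))
                             paste0("_tc", target_coverage)
                           else paste0("_mcmb", mcmb),
                           if (min_subgroup > 0) paste0("_ms", min_subgroup)))
}

method_label <- function(m) attr(m, "label")

#' Build the relationship matrix a method prescribes
#'
#' Runs the method's haplotype construction on `gametes`, encodes
#' pseudo-markers for `analysis_ids`, drops singleton alleles within the
#' analysis set, and returns the (possibly weighted) VanRaden GRM. For a
#' library method, `construction_extra` individuals (e.g. the capture
#' line in across-population runs) take part in library construction but
#' are excluded from the GRM and from the singleton count.
#'
#' @param method a `gp_method`.
#' @param gametes a [gamete_set()] holding at least the analysis
#'   individuals.
#' @param analysis_ids individuals the GRM is built for (default all).
#' @param subgroups optional named character vector (per gamete id) for
#'   the library's minimum-subgroup filter.
#' @param construction_extra ids included in construction only.
#' @param gene_track optional gene intervals for gene-count weighting.
#' @return list with `G` (the GRM) and `n_columns` (explanatory
#'   variables used).
#' @export
build_method_grm <- function(method, gametes, analysis_ids = NULL,
                             subgroups = NULL, construction_extra = NULL,
                             gene_track = NULL) {
  stopifnot(inherits(method, "gp_method"))
  ids <- analysis_ids %||% setdiff(individuals(gametes), construction_extra)
  gs_constr <- gametes
  if (method$type == "snp") {
    D <- dosage_matrix(subset_individuals(gametes, ids))
    return(list(G = grm_vanraden(D, kind = "SNP"), n_columns = ncol(D)))
  }
  pm <- switch(method$type,
    fixed = {
      part <- fixed_blocks(gametes$map, method$window)
      encode_alleles(part, gs_constr, individuals = ids,
                     gene_track = gene_track)
    },
    ld = {
      gs_an <- subset_individuals(gametes, ids)
      gs_an <- keep_polymorphic(gs_an)
      part <- switch(method$algorithm,
        gab = gabriel_blocks(gs_an, max_span = method$max_span),
        `4gam` = four_gamete_blocks(gs_an),
        spine = spine_blocks(gs_an, max_span = method$max_span))
      encode_alleles(part, gs_an, individuals = ids, gene_track = gene_track)
    },
    library = {
      lib <- build_library(gs_constr, w = method$w,
                           multi_window = method$multi_window,
                           mcmb = method$mcmb,
                           target_coverage = method$target_coverage,
                           subgroups = subgroups,
                           min_subgroup = method$min_subgroup)
      if (!length(lib$blocks)) stop("empty haplotype library")
      encode_alleles(lib, gs_constr, individuals = ids,
                     gene_track = gene_track)
    },
    stop("unknown method type"))
  pm <- drop_singletons(pm, population = ids)
  if (ncol(pm$M) == 0) stop("no haplotype alleles left after singleton drop")
  G <- if (is.null(method$weighting)) grm_vanraden(pm, kind = "haplotype")
  else grm_weighted(pm, haplotype_weights(pm$info, method$weighting),
                    kind = paste0("weighted_", method$weighting))
  list(G = G, n_columns = ncol(pm$M))
}

# fold assignment: shuffle ids into k near-balanced folds
make_folds <- function(ids, k) {
  sh <- sample(ids)
  split(sh, rep_len(seq_len(k), length(sh)))
}

#' Within-population cross-validation (scenario 1)
#'
#' Runs `iters` iterations of `k`-fold cross-validation inside one
#' population. Haplotypes are constructed once on the full population
#' per method; fold assignments are shared across methods and traits so
#' that accuracy comparisons are paired. Accuracy is the correlation
#' between predicted genetic values and observed phenotypes of the
#' held-out fold divided by the square root of the trait's heritability
#' (taken from the phenotype table's `h2` column).
#'
#' @param gametes a [gamete_set()] of one population.
#' @param phenotypes phenotype table as from [sim_phenotypes()] (columns
#'   `individual`, `trait`, `value`, `h2`).
#' @param methods named list of [gp_methods].
#' @param k folds (default 5).
#' @param iters iterations (default 10).
#' @param seed master seed; records are bit-reproducible given it.
#' @return data.frame of accuracy records: `scenario`, `method`, `trait`,
#'   `iteration`, `fold`, `accuracy`.
#' @export
run_scenario1 <- function(gametes, phenotypes, methods, k = 5, iters = 10,
                          seed = 1) {
  ids <- individuals(gametes)
  if (k > length(ids)) stop("more folds than individuals")
  stopifnot(all(phenotypes$individual %in% ids))
  grms <- lapply(methods, build_method_grm, gametes = gametes,
                 analysis_ids = ids)
  traits <- unique(phenotypes$trait)
  withr_seed(seed)
  fold_sets <- lapply(seq_len(iters), function(i) make_folds(ids, k))
  rec <- list()
  for (it in seq_len(iters)) {
    folds <- fold_sets[[it]]
    for (f in seq_len(k)) {
      ps <- folds[[f]]
      ts <- setdiff(ids, ps)
      for (mname in names(methods)) {
        G <- grms[[mname]]$G
        for (tr in traits) {
          ph <- phenotypes[phenotypes$trait == tr, ]
          y <- stats::setNames(ph$value, ph$individual)
          h2 <- ph$h2[1]
          fit <- reml_fit(y[ts], G, ts)
          pred <- predict(fit, ps)
          acc <- prediction_accuracy(pred, y[ps], h2)
          rec[[length(rec) + 1]] <- data.frame(
            scenario = 1L, method = method_label(methods[[mname]]),
            trait = tr, iteration = it, fold = f, accuracy = acc)
        }
      }
    }
  }
  do.call(rbind, rec)
}

#' Across-population / across-landrace prediction (scenarios 2 and 3)
#'
#' Per repeat, `n_ts` training lines are sampled from one population and
#' `n_ps` prediction lines from the other (without replacement, same
#' sample for every method: the design is paired). Haplotypes are
#' constructed on the merged TS+PS genotypes of the repeat; for a
#' library method in a DH-vs-GC run the capture line's gametes can be
#' appended to the GC subgroup during construction via `fv2`.
#'
#' @param gs_ts,gs_ps [gamete_set()]s of the training-side and
#'   prediction-side populations.
#' @param pheno_ts,pheno_ps their phenotype tables.
#' @param methods named list of [gp_methods].
#' @param scenario 2 (across DH/GC within landrace) or 3 (across
#'   landraces).
#' @param n_ts,n_ps sample sizes per repeat (defaults 200 / 50).
#' @param reps number of repeats (default 100).
#' @param seed master seed; one substream per repeat.
#' @param fv2 optional capture-line [gamete_set()]; its gametes join the
#'   GC population's subgroup during haplotype construction (scenario 2).
#' @param gc_side which side is the GC population when `fv2` is given:
#'   `"ts"` or `"ps"`.
#' @return data.frame of accuracy records: `scenario`, `method`, `trait`,
#'   `repeat_id`, `accuracy`.
#' @export
run_scenario_across <- function(gs_ts, gs_ps, pheno_ts, pheno_ps, methods,
                                scenario = 2, n_ts = 200, n_ps = 50,
                                reps = 100, seed = 1, fv2 = NULL,
                                gc_side = c("ps", "ts")) {
  gc_side <- match.arg(gc_side)
  ids_ts_all <- individuals(gs_ts); ids_ps_all <- individuals(gs_ps)
  if (length(ids_ts_all) < n_ts || length(ids_ps_all) < n_ps)
    stop("insufficient lines for the requested sample sizes")
  traits <- intersect(unique(pheno_ts$trait), unique(pheno_ps$trait))
  withr_seed(seed)
  sub_seeds <- sample.int(2^31 - 1, reps)
  rec <- list()
  for (rp in seq_len(reps)) {
    withr_seed(sub_seeds[rp])
    ts <- sample(ids_ts_all, n_ts)
    ps <- sample(ids_ps_all, n_ps)
    merged <- merge_gamete_sets(subset_individuals(gs_ts, ts),
                                subset_individuals(gs_ps, ps))
    analysis_ids <- c(ts, ps)
    for (mname in names(methods)) {
      m <- methods[[mname]]
      gs_constr <- merged
      extra <- NULL
      if (m$type == "library" && !is.null(fv2)) {
        gs_constr <- merge_gamete_sets(merged, fv2)
        extra <- individuals(fv2)
      }
      # subgroup per gamete: population side; the capture line counts
      # with the GC side during construction
      pop_of <- c(stats::setNames(rep("TS", length(ts)), ts),
                  stats::setNames(rep("PS", length(ps)), ps))
      if (!is.null(extra))
        pop_of[extra] <- if (gc_side == "ps") "PS" else "TS"
      subgroups <- stats::setNames(
        pop_of[gs_constr$gamete_individual], rownames(gs_constr$alleles))
      gm <- build_method_grm(m, gs_constr, analysis_ids = analysis_ids,
                             subgroups = subgroups,
                             construction_extra = extra)
      for (tr in traits) {
        yt <- pheno_ts[pheno_ts$trait == tr, ]
        yp <- pheno_ps[pheno_ps$trait == tr, ]
        y_train <- stats::setNames(yt$value, yt$individual)[ts]
        y_obs <- stats::setNames(yp$value, yp$individual)[ps]
        fit <- reml_fit(y_train, gm$G, ts)
        pred <- predict(fit, ps)
        acc <- prediction_accuracy(pred, y_obs, yp$h2[1])
        rec[[length(rec) + 1]] <- data.frame(
          scenario = as.integer(scenario), method = method_label(m),
          trait = tr, repeat_id = rp, accuracy = acc)
      }
    }
  }
  do.call(rbind, rec)
}

#' Compare methods against the SNP baseline
#'
#' Summarizes accuracy records into one row per method x trait with the
#' mean accuracy, the paired Wilcoxon signed-rank p value against the
#' SNP records (paired over replicates), and its Bonferroni adjustment
#' over the whole batch.
#'
#' @param records accuracy records from a scenario runner.
#' @param baseline method label of the baseline (default `"SNP"`).
#' @return data.frame: `method`, `trait`, `mean_accuracy`,
#'   `mean_accuracy_baseline`, `p_value`, `p_adjusted`.
#' @export
compare_to_baseline <- function(records, baseline = "SNP") {
  stopifnot(baseline %in% records$method)
  keycols <- intersect(c("iteration", "fold", "repeat_id"), names(records))
  out <- list()
  for (tr in unique(records$trait)) {
    base <- records[records$method == baseline & records$trait == tr, ]
    base <- base[do.call(order, base[keycols]), ]
    for (m in setdiff(unique(records$method), baseline)) {
      r <- records[records$method == m & records$trait == tr, ]
      r <- r[do.call(order, r[keycols]), ]
      p <- as.numeric(wilcoxon_signed_rank(r$accuracy, base$accuracy))
      out[[length(out) + 1]] <- data.frame(
        method = m, trait = tr, mean_accuracy = mean(r$accuracy),
        mean_accuracy_baseline = mean(base$accuracy), p_value = p)
    }
  }
  out <- do.call(rbind, out)
  out$p_adjusted <- bonferroni(out$p_value)
  out
}
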