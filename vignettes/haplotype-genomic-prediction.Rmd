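---
title: "Haplotype-based genomic prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based genomic prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`haplopred` implements a complete haplotype-based genomic prediction
pipeline for landrace-derived breeding populations: haplotype locus
construction (fixed windows and three LD-based algorithms), an IBD-based
haplotype library with the four tuning parameters that matter for
across-population prediction, pseudo-marker encoding, SNP and haplotype
genomic relationship matrices (GRMs), REML-based GBLUP, and the
evaluation machinery for within-population, across-population and
across-landrace prediction. A synthetic-data module simulates the two
population types the pipeline targets — fully homozygous doubled-haploid
(DH) lines taken directly from landrace S0 plants, and gamete-capture
(GC) S1 lines from an S0 x capture-line (FV2) cross — so every stage can
be exercised and tested without external data.

# The genotype substrate

All genotypes live in a `gamete_set`: a binary gametes x SNPs matrix with
a genetic map (chromosome, bp, cM), a gamete-to-individual mapping and
population labels. Every individual owns exactly two gametes; a DH line
owns two identical copies. Treating phased GC genotypes as two
"pseudo-inbred" gametes preserves the phase information of double
heterozygotes in all downstream block construction — the same device the
LD-based block finders use. Internally SNP positions are 1-based
inclusive indices into the map (the R/Bioconductor convention); BED
export is 0-based half-open and VCF POS 1-based at the I/O boundaries.

The QC filter applies, in order: markers then individuals above the
missing-rate threshold (default 10%, strict inequality), then — for DH
data — markers then individuals above the heterozygosity threshold
(default 5%), then conversion of residual heterozygous calls to missing.
Because that conversion can push a marker back over the missing-rate
threshold, the pass is iterated to a fixed point; this is what makes the
filter idempotent, which we consider the more important contract.
Imputation is deliberately out of scope: simulated data are complete and
phased, and real inputs are expected to be pre-imputed and phased
upstream.

# Haplotype construction

**Fixed windows** (`fixed_blocks`) tile each chromosome with
non-overlapping runs of exactly *w* adjacent SNPs; the final window may
be shorter (remainder SNPs form a short block rather than being thrown
away). Window sizes of 5–100 SNPs are the useful range; 20 is the
default used throughout the analysis scripts.

**LD-based blocks** come in the three classical flavours:

* `gabriel_blocks` — a SNP pair is in "strong LD" when the
  likelihood-based confidence bounds of D' satisfy upper >= 0.98 and
  lower >= 0.70; an interval qualifies as a block when at least 95% of
  all its within-interval pairs are strong-LD, and qualifying intervals
  are accepted greedily from longest to shortest (ties to the leftmost).
  This is a deliberate simplification of the original informative-pair
  bookkeeping: the published rule ("95% of pairs") is applied to all
  pairs, which changes results only on edge cases and keeps the
  procedure transparent.
* `four_gamete_blocks` — consecutive SNPs join a block while the rarest
  of the four two-locus gamete classes stays below 1% frequency, i.e.
  while the data do not force a recombination event between them.
* `spine_blocks` — a block grows to the right while its (first, last)
  pair remains strong-LD, admitting intermediate SNPs regardless of
  their pairwise LD.

The D' confidence bounds are computed by profiling a multinomial
likelihood over a grid on D' in [0, 1] (step 0.001) with the observed
allele frequencies held fixed, normalizing to unit mass, and reading off
the central 90% interval (5th/95th percentile bounds, as in the original
block-definition procedure, although the published description speaks of
a "95% confidence interval"; the mass is exposed as a parameter).
Because inputs are phased and complete, two-locus gamete frequencies are
direct counts — no EM step exists anywhere.

No maximum pair-distance cap is applied by default; `max_span` caps the
block length in SNPs for large chromosomes, where the O(m^2) pair
computation would otherwise dominate.

**The IBD-based library** (`build_library`) follows the window-cluster /
exact-extension scheme: gametes are grouped by identical sequence within
consecutive windows of *w* SNPs; every group is extended left and right
one SNP at a time while *all* carriers agree; duplicates and blocks
nested inside an equal-carrier longer block are removed. Only exact
matching is supported (`merging_error = 0`), matching the high-accuracy
array setting the method is used in; equivalence with any particular
program's internal simplification heuristics is not claimed — only the
parameter semantics are reproduced:

* `w` (window size, default 20; `multi_window` unions candidates over
  {5, 10, 20, 50}),
* `mcmb` — minimum number of cells, where a block's cells are its SNP
  length times its carrier count (default 5000 at full scale; the
  analysis scripts use desk-scale values since cells scale with both
  population size and SNP count),
* `target_coverage` — instead of a fixed `mcmb`, pick the cell-count
  threshold by bisection over the sorted distinct cell counts so that
  achieved coverage is the smallest coverage at or above the target;
  deterministic, and flagged `unreachable` when even a threshold of 1
  falls short,
* `min_subgroup` — keep only blocks with at least that many carriers in
  *every* predefined subgroup (e.g. DH and GC), the handle for focusing
  on haplotypes shared across populations.

Coverage is the fraction of gamete x SNP cells covered by at least one
retained block; it is non-increasing in both `mcmb` and `min_subgroup`
(asserted by tests over the full sweep grids).

# Pseudo-markers and relationship matrices

Each haplotype allele becomes a pseudo-marker column coded 0/1/2 — the
number of the individual's gametes carrying it. For partition-based loci
each individual's row sums to exactly 2 within a locus; library blocks
may overlap, so no such constraint holds there. Alleles carried by only
one individual within the defined analysis population are dropped
(`drop_singletons`); a capture line included only for library
construction does not count as an individual for this rule (a flag
controls this).

GRMs use VanRaden method 1,
`G = (X - 2P)(X - 2P)' / (2 sum p_j (1 - p_j))`, with observed
frequencies of the analysis set as the centering base (the standard
practice when no base population is defined). With fixed windows of size
1 and no singleton drop, the haplotype GRM equals the SNP GRM *exactly*
(each SNP contributes two complementary columns; numerator and
denominator both double) — asserted to 1e-10 and a useful end-to-end
identity linking the encoder and the GRM. The weighted variant scales
each column by map length (cM), gene count or SNP count, normalized to
mean 1; zero cM spans are floored at the smallest positive span, and
gene counts come from half-open interval overlap with a BED-style track.

# GBLUP

`reml_fit` fits `y = 1 mu + Z u + e` with `u ~ N(0, U sg2)` by
restricted maximum likelihood, profiling over `lambda = se2/sg2` via one
eigendecomposition of the training block of `U`: a 41-point log-grid on
[1e-6, 1e6] brackets the optimum, golden-section refinement (tolerance
1e-8) finishes it, and `mu`, `sg2` follow in closed form. BLUPs
propagate to all individuals through `U[, train] (K + lambda I)^{-1}
(y - mu)`. A jitter of 1e-8 x mean(diag) is added when the smallest
eigenvalue is a tiny negative number; anything more negative is an
error. The estimator is validated against two oracles: a direct
mixed-model-equations solve, and the ridge-regression marker-effect
equivalence whenever `U` is an inner-product kernel of the dosages (both
to 1e-8).

Prediction accuracy is `cor(predicted, observed) / sqrt(h2)` with the
heritability of the prediction set. In synthetic runs the generator's
true h2 is carried in the phenotype table; for real data h2 is a
required user input, as it comes from prior trial analyses outside this
package's scope.

One consequence of working with fully homozygous material is worth
stating: on DH lines the VanRaden diagonal is close to 2, so the
model-scale ratio `sg2/(sg2+se2)` is *not* the trait h2 there. The
variance-ratio recovery checks therefore run on Hardy-Weinberg
(founder-type) samples, where the ratio is directly comparable to the
simulated h2.

# Prediction scenarios and statistics

Scenario 1 is k-fold cross-validation within one population (default
5-fold, 10 iterations at full scale; haplotypes are constructed once per
population). Scenarios 2 (across DH/GC within a landrace) and 3 (across
landraces) resample a training set and a prediction set per repeat and
rebuild haplotypes on the merged genotypes of that repeat; in scenario 2
the capture line's gametes join the GC subgroup during library
construction. One master seed spawns per-repeat substreams and every
method sees identical samples, so method comparisons are paired — the
design the Wilcoxon signed-rank test requires.

The Mantel test correlates the strictly-lower triangles of two GRMs and
permutes rows/columns of the first matrix jointly (999 permutations by
default, one-sided upper p with the add-one correction — the common
default of the standard implementation). The Wilcoxon signed-rank test
drops zero differences, enumerates the exact null for up to 25 non-zero
differences by dynamic programming over doubled midranks (ties handled
exactly), and falls back to the tie-corrected normal approximation with
continuity correction beyond that; all differences zero returns p = 1 by
convention. Bonferroni adjustment is `min(1, p m)` over the whole
scenario batch (the grouping is a package choice, as no finer family is
canonical).

The FV2-composition diagnostic counts the library alleles carried by the
capture line that also occur in at least one DH individual, over the
total number of library alleles. The sweep table reports both raw counts
so the alternative numerator (all FV2-carried alleles regardless of DH
occurrence) is recoverable. `tune_min_subgroup` picks the threshold
minimizing the composition, ties to the smaller threshold — a
phenotype-free tuning criterion for scenario 2.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not maize genetics in coalescent detail:

* **Founders.** Per-landrace allele frequencies follow a Balding-Nichols
  model around shared ancestral frequencies with differentiation 0.15 by
  default; within-chromosome LD comes from a first-order Markov copy
  process with lag-1 correlation `exp(-ld_decay x d_cM)` (default decay
  1 per cM). Defaults: 35 founders per landrace, 2 chromosomes x 150 cM,
  2,000 SNPs at full scale. The real populations' founder numbers are
  unknown; these are desk-scale choices, not estimates.
* **Meiosis.** Poisson(L/100) crossovers per chromosome, uniform
  positions on the cM scale, no interference (Haldane), fair choice of
  the starting parent — the simplest model that creates block structure.
* **DH lines** are one founder meiosis duplicated; **GC lines** stop at
  the phased S1 genotype (two meioses of the F1), because only S1
  gametes enter the analysis. Founder origins are tracked per cell, so
  IBD is auditable and the expected 50% FV2 genome share is testable.
* **Phenotypes.** Additive-SNP or founder-origin QTL effects; noise is
  scaled to the realized genetic variance so the target h2 holds on the
  sample. The founder-origin mode attaches effects to ancestral segments
  rather than individual SNPs — the regime in which haplotype predictors
  demonstrably beat SNP predictors (a premise of the whole approach),
  and the basis of the directional test that fixed-window haplotype
  GBLUP outperforms SNP GBLUP in most seeded replicates.
* **The capture line** is simulated as an inbred fixed from one KE
  founder meiosis, so some of its haplotypes are alike in state with DH
  haplotypes — without this, the FV2-composition diagnostic is trivially
  zero.

What the generator does *not* emulate: genotyping error, missingness
mechanisms of real arrays, selection, multi-environment trial structure,
and realistic minor-allele-frequency spectra. Passing tests therefore
show correctness of the algorithms and the direction of core effects
under the stated model, not the magnitudes one would observe on the real
populations, whose reproduction requires the deposited data and is out
of scope here.

# Problem sizes and numerical choices

The analysis scripts and the acceptance script run at desk scale — 400
SNPs on 2 chromosomes, 90–120 lines per population, 5-fold
cross-validation with 2 iterations, 5 resampling repeats across
populations — sizes chosen so the whole workflow reruns in minutes while
every qualitative contrast (block-structure differences between methods
and populations, coverage monotonicity, haplotype advantage under
founder-origin architectures, the across-landrace accuracy collapse)
remains visible. Cell-count and subgroup thresholds scale with data
size, so the scripts use scaled grids (e.g. `min_subgroup` in {1, 2, 4,
8} where 90 GC lines contribute 182 gametes; the full-scale grid {0, 5,
20, 40, 80, 160} corresponds to populations several times larger).

Numerical conventions collected in one place: D' grid step 0.001 and
interval mass 0.90; strong-LD thresholds 0.70/0.98; four-gamete cutoff
0.01; GRM PSD tolerance 1e-8 x trace/n with matching REML jitter;
REML bracket [1e-6, 1e6] and tolerance 1e-8; greedy longest-first,
leftmost-tie block acceptance; ties in `tune_min_subgroup` resolve to
the smallest threshold; Mantel permutations include the identity in the
sampled null (standard estimator), so the smallest attainable p is
1/(n_perm + 1) only up to sampling of automorphisms.

# Known limitations

* The library construction reproduces parameter semantics, not any
  specific program's internals; block sets will differ from tools that
  apply graph simplification or error-tolerant merging.
* The minimum-subgroup filter's *accuracy* benefit in across-population
  prediction — reported on the real populations — does not reproduce
  reliably at desk scale under this generator: population-specific
  pseudo-marker columns largely rescale the GRM, and correlation-based
  accuracy is scale-free, so the filter's net effect is within replicate
  noise here. The package tests the deterministic parts of the
  mechanism (FV2-specific alleles are removed; composition and coverage
  respond as documented) and reports the accuracy contrast without
  asserting its direction.
* Unassigned SNPs of the LD-based methods are recorded but not offered
  as extra explanatory variables; that extension reduced accuracy in the
  motivating study and is omitted.
* GBLUP is single-trait with an intercept only; adjusted means are the
  expected phenotype input.
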