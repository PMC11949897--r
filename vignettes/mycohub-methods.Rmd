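---
title: "Models and methods behind mycohub"
author: "mycohub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mycohub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycohub)
```

# The scientific problem

Plants that accumulate a rare secondary metabolite — here a lycopodium
alkaloid measured in micrograms per gram fresh weight across tissues — often
host fungi suspected of contributing to its biosynthesis. Given a denoised
amplicon survey of the phyllosphere mycobiome (an ASV count table over
tissues and replicates, ITS2 sequences, taxonomy) together with the tissue
metabolite concentrations and a curated set of reference producer strains,
the questions this package answers are:

1. How do fungal communities differ across tissues and between a producer
   and a non-producer plant (alpha/beta diversity, ordination, PERMANOVA)?
2. Which ASVs are *potential producers* (PHP ASVs)? Two independent lines of
   evidence are combined: sequence identity of at least 97% to a reference
   producer strain, and Kendall tau-b above 0.4 between an ASV's tissue-mean
   relative abundance and the metabolite gradient.
3. Is the distribution of ASVs across tissues *nested* — do poor communities
   form subsets of rich ones (NODF, matrix temperature, null models)?
4. Which ASVs are differentially abundant between the two species' leaves
   (a simplified negative-binomial Wald test)?
5. How are ASVs organised in co-occurrence networks: modules, Zi-Pi keystone
   roles, and which *facilitator genera* repeatedly share modules with PHP
   ASVs?

Everything is exercised end to end on synthetic data with planted ground
truth, so each claim the pipeline makes is backed by a recovery or
calibration test.

# The synthetic-data generator

`simulateDataset()` emulates the post-denoising state of a tissue-resolved
survey. Its components, and what they emulate:

* **Nested tissue pools.** Each tissue has a pool of ASVs that can occur in
  it; pools are nested (every poorer, younger tissue's pool is contained in
  every richer, older one), with default pool fractions
  0.30, 0.35, 0.45, 0.60, 0.80, 1.00 of the 300 ASVs across six tissues.
  This mirrors the qualitative observation that young tissues host the
  poorest communities while stems contain the majority of ASVs found
  elsewhere. With `pool_swap_noise > 0` pool members are exchanged with
  outsiders, degrading nestedness monotonically.
* **Abundances.** Each ASV has a lognormal(0, 1) base abundance, scaled by
  `shell_scale^(s-1)` where `s` indexes the first tissue whose pool contains
  it: tissue specialists are rare taxa. Per-(tissue, ASV) lognormal effects
  (`tissue_effect_sd`, default 0.2) decouple tissue profiles from the
  metabolite gradient for non-producers; gamma overdispersion
  (`dispersion`, default 0.1) adds replicate-level noise. Counts are
  multinomial draws at lognormal depth (default mean ~70,000 reads, log-sd
  0.35, roughly the read-depth regime of tissue-level ITS2 surveys).
* **The metabolite gradient and producers.** Tissue means default to a
  log-spaced gradient from 360.27 down to 135.9 ug/g, the observed range in
  the motivating system. The `n_producers` (20) producer ASVs are drawn from
  the everywhere-present pool and their intensity in tissue `t` is
  multiplied by `(g_t / min g)^(gradient_exponent * tau_link_strength)`;
  at `tau_link_strength = 1` and all noise off, tissue-mean abundance is
  perfectly rank-concordant with the gradient (tau-b = 1). The exponent
  (default 3) encodes a strong enrichment of producers in young,
  metabolite-rich tissue — which also reproduces, through compositional
  closure, the observed dominance of a few taxa in young tissues.
* **Sequences.** Reference strains are i.i.d. uniform ACGT sequences
  (length ~ normal(300, 30), truncated at 150 bp); producer ASV sequences
  are derived from their source strain at 2% per-site substitution, all
  other ASVs from a random strain at 15%. The 2%/15% split leaves a clean
  margin on either side of the 97% identity threshold: a binomial
  tail computation gives ~92% of 300 bp producers at >= 97% identity, and
  essentially no non-producer ever passes.
* **Co-abundance modules.** The `n_modules` x `module_size` (8 x 10) module
  members share a lognormal latent factor per (module, sample)
  (`factor_sd`, default 1), inducing strong positive rank correlations.
  Members are the widest-occupancy ASVs so that module signal is not
  confounded with occupancy pattern.

`simulateStudy()` assembles the two-species layout the full pipeline
consumes: the producer species as above, a two-tissue (leaf, stem)
non-producer companion without a metabolite link, and a small set of shared
ASV identifiers (default 13) carried across with their sequences.

## What the generator does *not* emulate

No chimeras, no taxonomy-classifier error, no spatial or temporal structure,
no phylogenetic signal in the sequences (references are unrelated random
sequences rather than a clade), and no real ecological interactions behind
the co-abundance modules. Passing the recovery tests therefore shows that
the *pipeline machinery* is correct and calibrated on data with known
structure — not that the biological inferences on any real dataset are
valid.

## Calibration of the generator

The generator's defaults were fixed once, against the recoverability the
design requires: planted producers must be recoverable by the dual-evidence
screen (measured sensitivity ~0.93-1.0 and precision ~1.0 across seeds), and
expected NODF must fall monotonically with pool-swap noise. Two points
deserve explanation:

* **Tissue noise vs the correlation screen.** With nested pools, the total
  community intensity varies across tissues, so an everywhere-present ASV's
  *relative* abundance trends with tissue even without any biological link
  to the metabolite. The per-(tissue, ASV) effects and, dominantly, the
  producers' own compositional mass in young tissues (which pushes
  non-producer shares *down* exactly where the gradient is high) keep the
  null taus of non-producers at or below zero, so the strict tau > 0.4
  screen stays precise.
* **Module recovery is benchmarked on a homogeneous design**
  (`moduleBenchmarkConfig()`: two near-identical tissues, no tissue
  effects, low dispersion). Under the full nested-tissue design,
  tissue-level common modes — habitat filtering, the producers'
  compositional mass, and pseudocount distortion of the centered-log-ratio
  transform when most ASVs are absent — correlate essentially *all* ASV
  pairs, and no correlation-based method can isolate latent co-abundance
  modules (measured adjusted Rand index ~0.05 there). This is an
  identifiability limit of co-occurrence analysis on habitat-structured
  data, worth keeping in mind when interpreting module content on real
  multi-tissue datasets; on the homogeneous benchmark the default backend
  recovers the planted modules with ARI ~0.9.

# Methods and numerical choices

## Diversity

* Shannon entropy uses natural logarithms (nats), the common default of
  ecology packages.
* Rarefaction subsamples reads without replacement (a multivariate
  hypergeometric draw) to a fixed depth; samples below the depth are dropped
  with a warning rather than erroring, since rarefying to the observed
  minimum drops nothing on complete data.
* Bray-Curtis dissimilarity is computed on per-sample percentage-normalized
  rows by default (`normalize` flag to disable), via `vegan::vegdist`.
* NMDS is `vegan::metaMDS` (Kruskal stress-1, monotone regression), best of
  `n_starts = 20` random starts; `stress1()` recomputes the stress of any
  configuration from scratch for verification.
* PERMANOVA is implemented from the Gower-centered partition of squared
  dissimilarities: `SS_total = sum d^2 / N` over all pairs, within-group
  sums analogously, `F = (SS_between/(a-1)) / (SS_within/(N-a))`. The p
  value permutes group labels with the add-one convention
  `p = (1 + #{F* >= F}) / (n_perm + 1)`, so 0 is never reported.
  Permutations are evaluated in a single BLAS batch, which keeps the type-I
  calibration suite (2,000 null datasets at 999 permutations) inside a few
  minutes on one CPU. `vegan::adonis2` serves as an independent cross-check
  of the pseudo-F in the tests, never as the implementation.
* Group comparisons are nonparametric: Kruskal-Wallis (tie-corrected; the
  degenerate all-tied case returns H = 0) followed by Dunn pairwise z tests
  on mean ranks with Holm-Bonferroni adjustment; the two-group path is the
  Wilcoxon rank-sum test, exact by enumeration when both groups have at
  most 8 tie-free observations and a tie-corrected normal approximation
  otherwise. Only the unpaired path is provided.

## Producer (PHP) screening

* **Identity.** Percent identity comes from a semi-global *fit* alignment:
  the shorter sequence is aligned end to end, terminal gaps on the longer
  sequence are free (affine scoring match +1, mismatch -1, gap of length L
  costs 2 + L). Identity = 100 x matches / alignment columns, columns
  excluding terminal gaps but including internal gaps; IUPAC ambiguity
  codes match iff their base sets intersect. Requiring the alignment to
  span the shorter sequence matters: a fully ends-free overlap alignment
  can return a trivial few-base perfect overlap between unrelated
  sequences, which would make "percent identity" meaningless as a
  clustering criterion. The threshold is inclusive (>= 97), the best hit
  per ASV is kept with ties broken by higher identity, longer alignment,
  then lexicographic strain id.
* **Correlation.** Kendall tau-b (tie-corrected in both margins) between
  per-ASV tissue-mean percentage abundance (zeros included; a
  `min-prevalence` style filter is deliberately not applied) and the
  compound's tissue means; the threshold is strict (> 0.4); an all-tied
  abundance vector has undefined tau and is never retained. At least three
  tissues are required.
* The two evidence sets are merged as a union with both flags preserved, so
  `|union| = |A| + |B| - |A intersect B|` holds by construction.
* Per-tissue summaries count an ASV as detected in a tissue iff it is
  nonzero in at least one sample of that tissue; producer percentages are
  rounded half-up to 2 decimals.

## Nestedness

* **NODF**: for every row pair and column pair with strictly different
  marginal totals the paired score is 100 x overlap / smaller total; equal
  totals score 0 (the decreasing-fill requirement); NODF is the mean over
  all pairs. Note that a matrix with many more columns than rows *cannot*
  reach 100: column totals must tie, and tied pairs score 0. Perfect
  nesting in the NODF sense requires strictly decreasing totals in both
  margins, i.e. a square staircase.
* **Temperature**: an in-house variant of the classic matrix-temperature
  construction. Columns are packed by decreasing totals; unexpected cells
  (absences left of a row's boundary, presences right of it) contribute
  squared relative displacements; within blocks of tied column totals the
  contribution is taken in expectation over uniform placement of the row's
  presences in the block, which makes the statistic exactly invariant under
  row/column permutation of the input; the total is normalized by the fully
  right-packed worst case, giving [0, 100]. It is 0 for perfectly nested
  matrices, 50 for the 4 x 4 checkerboard (a frozen regression constant of
  this implementation), and grows under de-nesting moves. Numeric equality
  with legacy temperature programs is explicitly not a goal — the
  original normalization is implementation-specific — so observed and null
  temperatures are always computed by the same code and only compared with
  each other.
* **Null model**: per-ASV occurrence counts (column totals) are preserved
  and row assignments redrawn uniformly without replacement; significance
  is one-sided (`p = (1 + #{null temperature <= observed}) / (n_sims + 1)`),
  lower temperature meaning more nested.
* The matrix fill is reported as ones / (rows x columns).

## Differential abundance

A deliberately simplified negative-binomial Wald test: median-of-ratios
size factors (geometric-mean reference over ASVs with no zeros; optional
+0.5 pseudocount reference for sparse cross-species tables),
method-of-moments dispersion `(s^2 - m)/m^2` pooled within groups and
floored at 1e-8, then a per-ASV log-link NB GLM with group indicator and
log size factors as offset at fixed dispersion. The Wald statistic is the
group coefficient over its standard error (dispersion fixed at 1 in the
covariance), p from the standard normal, BH adjustment across ASVs, and
the significance rule padj < 0.01 with |log2 fold change| > 2, reported per
direction (positive = second group level). There is no dispersion
shrinkage, no outlier refitting and no fold-change shrinkage: the
contract is calibration (empirical FDR under the global null within its
nominal level) and power on planted effects, not bit-compatibility with
any particular large package. A group of all-zero counts triggers a +0.5
pseudocount refit and a flag; non-convergence after 100 IRLS iterations is
flagged with p set to missing.

## Co-occurrence networks

* **Category filter**: ASVs with strictly more than `min_reads = 25` total
  reads within the category's samples are retained ("more than 25" read as
  a strict per-category total).
* **Backend**: graphical-model inference is out of scope; the default
  backend is a documented, testable substitute with the same output
  semantics (a sparse signed graph): +0.5 pseudocount, closure to
  proportions, centered-log-ratio transform, Spearman correlation per pair,
  permutation p values from column-independent shuffles (default 1,000),
  BH across pairs, edges kept at q <= 0.05 with the signed correlation as
  weight. The backend registry (`registerNetworkBackend`) keeps the
  interface pluggable. Note the permutation floor: with 1,000 permutations
  the smallest attainable p is 1/1001, so FDR control is meaningful only
  when many pairs share the floor; under the global null BH essentially
  never selects an edge.
* **Modules**: Clauset-Newman-Moore fast-greedy modularity maximization
  (igraph) on the unweighted graph over all edges regardless of sign; the
  returned partition is additionally required to dominate the all-singleton
  and single-module partitions, which also guards against floating-point
  noise in the greedy merge path. Sign handling and unweighted degrees are
  stated choices: the Zi-Pi literature most commonly uses unweighted
  degrees.
* **Zi-Pi**: within-module degree z-score (population standard deviation;
  a zero spread gives Zi = 0) and participation coefficient
  `1 - sum_t (k_it/k_i)^2`; isolated nodes get Zi = Pi = 0. Roles use the
  strict thresholds Zi > 2.5 and Pi > 0.62 (network hub), Zi > 2.5 & Pi <
  0.62 (module hub), Zi < 2.5 & Pi > 0.62 (connector), everything else —
  including exact boundary values — peripheral.
* **Baselines**: R = 100 uniform G(n, m) random graphs with equal node and
  edge counts (degree-preserving rewiring behind a flag); modularity and
  mean local clustering (isolates counted as 0) are reported observed vs
  null mean +/- sd with z-scores. The degree distribution is fit by OLS of
  log10 frequency on log10 degree over degrees >= 1 with nonzero frequency
  (gamma = -slope, R^2 as the goodness of fit); fewer than three distinct
  degrees make the fit undefined.
* **Facilitators**: within each network a module is PHP-containing iff it
  holds at least one PHP call; a genus supports facilitation there iff a
  *non*-PHP member occurs in such a module. Genera reaching `flag_min = 4`
  PHP-containing modules in a producer-plant network are flagged as
  co-culture candidates; genera whose support occurs only in the
  non-producer network are cautioned. Unclassified genera are pooled and
  never flagged.

## Pipeline

`runPipeline()` derives one seed per stage by hashing the stage name into
the global seed, so adding a stage never shifts another stage's randomness;
all outputs are plain text (TSV/JSON/GraphML) and the manifest lists every
file with its md5 hash — two runs with the same configuration produce identical
manifests. Categories follow the study design: A = the producer species'
metabolite-rich young tissues, B = producer leaves + stems, C = non-producer
leaves + stems; a category with fewer than 8 samples is skipped with a
logged reason, as is the correlation screen when no metabolite table is
present. The differential-abundance contrast is the two species' leaf
samples on the merged (zero-filled) table.

## Problem sizes used in the tests

The shipped tests run the full study scale where the claim depends on it
(producer recovery uses the default 300-ASV, 36-sample generator over 20
seeds; module recovery uses the 150-ASV homogeneous benchmark over 10
seeds; PERMANOVA calibration uses 2,000 null datasets of 12 samples at 999
permutations) and reduced scales elsewhere (pipeline determinism runs an
80-ASV study; property tests use matrices up to 8 x 15 and sequences up to
60 bp against brute-force oracles). These sizes are the package's own
choices, balancing statistical resolution of each claim against a test
suite that a maintainer will actually run.

# Known limitations

* The correlation screen inherits the compositionality of relative
  abundances; its null behaviour on real data depends on community-size
  differences between tissues in ways the generator only partially mimics.
* The temperature statistic is a variant: values are comparable within this
  package (observed vs null), not across programs.
* The NB test's Wald p-values are asymptotic and the per-ASV moment
  dispersion estimate is plugged in as known. Without cross-ASV dispersion
  pooling (deliberately omitted from this simplified test) the null
  calibration holds in the many-replicate regime in which the dispersion is
  estimable — the shipped calibration suite runs at 60 replicates per
  group — and is anticonservative at the handful of replicates typical of
  tissue surveys. For designs of that size the permutation-based tests in
  the diversity module are the more trustworthy inferential route, and the
  differential-abundance thresholds (padj < 0.01, |log2FC| > 2) should be
  read as a strong-effect filter rather than a calibrated error rate.
* Facilitator ranking is a co-membership heuristic, not an interaction
  inference; it flags candidates for co-culture experiments, nothing more.
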