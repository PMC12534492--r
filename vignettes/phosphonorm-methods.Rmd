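---
title: "Methods: proteome-normalized phosphoproteomics and cell-type profiling"
author: "phosphonorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-normalized phosphoproteomics and cell-type profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphonorm)
options(phosphonorm.verbose = FALSE)
```

## The problem

A phosphosite measured by LC-MS changes in apparent abundance for two very
different reasons: because the fraction of protein copies phosphorylated at
that residue changed (a stoichiometry change — usually the biologically
interesting signal), or simply because the parent protein itself became more
or less abundant. Differential-expression analysis of an enriched
phosphoproteome alone cannot tell these apart. This package implements a
conservative correction that subtracts protein-level regulation from
phosphosite regulation and dampens the phosphosite's p-value in proportion
to how much of its fold change the protein explains, together with the
surrounding pipeline: collapse of precursor-level phosphopeptide reports to
confidently localized (class I) phosphosites, two-group differential
expression, left-shifted Gaussian imputation, proteome–transcriptome
replicate correlation, and ANOVA/k-means cell-type profiling. A
synthetic-data generator with known ground truth makes every stage testable
without access to raw instrument data.

## Proteome normalization of phosphosite regulation

Both the collapsed phosphosite matrix and the matched unenriched proteome
are analyzed with the same two-group engine, yielding a log2 fold change
and p-value per feature. Each site is joined to its parent protein group by
leading accession, and:

* **Corrected fold change.** `correctFoldChange()` returns
  $\Delta = \mathrm{FC}_{\text{phospho}} - \mathrm{FC}_{\text{protein}}$
  (log2 units). A site with phospho log2 FC 2 on a protein with log2 FC 2
  corrects to 0: its stoichiometry did not change.
* **Damping ratio.** `dampingRatio()` computes
  $r_{FC} = \Delta / \mathrm{FC}_{\text{phospho}}$, clamped to $[0,1]$.
  The printed transform alone would *increase* significance when the
  corrected fold change exceeds the original ($r > 1$) or when the two
  disagree in sign ($r < 0$); the stated boundary behaviour — protein
  regulation at least as strong as the phospho regulation must yield p = 1 —
  forces the floor at 0, and conservatism motivates the cap at 1. A site
  with original fold change 0 gets $r = 1$: there is no regulation to
  dampen, and leaving its p-value unchanged avoids a division by zero
  without ever creating significance.
* **Dampened p-value.** `dampenPValue()` applies
  $p' = 10^{\log_{10}(p_{ptm}) \cdot r_{FC}}$. Because the exponent acts on
  the logged p-value, each 0.1 drop in $r_{FC}$ removes a tenth of the
  p-value's orders of magnitude: for $p = 10^{-k}$, $p' = 10^{-k r}$. The
  transform is conservative ($p' \ge p_{ptm}$ always) and monotone in both
  arguments; both properties are tested.

Multiple-testing adjustment (Benjamini–Hochberg) is re-applied **after**
dampening, across all tested sites of the contrast, so downstream
significance calls reflect the corrected evidence; sites whose parent is
absent from (or untested in) the proteome table keep their raw statistics
and are flagged `matched = FALSE` rather than dropped.

A consequence worth knowing: for a site whose change is fully
protein-driven, the *estimated* corrected fold change fluctuates
symmetrically around 0, so the clamped ratio is 0 — and the dampened
p-value exactly 1 — for half of such sites in expectation, and near 0 for
most of the rest. The population median of the dampened p-value is 1, but
any finite-sample median hovers just below it; the test suite therefore
asserts the stable finite-sample consequences (the fraction exactly at 1,
a median above 0.5, and clean separation from stoichiometry-change sites in
the p-value ranking) rather than an unstable point value.

## Phosphosite collapse

`collapseToSites()` assigns a precursor to the site (protein group,
position, residue) exactly when that site's localization probability is at
or above the cutoff (default 0.75, the class-I criterion). The decision is
per site: a doubly phosphorylated precursor may support one confident site
and fail another. Site intensity is the **sum** of contributing precursor
intensities — the linear-aggregation default of the Perseus peptide-collapse
workflow — which preserves total intensity mass and makes conservation
testable; missing precursor values are ignored and a site with no observed
contributor stays missing. Multiplicity is carried as annotation but does
not split site identities. Sites are keyed on the protein-relative
positions as reported; no sequence re-mapping is attempted.

## Differential expression engine

Phosphoproteomics workflows of this kind often rely on dedicated DE
engines such as MS-EmpiRe's peptide-pair empirical error model. Such
engines are external published methods and are deliberately **not**
re-implemented here: the normalization above is agnostic to the DE engine,
needing only a log2 fold change and p-value per feature. `differentialExpression()` uses Welch's unequal-variance t-test on
log2 intensities of collapsed features, with mean(B) − mean(A) as the fold
change, BH adjustment across tested features, and a minimum of 2 observed
values per group (failing features are flagged and excluded from
adjustment). Exactly-zero test statistics report p = 1 so degenerate
equality never looks significant. On null data the raw p-values are
uniform (checked by a Kolmogorov–Smirnov test at 10^4 features); swapping
the contrast negates every fold change and leaves p-values unchanged.

## Imputation, z-scoring and sample clustering

`imputeGaussian()` implements left-shifted Gaussian imputation: missing
values of a feature with observed mean $\bar{x}$ and standard deviation $s$
are drawn from $N(\bar{x} - 3s,\ (0.3 s)^2)$. The downshift (3) and width
(0.3) are the standard parameters for this imputation family; both are
exposed. Imputation is per feature, touches only missing cells, and is
deterministic under a seed. Features with fewer than two observed values
cannot supply $(\bar{x}, s)$ and are dropped with a warning.

The sample-clustering recipe is applied in a fixed order: impute, z-score
each feature ($x \mapsto (x-\bar{x})/s$), then Pearson-correlate every pair
of samples; `sampleCorrelationMap()` orders the correlation matrix by
single-linkage agglomeration on Euclidean distances between sample
profiles. Cross-omics replicate correlations, in contrast, are computed on
**observed complete pairs only** — imputed values never enter a reported
correlation; the recipe reserves imputation for the clustering heatmap.
This complete-pairs choice is flagged in the output rather than silently
assumed.

## Proteome–transcriptome integration

`matchFeatures()` applies the gene↔protein mapping as given, keeps only
one-to-one pairs (ambiguous many-to-many links are dropped and logged,
never guessed), and returns both matrices in identical row order. Within
each (cell type, treatment) group, `crossOmicsCorrelations()` compares
every proteomics replicate against every transcriptomics replicate (3 × 3
= 9 pairings for triplicates) by Pearson correlation and simple linear
regression on log2 values; `compareConditionCorrelations()` compares the
per-pairing r values between conditions with a two-sided independent
Student's t-test. Replicate reproducibility is summarized as pairwise
replicate R² on log2 values and per-feature CVs computed on **linear**
intensities (sd/mean; a CV on log scale is meaningless).

## Cell-type profiling

`anovaAcrossGroups()` runs a one-way ANOVA per feature across all (cell
type × treatment) groups — one-way across all six groups, so both
cell-type and treatment differences register — with BH adjustment and a
complete-observations policy (any group with fewer than two observed values
excludes the feature, which is counted). For a two-group design the F
statistic reduces to the square of the pooled t statistic, which the suite
checks numerically. `kmeansResponseClusters()` z-scores features, averages
them per group into 6-dimensional profiles, and k-means-partitions the
profiles into k = 6 response categories with 25 random restarts under a
fixed seed; k-means initialization is otherwise arbitrary, and restarts
make the result reproducible and near-deterministic.
`pairwiseEnrichmentTables()` delegates every cell-type pair within
treatment and control-vs-treated within cell type to the DE engine and
summarizes shared versus cell-type-specific treatment responses.

## The synthetic-data generator

`simulateOmicsPair()` and `simulatePhosphoExperiment()` emulate the study
design the pipeline targets — 3 cell types × 2 treatments × 3 biological
replicates — with known ground truth:

* **Baselines.** Log2 abundances are Gaussian with sd 2.5 (proteome) and
  2.0 (transcriptome), i.e. a ~5-order-of-magnitude linear dynamic range,
  so rank- and censoring-dependent behaviour is realistic.
* **Noise.** Replicate noise is log-normal with
  $\sigma_{\log 2} = \sqrt{\ln(1+\mathrm{CV}^2)}/\ln 2$, calibrated to
  within-group CVs of 9.3 % (proteome) and 21.8 % (transcriptome) by
  default — the replicate variability scale typical of sorted-cell DIA
  proteomes and matched bulk RNA-seq.
* **mRNA–protein coupling.** Matched features share a latent log-abundance
  mixed to reach a target feature-wise Pearson correlation (default 0.6, a
  typical across-gene mRNA–protein correlation); the latent weight is
  inflated slightly to compensate for noise attenuation.
* **Effects.** 20 % of features carry a +2 log2 cell-type marker in one
  cell type; 15 % respond to treatment with |log2 FC| 2 following one of
  six archetypes (each single cell type, all up, all down, one pair).
  Effects act on both omics layers.
* **Phosphosites.** 30 % stoichiometry-change sites (phospho FC ±2, parent
  protein 0), 30 % protein-driven sites (identical phospho and protein FC,
  true corrected FC 0), the rest null. Each site is reported by 1–4
  precursors with fixed log-normal ionization-efficiency offsets, so
  collapse-by-sum recovers the site profile; 10 % of precursors draw a
  localization probability below 0.75 to exercise class-I filtering, and
  the ground truth records which sites retain a confident precursor. The
  generator emits single-site precursors; multi-site records are exercised
  by hand-built fixtures in the tests.
* **Missingness.** Cells drop out with probability decreasing
  logistically in log2 intensity (steepness 0.8 per log2 unit), with the
  logistic midpoint calibrated so the expected missing fraction matches the
  configured rate (default 10 %) — the left-censored
  missing-not-at-random pattern that downshifted-Gaussian imputation
  presumes. The mechanism behind real DIA missingness is not observable
  from matrices alone; left-censoring is assumed because the imputation in
  use presumes it.
* **Determinism.** All randomness flows from one master seed through
  deterministic per-stage sub-streams, so identical configurations give
  bit-identical outputs and partial runs are reproducible.

What the generator does **not** emulate: peptide-level digestion and
shared peptides, retention-time or ion-mobility structure, batch effects,
correlated (pathway-level) effects, count-based transcriptomic error, or
interactions between marker and treatment effects beyond additivity.
Passing tests on this generator therefore demonstrate the pipeline's
statistical correctness under its stated model, not performance on any
particular real dataset.

## Numerical and design choices

* Zero intensities are treated as missing on read and at log2 transform
  (DIA exports encode non-detection as blank or 0 depending on settings); a
  flag disables this.
* p-values are floored at 1e-300 before any log transform.
* BH was chosen as the meaning of "adjusted p-value"; it is isolated
  behind `benjaminiHochberg()`.
* Protein groups are keyed by their full ";"-separated accession string;
  phospho↔proteome matching uses the leading accession.
* Problem sizes used in the test-suite recovery runs — 2000 proteins, 500
  phosphosites, 3 × 2 × 3 design, 10^5-draw imputation calibrations — are
  the package's chosen desk-scale study conditions; dataset-level counts
  from any particular acquisition are not reproduced at this scale.
* For the planted-archetype clustering check, cell-type markers are
  disabled in the generator: a feature that is simultaneously a marker and
  treatment-responsive has a composite profile that belongs to none of the
  six planted archetypes, so markers-off is the correct planted-partition
  design.

## Worked example

```{r example}
cfg <- SimulationConfig(n_proteins = 400, n_phosphosites = 100, seed = 5)
ph <- simulatePhosphoExperiment(cfg)
sites <- collapseToSites(ph$report)$sites
d <- ph$truth$design
ctr <- resolveContrast(d, c(cell_type = "beta", treatment = "control"),
                       c(cell_type = "beta", treatment = "IFNg"))
de_site <- differentialExpression(log2Transform(sites), ctr)
de_prot <- differentialExpression(log2Transform(ph$proteome), ctr)
norm <- normalizePhosphoDataset(de_site, de_prot)
norm$class <- ph$truth$sites$class[match(norm$site_id,
                                         ph$truth$sites$site_id)]
aggregate(cbind(abs(log2fc_corrected), p_dampened) ~ class,
          data = norm, FUN = median)
```

Stoichiometry-change sites keep corrected fold changes near the injected
±2 with small dampened p-values; protein-driven sites collapse to corrected
fold changes near 0 with dampened p-values pushed toward 1.

## Known limitations

* The dampening is a heuristic, not a calibrated error model: dampened
  p-values are conservative bounds, not frequentist p-values, and their BH
  adjustment should be read accordingly.
* Fold-change correction propagates no uncertainty from the protein
  estimate; a noisy protein fold change perturbs the corrected value.
* Welch's t-test with triplicates has limited power; the engine is
  deliberately simple and swappable.
* One-to-one feature matching discards genuinely multi-mapped genes.
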