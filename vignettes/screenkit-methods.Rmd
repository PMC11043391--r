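---
title: "Methods: models and decisions behind screenkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and decisions behind screenkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

screenkit analyses CRISPR drug-resistance screening studies in cancer cell
lines end to end: pooled-screen enrichment testing with gene-level robust
rank aggregation, integration of hit tables across screens into core
resistance genes, arrayed high-content nuclear-translocation scoring,
gene-set and transcription-factor enrichment, and IHC H-scoring. This
vignette explains the statistical models, the tunable parameters, the
synthetic-data generators used for validation, and the design decisions
taken where several defensible choices existed.

## Pooled-screen model

A pooled screen compares guide abundance between drug-treated and
vehicle-treated populations. The analysis has four stages.

**Normalization.** Sequencing depth differs between samples, so raw counts
are scaled by median-of-ratios size factors: for each guide with positive
counts in every sample, the ratio of its count to its geometric mean across
samples is formed, and each sample's factor is the median of these ratios.
This is the standard count-matrix normalization of the DESeq family and is
robust to a minority of strongly enriched guides.

**Per-guide negative-binomial test.** Counts are modelled as negative
binomial with variance $\mu + \phi\mu^2$. A single dispersion $\phi$ is
pooled across guides by method of moments from the vehicle replicates
(regression through the origin of the excess variance $v_g - m_g$ on
$m_g^2$, floored at $10^{-8}$); with thousands of guides and two or three
replicates, per-guide dispersion estimates would be dominated by noise,
while the pooled estimate is stable. The enrichment p-value of a guide is
the upper tail probability of its *summed* drug count under the
vehicle-derived expectation scaled to the drug samples' depth. A sum of
negative binomials with unequal size factors is not itself negative
binomial; we use the NB distribution with matched first and second moments,
which is exact for equal size factors and an excellent approximation
otherwise. The depletion p-value is the analogous lower tail. Fold changes
are reported as $\log_2((\bar d + 0.5)/(\bar v + 0.5))$ on normalized
means; the pseudocount of 0.5 affects reporting only, never the test.

**Gene-level aggregation (alpha-RRA).** Guides are ranked by their
directional p-value and assigned normalized mid-ranks $u \in (0,1]$. For a
gene with $k$ guides and sorted ranks $u_{(1)} \le \dots \le u_{(k)}$, the
score is
$$\rho = \min_{j : \text{guide } j \text{ selected}} P\big(\mathrm{Beta}(j,\,k-j+1) \le u_{(j)}\big),$$
where only guides with directional p below `rra_alpha` (default 0.05) are
*selected*; a gene with no selected guide scores $\rho = 1$. Restricting to
selected guides is what makes the statistic robust to inert guides: a gene
with two strong guides and three inert ones is still scored on the strong
pair. The significance of $\rho$ comes from permutation of the guide-to-gene
assignment, stratified by guides-per-gene: the null is built by drawing
random guide sets of size $k$ from the screen (equivalently, reading one
gene off a permuted assignment), with $p = (b+1)/(B+1)$ over $B$ Monte-Carlo
draws (default 10,000, so the attainable floor is $1/10001$). For toy
universes an exhaustive mode enumerates all $\binom{N}{k}$ assignments and
reports the exact tail fraction. Benjamini–Hochberg FDR is computed across
genes within each direction.

**Hit calling.** A resistance hit is enriched under drug with linear fold
change $\ge 2$ and permutation $p < 0.005$. The fold-change boundary is
configurable as strict or non-strict (`fc_strict`) because published
practice states it both ways; the default is non-strict ($\ge$).
Resistance calling uses the enriched direction; the depleted direction is
computed and exposed for sensitizer analyses. The plasmid arm is carried in
the sample sheet for QC but the test compares drug vs vehicle.

## Cross-screen integration

Core resistance genes are genes recurrently called across independent
screens (cell lines × drugs × knockout/activation modality). Recurrence is
a plain count of screens in which the gene's hit flag is set, with genes
absent from a screen counted as non-hits; the core set is `recurrence >=
recurrence_min` (default 4, intended for a six-screen design). Knockout and
activation screens are counted symmetrically. Gene matching is exact and
case-sensitive; alias resolution is out of scope.

## Arrayed high-content scoring

Per-cell tables (one row per segmented cell, with nuclear and cytoplasmic
mean intensity per channel, area, and a border flag) are filtered before
any statistic is formed: border-touching cells are removed, and within each
well the cells in the lowest and highest area deciles are trimmed
($\lfloor 0.1 n \rfloor$ at each end, ties broken by stable input order) to
exclude segmentation artefacts and doublets.

The translocation readout is the per-cell nuclear:cytoplasmic intensity
ratio of the YAP1/WWTR1 channel; cells with non-positive cytoplasmic signal
are excluded rather than clamped. Wells are summarised by the median (robust
to residual segmentation outliers; the aggregation statistic is a package
choice, as is the per-channel marker statistic — the median of the per-cell
average of nuclear and cytoplasmic means).

**Two-point normalization.** Pathway-marker signals are expressed on a
plate-anchored scale: the mean NTC-vehicle well statistic maps to 0 (full
pathway activity) and the mean NTC-drug statistic to −100 (full drug
inhibition),
$$\mathrm{norm}(x) = -100\,\frac{x_{\max} - x}{x_{\max} - x_{\min}}.$$
The map is affine, so values above the vehicle anchor are positive and a
knockout that fully preserves, say, pERK under drug scores near 0.

**Hit calling.** A perturbation is a nuclear-translocation hit when its
Nuc:Cyt fold change over the treatment-matched NTC mean exceeds 1.2 (a
strict >20% increase). The rule is evaluated under drug by default — the
biologically motivated arm, since translocation there reflects bypass of
EGFR inhibition — with the arm configurable; replicate wells are averaged.
A two-sided Wilcoxon rank-sum test on per-cell ratios accompanies each
call. The association between translocation hits and pathway preservation
(normalized marker effect ≥ −50, i.e. at least half-rescue, on any marker)
is tested with Fisher's exact test on the 2×2 table; the −50 preservation
boundary is a package default, configurable.

The rank-sum test enumerates all rank assignments exactly when both groups
have ≤8 observations (valid under ties via mid-ranks) and otherwise uses
the normal approximation with tie and continuity corrections; the 2×2
Fisher test delegates to `stats::fisher.test`.

## Enrichment

Over-representation of a DE gene list (filter: $p < 0.01$ and linear
$|\mathrm{FC}| \ge 1.5$) in a gene-set collection is tested with the
upper-tail hypergeometric distribution against an explicit background, with
BH correction across sets. The odds ratio comes from the 2×2 overlap table
with Haldane's 0.5 correction when a cell is zero. The combined score is
$-\ln(p) \times \mathrm{OR}$: enrichment tools that publish a "combined
score" derive their odds-ratio-like term from background rank simulations
that are not reproducible from their description, so this package defines
its own documented combination and labels it as such. TF activity is the
same machinery over TF target sets with a $p < 0.01$ significance flag; the
display transform (min-max scaling of combined scores followed by
$\log_2(1+\cdot)$) is likewise a package choice, made explicit because
published heatmaps of "log2 normalised" activity do not pin down a formula.

Pre-ranked enrichment uses the weighted Kolmogorov–Smirnov running sum
(weight exponent 1 on |score|, 0 giving the classic unweighted statistic),
with significance from sign-matched gene-label permutations — label rather
than phenotype permutation because the input is a ranked list, not an
expression matrix. Signature (module) scores per cell are the mean
normalized expression of signature genes minus that of control genes drawn
per signature gene from the same average-expression bin (24 bins, 100
controls per gene by default, matching the convention popularized by
single-cell toolkits); expression is library-size normalized to 10,000
counts and log1p-transformed.

## IHC H-score

Tumour cells are classed per compartment into intensity categories 0, 1+,
2+, 3+; the H-score is $\%1{+} + 2\times\%2{+} + 3\times\%3{+}$, ranging 0
to 300 and maximized only by a sample entirely at 3+. Percentages, not raw
counts, are the canonical input (a count-to-percentage helper is provided)
and are kept at full precision until report time. Group comparisons use the
rank-sum test, consistent with the per-cell comparisons elsewhere in the
package.

## Synthetic data: what it emulates and what it does not

Every stage is validated on generated data with planted truth.

* **Pooled screens** draw guide counts NB$(\mu, \phi)$ with a shared
  $\phi$ and equal expected depth $\mu$ per guide; drug samples multiply
  $\mu$ by $2^{\Delta}$ for effective guides of planted resistance genes.
  Defaults (1000 genes × 5 guides, 20 resistance genes at $\Delta = 2$,
  depth 300, $\phi = 0.1$, 2 replicates per arm) reflect a realistic
  genome-scale screen corner at desk scale. `dropout_fraction` (default 0)
  makes a fraction of resistance-gene guides inert to exercise the
  aggregation's partial-evidence behaviour.
* **Cell tables** use lognormal areas and intensities (positive support,
  multiplicative microscopy noise; no published noise model exists to copy),
  a Bernoulli border flag, a planted Nuc:Cyt fold per perturbation, and
  multiplicative marker suppression under drug with optional per-
  perturbation rescue. Two fields have no counterpart in any published
  description and are package additions: the baseline cytoplasmic
  intensity (1000 a.u.) and the `marker_rescue` map, needed to plant
  pathway-preservation effects.
* **DE lists** are iid Bernoulli memberships over a labelled background
  with a multiplicative boost for active-set genes — exchangeable under the
  null, so hypergeometric p-values are honestly calibrated by construction.
* **IHC distributions** are multinomial draws converted to percentages.

These generators deliberately omit well/plate batch effects, guide-level
baseline abundance variation, cell-cycle and density covariates, and
spatial intensity gradients. Passing tests therefore demonstrate
correctness of the statistics and recovery under the stated generative
model, not robustness to every artefact of real screens.

## Numerical choices and problem sizes

* Dispersion and permutation floors: $\phi \ge 10^{-8}$,
  $p_{\text{perm}} \ge 1/(B+1)$.
* Ties: mid-ranks everywhere; area-decile trimming resolves ties by stable
  input order so retained counts are deterministic.
* All stochastic operations take an explicit seed and restore the caller's
  RNG state; a fixed seed reproduces every output byte for byte.
* The validation suite runs pooled-screen recovery at 1000 genes × 5 guides
  over 5 seeds, null calibration over 10 seeds, translocation calling at
  2000 cells/well over 20 seeds, and null-enrichment calibration over 1000
  simulated DE lists — sizes chosen so the whole suite completes in about a
  minute while keeping Monte-Carlo error well below the margins being
  asserted.
* Calibration of discrete p-values is checked with a Kolmogorov–Smirnov
  comparison against the uniform; that comparison is only meaningful when
  the discrete support is fine relative to KS resolution, so the check uses
  a large background (20,000 genes) and a large set (4,000 genes, query
  ≈ 4,000) where the largest p-value atom is far below the KS critical
  value at the simulated sample size.

## Known limitations

* The NB test is a moment-based approximation, not an iterative
  maximum-likelihood GLM fit; with very few replicates this is a feature
  (stability), but shrinkage-based tools will differ in detail.
* Copy-number correction, paired designs, and alias-aware gene matching are
  out of scope.
* The combined enrichment score and the TF activity display transform are
  package-defined stand-ins (see above) and should not be compared
  numerically against other tools' scores.
* Image segmentation is upstream of this package: per-cell tables are taken
  as given.
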