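---
title: "Methods: cross-platform RA/OA expression meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform RA/OA expression meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(raometa)
```

# Scope

`raometa` implements a meta-analysis workflow for heterogeneous microarray
datasets comparing rheumatoid arthritis (RA), osteoarthritis (OA) and
normal-control (NT) cohorts: per-array z-score harmonization into a
multi-study gene compendium, pairwise expression-divergence analysis,
SAM (Significance Analysis of Microarrays) differential expression with a
permutation false discovery rate, and gene-set over-representation
analysis. Because the original public datasets span eight platforms and
are not redistributed here, the package carries a synthetic-data generator
that reproduces the statistical structure those stages rely on, together
with ground truth, so every stage is testable end to end.

# Harmonization model

Each array (one sample column of one dataset) is standardized across the
genes its platform measures:

$$ z_{g} = \frac{x_{g} - \bar{x}}{s}, $$

with $\bar{x}$ the mean and $s$ the sample standard deviation
(denominator $n-1$) over the array's measured intensities. Two choices
deserve comment.

* **Standardization is per array, on the log2 scale.** `build_compendium()`
  log2-transforms the linear intensities before z-scoring. Z-score
  harmonization of microarray intensities is conventionally defined on
  log-transformed values; raw linear intensities are so heavily
  right-skewed that a handful of bright genes would dominate every array's
  mean and standard deviation and the standardized values would carry
  almost no usable per-gene contrast. The z-score itself is invariant
  under positive affine transforms, which is exactly what removes
  platform gain (multiplicative on the linear scale, additive in log2)
  and platform offset.
* **"Experiment" is read as a single array**, not a whole dataset: every
  sample column is standardized independently against its own gene panel.
  This is the standard reading for cross-platform compendium building and
  requires no cross-sample normalization assumptions.

Datasets are merged on uppercased official gene symbols; probe-level rows
mapping to one symbol are collapsed to their per-sample arithmetic mean
(`collapse_duplicates()`). No cross-platform probe re-annotation is
attempted. Genes absent from a platform are recorded as missing — never
imputed — and the presence filter retains genes measured in strictly more
than 60% of all samples (`presence_filter()`, strict inequality).

# Expression divergence

Divergence between two samples is the Euclidean distance over the genes
both measure, rescaled to the full gene space so pairs with different
panel overlap live on one scale:

$$ d(a,b) = \sqrt{\sum_{g \in \text{shared}} (z_{a,g}-z_{b,g})^2 \cdot
\frac{G}{g_\text{shared}}}. $$

Distances are summarized per group-pair class (RA–NT, OA–NT, RA–OA and
the three within-group classes) as mean ± standard error over pairs, and
the class multisets are compared with a two-sided Mann-Whitney U test:
exact by enumerating all $\binom{n+m}{n}$ label assignments (midrank ties)
when that count is at most 10,000, otherwise the normal approximation with
tie and continuity corrections. No multiple-testing correction is applied
across the three reported comparisons.

**Caveat, by construction:** distance pairs share samples, so the U
statistic's real null variance is much larger than the independence
variance the test assumes. The workflow reports these p-values because
that is the established procedure for this analysis, but they should be
read descriptively. Under a no-effect simulation the comparison rejects at
5% far more than 5% of the time (about half the seeds at the default
generator configuration, see `analysis/07_operating_characteristics.R`);
this is a property of applying a rank test to dependent pairs, not of the
implementation.

# SAM differential expression

For a two-class contrast (disease group listed first) the per-gene
relative difference is

$$ d_i = \frac{\bar{x}_{1,i} - \bar{x}_{2,i}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_1 (x-\bar{x}_1)^2 + \sum_2 (x-\bar{x}_2)^2}{n_1+n_2-2}}, $$

computed on the z-scored compendium values; genes with any missing value
among the contrasted samples are excluded (their count is reported). The
fudge factor $s_0$ is chosen by `estimate_s0()`:

* `tusher_cv` (default): candidates are the scatter quantiles at
  $0, 0.05, \dots, 1$; each candidate is scored by the coefficient of
  variation of the median absolute deviation of $d$ within percentile
  windows of $s_i$, and the minimizer is taken. The point is to make the
  spread of $d$ independent of gene variance. With fewer than 100 genes
  the method falls back to `percentile5`.
* `percentile5`: the 5th percentile of the $s_i$ (linear interpolation).

The permutation null (`permutation_null()`) recomputes $d$ under permuted
class labels with $s_0$ fixed — all $\binom{n}{n_1}$ distinct assignments
when that number is at most `exhaustive_limit` (10,000), otherwise
`n_permutations` (default 1,000) seeded uniform draws — sorts each
permutation's d-vector and averages per rank to get the expected order
statistics $\bar{d}_E(i)$. For a threshold $\Delta$, the upper cut is the
smallest observed $d$ whose displacement above $\bar{d}_E$ reaches
$\Delta$ (lower cut symmetric), genes beyond the cuts are called, and

$$ \widehat{FDR}(\Delta) = \frac{\text{mean over permutations of the
number of permuted } d \text{ beyond the cuts}}{\#\text{called}}, $$

capped at 1 and defined as 0 for empty call sets. The **mean** (not the
median) of the permutation counts is used deliberately: the count
distribution is strongly zero-inflated when few genes are called, so a
median-based estimate collapses to zero and badly understates the FDR for
small call sets; with the mean, a no-effect simulation yields empty call
sets in well over 90% of seeds, which is the behavior a 5% criterion
should deliver. `choose_delta()` scans 100 equally spaced $\Delta$ values
over $[0, \max_i |d_{(i)} - \bar{d}_E(i)|]$ and selects the smallest one
with $\widehat{FDR} < 0.05$; a gene's q-value is the smallest
$\widehat{FDR}$ over all grid thresholds at which it is called.

Fold changes cannot be ratios of z-scores (z-scores are signed), so
`run_sam()` computes them on the linear scale: each dataset's intensity
matrix is divided by its overall median (removing platform gain), the
contrasted samples are pooled, and $fc = \text{mean(disease)} /
\text{mean(control)}$ per gene. A gene's status is `up_regulated` when
$q < 0.05$ and $\log_2 fc > 1$, `down_regulated` for the symmetric case,
`not_significant` otherwise. "Up" always means higher in the first-named
(disease) group — the package pins this self-consistent convention, since
direction labels in published summary tables of this kind are sometimes
stated relative to the other group. The log threshold is base 2
("minimal two-fold change"). SAM runs once on the pooled compendium, not
per dataset with later merging.

# Over-representation analysis

For a DE list of size $n$ from a background universe of size $N$ (the
post-presence-filter compendium genes — "all expressed genes"), a term
with $K$ background members and overlap $k$ is scored by the one-sided
upper-tail hypergeometric probability $P(X \ge k)$ (Fisher exact test for
enrichment; depletion is not tested). Term members outside the background
are ignored; terms with no background member are dropped. P-values are
adjusted across terms with Benjamini–Hochberg — the FDR procedure is
pinned to BH since the upstream convention only names "FDR" — and terms
with adjusted $p < 0.05$ are flagged. Annotation catalogs are plain GMT
files; no ontology-graph propagation or term de-duplication is performed.

# Synthetic data generator

`simulate_compendium_inputs()` draws, for gene $g$, dataset $d$, sample
$s$ in group $G$:

$$ y = \mu_g + \delta_{G,g} + o_d + \varepsilon, \qquad
\text{linear intensity} = gain_d \cdot 2^{y}, $$

with baseline $\mu_g \sim N(8, 2^2)$ (log2 units, typical microarray
intensity location and spread), noise $\varepsilon \sim N(0, 1)$,
platform offset $o_d \sim N(0, 0.5^2)$ (log2) and gain
$gain_d \sim U(0.8, 1.25)$ (linear). Each dataset measures a uniform
70–95% random panel of the 2,000-gene universe. 100 genes are spiked per
disease with $|\delta| \sim U(1.5, 3)$ log2 units and random sign;
a fraction (default 0.4, `floor`-rounded on the smaller spike set) is
shared between RA and OA with identical effect — the shared-pathology
component. Dataset designs default to a template mixing two-disease,
disease-vs-control and RA-only series in roughly the proportions seen in
the published compendium this workflow targets. One global seed drives a
per-dataset seed sequence (`seed + dataset index`), so datasets can be
regenerated independently; the annotation generator uses
`seed + n_datasets + 1`. `simulate_annotation()` creates 50 terms of
10–80 genes; five planted terms sample spiked genes with weight 5
relative to non-spiked genes.

What the generator does **not** emulate: probe-level structure beyond
duplicate-symbol collapse, correlated gene modules, intensity-dependent
variance, array-quality artifacts, or covariate structure (age, sex,
treatment). Passing tests therefore demonstrate that the statistical
machinery behaves as designed under its own assumptions, not that those
assumptions hold in any particular public dataset.

# Operating characteristics and problem sizes

The simulation studies (`sam_operating_characteristics()`,
`divergence_ordering_study()`, `enrichment_recovery_study()`; driven by
`analysis/07_operating_characteristics.R` and the test suite) use the
following sizes, chosen to estimate each property stably at desk scale:

* SAM: 20 replicates of the reference two-group conditions — 2,000
  genes, 100 spiked with $|\delta| \in [1.5, 3]$, 10 vs 10 arrays split
  over two full-coverage datasets, noise SD 1. Scored against ground
  truth: median false-discovery proportion among called genes, and median
  sensitivity for spikes with $|\delta| \ge 2$.
* Divergence: 50 seeds of the default compendium with the shared-spike
  fraction raised to 0.8 ("high sharing"): with most disease effects
  shared, few genes separate RA from OA while all of them separate either
  disease from NT, so the RA–NT and OA–NT distances should exceed RA–OA.
  At the default sharing of 0.4 the ordering reverses — 120 genes then
  separate the two diseases versus 100 separating disease from control —
  which the end-to-end narrative in `analysis/04_divergence.R` shows
  honestly. A 200-seed null study quantifies the dependence-driven
  rejection-rate inflation discussed above.
* Enrichment: 20 seeds, submitting the ground-truth spiked genes as the
  DE list. This isolates the over-representation machinery from upstream
  DE power; DE lists produced by the full pipeline at default conditions
  are much smaller (tens of genes after presence filtering and
  complete-case exclusion) and are typically too small to flag planted
  terms — visible in `analysis/06_enrichment.R`.

# Numerical and edge-case conventions

* Sample standard deviation (denominator $n-1$) throughout; pinned by
  tests.
* Presence filter: strictly greater than the threshold; a gene at exactly
  60% presence is removed.
* Constant arrays (zero variance) and non-finite intensities are errors,
  not silently skipped.
* Distance between samples with no shared genes is undefined: `NA` with a
  warning in the matrix, an error for a single pair.
* Mann-Whitney exact/approximate switch at 10,000 enumerable assignments;
  ties scored 0.5 in U, midranks in the enumeration, tie-corrected
  variance plus 0.5 continuity correction in the approximation. All
  values tied across both samples gives p = 1.
* All-zero gene scatters: $s_0$ floors at $10^{-8}$ with a warning.
* Delta grid of 100 points including 0; at $\Delta = 0$ every gene is
  called (the cuts meet at the observed d-values' crossing), and if no
  grid point achieves the FDR threshold the run returns an empty call set
  with a warning.
* FDR estimates and q-values are capped at 1.
* Sorting of DE tables: decreasing $|\log_2 fc|$, mirroring
  report-style summary tables.

# Known limitations

* The Mann-Whitney p-values on distance multisets are anticonservative
  under the null (dependent pairs; see above) and are reported for
  procedural fidelity, not as calibrated error rates.
* Complete-case gene exclusion per contrast discards many genes when
  panels overlap weakly; with 70–95% panel coverage across six datasets,
  roughly two-thirds of presence-filtered genes drop from a typical
  contrast. Imputation was deliberately rejected as inventing data.
* Fold changes on per-dataset median-scaled pooled intensities are
  comparable across platforms but are not the within-study ratios a
  single-dataset analysis would report.
* Gene matching is by symbol only; divergent probe annotations across
  platforms are out of scope.
* BH is one specific FDR procedure; tools wrapping this analysis type do
  not always document theirs, so adjusted p-values need not match any
  particular external service.
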