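---
title: "Methods: per-cell positivity scoring and transcriptome comparison"
author: "trophoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell positivity scoring and transcriptome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophoquant)
```

trophoquant implements two analysis arms used when characterizing
trophoblast stem-cell cultures: scoring the fraction of marker-positive
nuclei in confocal immunofluorescence images against an isotype-control
threshold, and comparing bulk RNA-seq count profiles between cell types.
Both arms are paired with seeded synthetic-data generators that carry full
ground truth, so every stage of the pipelines can be validated by parameter
recovery rather than by eye.

## The imaging arm

### Model and procedure

An imaged field is a pair of grayscale channels over the same pixel grid: a
DAPI channel marking nuclei and a marker channel (e.g. CDX2) whose per-cell
intensity is the quantity of interest. The procedure is:

1. **Segmentation** (`segment_nuclei`). The DAPI channel is binarized with
   Otsu's global threshold, holes are filled, components smaller than
   `min_area` pixels (default 30) are discarded as debris, and the surviving
   components are labelled `1..n`. An optional watershed on the distance
   transform (`split_touching = TRUE`) separates touching nuclei; it is off
   by default because the synthetic generator guarantees separated nuclei
   and a watershed can only oversegment in that regime.
2. **Per-cell intensity** (`per_cell_mean_intensity`). Only marker pixels
   that overlap a labelled nucleus are used; each is assigned to the nucleus
   it overlaps, and the arithmetic mean per nucleus is the cell's raw
   intensity.
3. **Control threshold** (`control_threshold`). One isotype-control image
   per antibody/condition is processed identically; the average of its
   per-cell means is the positivity threshold for every experimental image
   of that condition.
4. **Scoring** (`score_cells`, `fraction_positive`). A cell's corrected
   expression is its raw mean minus the control mean, floored at zero; a
   cell is positive exactly when the corrected value is non-zero (strict
   inequality, so a cell at the threshold is negative). An image's score is
   the fraction of positive cells.
5. **Group comparison** (`compare_groups`). Per-image fractions from two
   treatment groups are compared with a two-tailed two-sample t test —
   Welch's form by default, the pooled-variance form behind `pooled = TRUE`;
   the choice matters little at the effect sizes of interest, and Welch is
   the safer default when image numbers differ.

Tunable parameters, with defaults: `min_area = 30` px (smallest credible
nucleus cross-section at typical confocal sampling), `split_touching =
FALSE`, `bit_depth = 16` (intensities in `[0, 65535]`), connectivity for
components is the 4-neighbour convention of the underlying labeller — for
disk-shaped nuclei 4- and 8-connectivity give identical labels.

### What the image generator emulates

`simulate_nuclei_field` renders nuclei as hard disks (radius 8 px by
default, constant interior intensity, no point-spread blurring) placed by
rejection sampling so that centres are farther apart than
`2 * radius + min_gap` with `min_gap = 3` px. The gap is deliberately
stronger than bare non-overlap: two disks whose rims are separated by less
than one pixel fuse into a single connected component after binarization,
which would silently corrupt count ground truth. Gaussian noise of
`noise_sd` (default 800, about 1.2% of the 16-bit range) is added to both
channels and clipped — not wrapped — to the valid range. DAPI is 30000
inside nuclei over a dark background; the marker channel is 20000 inside
positive nuclei and 2000 elsewhere.

The isotype-control generator (`simulate_control_field`) uses a nonspecific
staining level of 2600 by default, deliberately above the 2000 background
of a true-negative cell. This is not cosmetic: the positivity rule
thresholds at the *average* control-cell intensity, so if control staining
exactly equalled the negative-cell level, symmetric noise would put half of
the negative cells above the threshold and the positive fraction of a
marker-negative population would be estimated near 0.5 rather than 0. The
algorithm is identifiable only when the control level exceeds the
true-negative level by a margin large relative to
`noise_sd / sqrt(nucleus area)` — which is exactly the property an isotype
control is chosen to have (it bounds nonspecific signal from above). The
default margin of 600 is about eight per-cell standard errors at the
default noise.

Features of real data the generator does not model: point-spread functions
and optical blur, z-stacks, intensity gradients and vignetting, nuclear
texture, touching or overlapping nuclei, multinucleated syncytia, and
autofluorescence structure. Passing recovery tests therefore demonstrates
correctness of the measurement logic, not robustness to segmentation
failure modes of dense tissue imaging.

### Degenerate inputs and edge rules

An image that binarizes to all background yields zero nuclei — an error
only when it is used as a control or scored. A requested field too dense to
place fails with an explicit density error after a retry limit (default
50000 candidate draws). A labelled nucleus with no assigned marker pixels
(possible only with hand-edited label maps) gets mean 0 and a warning. If
both groups of `compare_groups` are constant the t statistic is degenerate:
equal means report `t = 0, p = 1`, unequal means `p = 0`, both with
warnings.

## The transcriptome arm

### Filtering, normalization, ordination

Genes expressed above background are those whose median count across
samples strictly exceeds the overall median of the matrix
(`filter_background`); the literal "median of all entries" reading is the
default, with the median-of-per-gene-medians alternative behind
`overall = "gene_medians"` because the phrase is genuinely ambiguous.

Sequencing depth is normalized by median-of-ratios size factors
(`size_factors`): the per-gene reference is the geometric mean across
samples, computed over genes with non-zero counts in every sample, and each
sample's factor is the median ratio of its counts to the reference. Note
these factors are *relative* depths — invariant to a global rescaling of
the whole matrix. `normalize_counts` divides by the factors and applies the
shifted log `log2(count/sf + 1)`, a monotone transform that stabilizes
variance at moderate counts; it is intentionally simple and documented as
such, not a reimplementation of model-based variance stabilization.

`expression_pca` centres genes (no scaling — expression changes should
weigh by magnitude) and returns sample scores with a deterministic sign
convention: each component's largest-magnitude gene loading is made
positive. `spearman_between_types` averages samples within each cell type
first, then rank-correlates the type profiles with mid-ranked ties;
two-sided p-values use the large-sample t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`. `cluster_samples` uses
`1 - Spearman rho` between samples as the distance and average linkage —
the correlation-based distance matches how transcriptome similarity is
usually judged, and average linkage reproduces ultrametric inputs exactly —
and emits Newick text for downstream tree tools.

### Differential expression and selection

`differential_expression` tests each gene by one-way ANOVA on the
log-scale normalized values, which for two groups is exactly the
pooled-variance two-sample t test. This is a deliberate, documented
stand-in for count-model (negative-binomial GLM) inference: it matches the
stated analysis plan of the workflow this package systematizes, and results
will diverge from a shrinkage-based NB fit especially at low counts.
P-values are FDR-adjusted by Benjamini–Hochberg step-up (`q_method =
"storey"` switches to Storey's estimate with a fixed lambda of 0.5). A gene
is *selected* iff `q < 0.05` and `|fold change| >= 1.5`.

Fold change is the ratio of group-mean normalized counts (linear scale;
`fold_on = "log"` computes it on the log values instead, since the source
wording does not pin this down), reported signed-symmetrically for group A
relative to group B: 2-fold up is `+2`, 2-fold down is `-2`, so the
threshold reads `|fc| >= 1.5` in both directions. Genes absent in both
groups get fold 1; genes with zero pooled variance get the degenerate rule
`p = 0` if the means differ, `p = 1` otherwise, with a warning.

Selected genes are split by direction (`split_by_direction`) and each list
is tested separately for gene-set enrichment (`fisher_enrichment`): the
right tail of the hypergeometric distribution for the overlap between the
list and each set, within the gene universe (sets are intersected with the
universe; list genes outside it are dropped with a warning), significant at
`p < 0.01`.

### The count generator

`simulate_count_matrix` draws negative-binomial counts with mean
`sf_s * mu_g * 2^(lfc_g)` in the second group and variance
`mu + dispersion * mu^2` (one common dispersion, default 0.05 — a typical
bulk RNA-seq value for well-behaved replicates). Defaults encode the study
conditions the benchmarks use: four biological replicates per group,
baseline means log-normal with median 200 and `sdlog = 1`, size factors
log-normal with `sdlog = 0.3`, planted |log2 fold change| of 2 with random
sign. `simulate_gene_sets` builds one planted set with a chosen overlap
with the differential list plus uniform decoy sets. One practical caution
encoded in the tests: the gene-set seed must differ from the count seed,
because two generators seeded identically subsample the same universe from
the same random stream and their draws are coupled.

What the count generator does not model: batch effects, gene-gene
correlation, length/GC biases, outlier samples, and per-gene dispersion
trends. Power and false-discovery-proportion results on it are therefore
upper bounds on real-data performance.

### delta-delta-Ct

`delta_delta_ct` computes, per sample, `dCt = Ct_target - Ct_reference`;
per target and group, `ddCt = mean dCt(group) - mean dCt(control group)`
and fold change `2^(-ddCt)`; and a per-target one-way ANOVA across groups
on the per-sample dCt values. Missing reference measurements are an error
naming the offending samples.

## Benchmark problem sizes

The recovery benchmarks in the test suite and `scripts/acceptance.R` use:
five planted fractions (0, 0.25, 0.5, 0.75, 1) at 3 images x 200 nuclei;
20 fields of 50 nuclei at 2% noise for counting; a 0.95-vs-0.25 fraction
contrast at 3 images per group; exhaustive Fisher enumeration over all
universes up to 30; 1000 random p-vectors for the BH oracle; 200 null and
20 planted-effect count simulations (200 and 1000 genes); 20 end-to-end
enrichment replicates. These sizes were chosen so the whole battery runs in
well under a minute while leaving the stochastic margins wide.

## Known limitations

* The imaging arm quantifies 2-D nuclear masks only; cytoplasmic or
  membrane localization, z-stacks, and syncytium detection are out of
  scope.
* The strict-mean control threshold has no built-in margin; interpreting
  fractions for markers whose negative population sits at the control level
  requires the isotype margin discussed above.
* Differential expression uses normal-theory tests on transformed counts,
  not a count likelihood; at very low counts or 2-replicate designs its
  p-values are approximate.
* Storey's q-value uses a single fixed lambda rather than the smoothed
  estimate; it is provided as an alternative, with BH the default.
* Spearman p-values use the t approximation, adequate for genome-scale gene
  counts but loose below ~10 genes.

```{r}
sessionInfo()
```
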