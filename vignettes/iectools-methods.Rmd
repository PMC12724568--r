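---
title: "Methods: cross-species programs, fate bias, and pH quantification in intestinal epithelial cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species programs, fate bias, and pH quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iectools)
```

## Scope

`iectools` implements the computational workflow used to characterize a rare
intestinal epithelial cell type — best4+ cells — across species and across
developmental perturbations:

1. **Preprocessing** of cells-by-genes count matrices: per-cell QC,
   log-normalization, variable-gene selection, covariate regression, PCA.
2. **Marker statistics**: Wilcoxon rank-sum and AUC marker tests with
   fold-change and percent-expressing filters, applied one-vs-rest or as
   genotype/region contrasts.
3. **Conservation scoring**: aggregation of per-species marker calls into
   ortholog families, conservation classes, and a cell-type specificity
   index.
4. **Regionalization**: within-cell-type spatial structure scored as
   correlation to an anchor gene with a permutation null.
5. **Fate bias**: a diffusion-map embedding of secretory derivatives,
   centroid-distance ranking of progenitors toward a reference cell type,
   and differential expression around the selected cells.
6. **Colorimetric and ratiometric pH quantification** from indicator color
   series and fluorescence readouts.

Every stage can be exercised end to end on synthetic data with planted
ground truth (the `simulate_*()` generators), which is how the test suite
and the acceptance script validate the pipeline without external data.

## Preprocessing

`qc_filter()` removes cells with too few detected genes or UMIs
(inclusive lower bound at 200), unusually high complexity (inclusive upper
bounds, 3500 genes; UMI cap 3000 under the `"pbx3a"` profile or 3500 under
`"meis1b"` — both experimental designs are shipped because the two
experiments used different caps), or mitochondrial content at or above 20%.
All stated bounds are inclusive: a cell at exactly 200 genes or exactly 20%
mitochondrial reads fails. Mitochondrial genes are identified by the `mt-`
prefix; ribosomal genes come from an explicit list (the zebrafish list is
shipped in `inst/extdata/`).

`log_normalize()` sets `norm = ln(1 + 1e4 * count / total)`, so de-logged
per-cell totals return exactly the scale factor — an identity the tests
assert. `select_hvg()` offers two rankings: the plain standard-deviation
ranking (used historically for some datasets) and a count-level
variance-stabilizing ranking that fits a degree-2 polynomial mean-variance
trend, standardizes counts by the trend sd, clips at `sqrt(n_cells)`, and
ranks by clipped variance. The polynomial trend replaces a loess fit: it is
deterministic, dependency-free, and adequate over the 2–3 decades of mean
expression the data span. The sd ranking conflates mean-driven and
biological variability (its planted-gene recall is visibly worse in the
test suite); the trend method is the default recommendation.

`scale_regress()` takes per-gene OLS residuals on mitochondrial and
ribosomal percentages (with intercept), z-scores, and clips at ±10 —
clipping bounds the influence of rare outlier cells exactly as standard
single-cell scaling does. `run_pca()` keeps 30 components by default; signs
are fixed by making each component's largest-magnitude loading positive so
results are reproducible across BLAS implementations.

Batch correction is intentionally not reimplemented; an optional per-batch
mean-centering in PC space would be the only integration offered, and
cluster labels are treated as inputs (no clustering, no UMAP).

## Marker statistics

`rank_sum_test()` is the two-sided Mann–Whitney test with tie correction —
exact enumeration when the pooled sample is at most 10 without ties, normal
approximation with continuity correction otherwise. The test suite checks
the exact branch against an exhaustive enumeration over all rank
assignments, and checks that the two branches agree (within 0.02) in the
significant regime where the filters operate; near the null center the
exact p of tiny samples is coarsely discrete and no smooth approximation
can track it pointwise.

Fold changes use natural log with a +1 pseudocount on de-logged
group means: `lfc = ln((mean_in + 1)/(mean_out + 1))`. The natural-log base
is fixed by the correspondence between the conventional threshold 0.25 and
the stated 1.28-fold floor (`exp(0.25) = 1.284`). Threshold semantics:
fold-change and percent-gap floors are inclusive ("at least"), the p gate
is strict (`p < 0.01`), and the gate is applied to the **raw** p value by
default — Bonferroni-adjusted values are always reported, and
`p_adjust = "bonferroni"` or `"bh"` moves the gate onto adjusted p for
users who prefer it. The inclusive comparisons carry a 1e-9 numerical
tolerance so that boundary cases like a percent gap of `0.6 - 0.5` are not
lost to float rounding. One-vs-rest marker calls additionally require a
percent-expressing gap of at least 0.1; genotype and fate-bias contrasts
do not (they use only the testability rule `min.pct = 0.1` and the fold
floor, in both directions), mirroring the two different call signatures the
workflow uses.

Output tables are sorted by `(p, -lfc, gene)` so repeated runs write
byte-identical files.

## Conservation scoring

Per-dataset marker lists are mapped onto reference ortholog families with
an **any-ortholog rule**: a family counts as marked in a species if any of
its genes there — including paralogs, e.g. both zebrafish pbx3a and pbx3b
for the PBX3 family — is a marker. Families marked in at least 6 of 8
datasets are `conserved`; families marked in exactly one are
`species_specific`. A clade rule captures programs restricted to mammals or
to aquatic species: at least 75% of the clade's datasets marked and at most
one flag outside the clade. The 75%/one-outside numbers are package
conventions — the clade-restricted repeat itself has no published numeric
rule — and both are configurable.

The specificity index of a gene is
`100 * mean_target / sum over clusters of mean_cluster`, with means taken
on de-logged normalized expression — i.e. the percentage of the gene's
mRNA (in normalized units) attributable to the target cluster. It sums to
100 over clusters whenever the gene is expressed, a property the tests
assert. A log-scale mean alternative would damp the index toward uniform;
the de-logged form matches the "percent of mRNA" reading and is the
default. Families with no annotated gene in a species are `NA` (unknown),
never `FALSE`: missing annotation neither supports nor contradicts
conservation.

## Regionalization

Within one cluster, every gene is correlated (Pearson by default) with an
anchor gene's log-normalized expression. Significance comes from
permutations of the anchor (1000 by default) with the add-one correction
`p = (1 + #{|r_perm| >= |r|}) / (n_perm + 1)`, so the smallest attainable p
is `1/(n_perm+1)`; the permutation null avoids committing to a parametric
distribution under dropout. Cells with zero anchor counts are retained by
default — dropout itself is informative about position — with a flag to
restrict to anchor-positive cells. Spearman correlation is available and is
invariant to monotone rescaling. Calls are gated at `p < 0.05`; direction
labels (anterior/posterior) are presentation-layer only, the engine reports
signs relative to the anchor.

## Fate bias

The diffusion map is built from the leading 30 PCs: a symmetric kNN graph
(k = 30, union of directed edges), a locally scaled Gaussian kernel
`w_ij = exp(-d_ij^2 / (sigma_i sigma_j))` with `sigma_i` the distance to
the cell's `ceiling(k/2)`-th neighbor, density normalization by the product
of row sums (the alpha = 1 anisotropic construction), and row
normalization to a Markov matrix. Diffusion components are right
eigenvectors 2..11 by decreasing eigenvalue, computed exactly through the
symmetric conjugation `D^{-1/2} W D^{-1/2}` and validated against a dense
non-symmetric eigendecomposition to 1e-8. A disconnected graph is an error
listing component sizes rather than a silent multi-component embedding.

Fate bias follows the published recipe: the centroid of the reference
cluster (wild-type best4+ cells) in DC1–DC2, Euclidean distances of
progenitors to that centroid, and per-genotype selection of the closest
25% (`ceiling(q*n)`, ties broken by cell id). Distances use raw eigenvector
coordinates; eigenvalue scaling is available behind a flag since the
original toolchain leaves the choice unstated, and the kernel itself is a
package decision validated by the oracle test rather than by bit-matching
any external implementation. Both genotypes are embedded jointly.

## Colorimetry and pH

ROI colors are channel-wise means over rectangles. `background_shift()`
recenters each image's background on the per-experiment mean background,
shifting the ROI color by the same offset — an additive correction that
preserves roi−bg contrasts exactly. "HCL" is the polar form of CIE L\*u\*v\*
under D65 (the dialect of base R and farver; the term is ambiguous across
color libraries, so the choice is stated explicitly). Shift-induced
out-of-gamut components are clamped to [0, 255] with a logged count. The
gray axis resolves to chroma ≈ 1e-2 rather than exactly zero under the
conversion's finite-precision constants, so the achromatic guard flags
chroma below 0.05 and reports hue 0 for those records.

Hue is shifted by 180° so the circular wrap point leaves the indicators'
color range; after the shift, plain linear means and t-based 95% confidence
intervals across animals are valid (circular statistics are deliberately
not used). Fourth-degree polynomial fits of hue on chroma and on luminance
(with R²) verify that hue alone describes the indicator state; a
constant-hue input reports R² = 1 with a zero-variance note.

For recovery of a pH relaxation `ph(t) = ph_home + (ph0 - ph_home)
exp(-t/tau)` from a hue trace, the package fits **in hue space** through a
monotone calibration curve built from known-pH standards
(`ph_standards()` + `fit_hue_relaxation()`). Pointwise hue→pH inversion is
ill-posed wherever the indicator saturates (with pKa 8 and a pH 4→7.5
transient, most of the early trajectory is invisible to the dye), and in
our experiments it overestimated the time constant severalfold; the
hue-space fit keeps the information in the indicator's takeoff time and
recovers tau to within a few percent at realistic noise. The 95% CI choice
is t-based (not bootstrap), flagged in `hue_timeseries()`.

`phluorin_ratio()` is the background-subtracted 405/488 excitation ratio
(invariant to common detector gain; non-positive denominators are excluded
as NA), and `ctcf()` is integrated density minus area times mean
background.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed and the tests run against them.

**Multi-species design** (`simulate_multispecies()`): 8 datasets labeled
alternately mammal/aquatic, 6 shared clusters, 40 cells per cluster, 150
ortholog families, counts Negative Binomial with dispersion 0.5 and
lognormal library-size variation (sdlog 0.3). 20 families are planted
8-fold up in the best4 cluster of at least 6 datasets ("conserved"), 10 in
exactly one ("species-specific"); each family may have two paralogs per
species at rate 0.2. The 8-fold effect and 0.5 dispersion are calibration
choices in the generator's configuration, not published values.

**Trajectory pair** (`simulate_trajectory_pair()`): wild-type trunk cells
on pseudotime t ∈ [0,1] from secretory progenitors to best4+ cells; mutant
trunk cells only below t = 0.5 with the 50-gene terminal program forced to
zero mean (the fate is unreachable, not merely delayed). Progenitor-identity
genes are identical between genotypes and decline only at terminal
differentiation — the mutant's progenitors are transcriptionally normal by
construction. The continuum is carried by a 300-gene maturation gradient
(half linear ramps, half sigmoidal switches staggered along t): real
differentiation continua involve genes turning on and off at every stage,
and with dispersion 0.5 the per-gene information saturates, so the density
of independently informative genes is what determines how precisely a
cell's position can be read. Both genotypes also form goblet and
enteroendocrine branches (unaffected by the mutation). The branches matter
for geometry: a pure one-dimensional chain embeds as the classic
diffusion-map horseshoe, in which DC2 curls the two ends toward each other
and distance-to-terminal-centroid in DC1–DC2 stops being monotone in
pseudotime; with side branches occupying DC2 — as in the tissue, where the
embedding covers all secretory derivatives — the centroid distance orders
progenitors correctly.

**Regionalization** (`simulate_regional()`): best4 cells with latent
position u ~ U(0,1); a strongly expressed anchor whose mean decreases in u
(the emulated anchor, otop2, is among the strongest markers of the cell
type — a weak anchor would attenuate every gene–anchor correlation by its
own sampling noise); 40 regional genes monotone in u, half opposing the
anchor. The planted program is compositionally balanced — opposing
amplitudes are rescaled so the summed planted mean (anchor included) is
constant in u. Without this, library-size normalization couples every gene
to the anchor and the "null" genes are not null in the realized data; with
it, the permutation gate's false-positive rate sits at its nominal 5%.
Background genes are drawn at moderate expression, as in a real
within-cell-type scan over expressed genes; very low-expressed genes share
a dropout-driven factor that again correlates everything with everything.

**pH series** (`simulate_ph_series()`): first-order pH relaxation, a
two-form indicator mixing in linear light via Henderson–Hasselbalch
(`f = 1/(1 + 10^(pKa - pH))`, pKa 8.0 as a phenol-red-like configuration
default), sRGB gamma encoding, a background offset, and Gaussian noise of
sd 0.5 on the ROI mean (each ROI averages ~11,000 pixels, so sub-unit noise
on the mean is the realistic regime). Imaging every minute over 30 minutes
across 6 animals.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: ambient RNA, doublets, batch chemistry,
cell-cycle structure, annotation errors in the ortholog table, spatial
autocorrelation beyond a single latent axis, indicator bleaching, or
illumination drift. Recovery rates on this synthetic ground truth are upper
bounds on what the same thresholds achieve on real atlases.

## Problem sizes and runtime

The validation suite uses 8 datasets × 240 cells for conservation
(~1,900 cells, ~180 genes per dataset), ~1,100 cells × 740 genes for the
fate-bias tree, 300 cells × 150–240 genes with 1,000 permutations for
regionalization, a 60-cell instance for the dense diffusion-map oracle, and
1,000 random colors for the conversion check. These sizes give every
recovery metric a comfortable margin over its threshold while keeping the
entire suite and the acceptance script each within a couple of minutes on
one CPU; they are the package's chosen validation conditions, and all are
parameters of `sim_spec()` for users who want larger experiments.

## Known limitations

- The normalization (global scale factor 1e4) is the workflow's own; no
  alternative size-factor estimators are offered.
- The conservation classes depend on the marker thresholds upstream; there
  is no uncertainty propagation from marker calls to conservation calls.
- The permutation null in regionalization treats cells as exchangeable;
  cryptic structure (batch, cell cycle) within a cluster would inflate
  calls on real data.
- The diffusion map solves a dense eigenproblem — exact and simple at 10³
  to low-10⁴ cells; beyond that an iterative solver would be needed.
- Hue→pH calibration is supported only as monotone interpolation of
  user-provided standards; no indicator chemistry is asserted.
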