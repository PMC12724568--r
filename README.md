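# iectools

Analysis toolkit for rare intestinal epithelial cell types, built around
the computational workflow used to characterize **best4+ cells** — a
vertebrate-conserved, BEST4/CFTR/OTOP2-expressing epithelial cell type that
is absent from mice and therefore studied across species atlases and in
zebrafish. The package is for single-cell researchers who want to run (or
audit) that workflow end to end: score how conserved a cell type's
transcriptional program is across species, dissect spatial heterogeneity
within the cell type, quantify developmental fate bias in mutant-vs-wild-type
designs, and measure luminal/intracellular pH from imaging readouts.

## What it computes

**Marker tests and filters.** One-vs-rest markers per dataset with the
two-sided Wilcoxon rank-sum test (exact for pooled n ≤ 10 without ties,
normal approximation with continuity correction otherwise), natural-log
fold change on de-logged means with a +1 pseudocount,

    lfc = ln((mean_in + 1) / (mean_out + 1)),

retained when `lfc ≥ 0.25` (≡ fold ≥ e^0.25 = 1.284, inclusive), `p < 0.01`
(strict, raw p by default), and `pct_in − pct_out ≥ 0.1`; an AUC
(`U/(n_A n_B)`, ties half) accompanies every call.

**Cross-species conservation.** Marker lists are mapped onto ortholog
families under an any-ortholog rule (paralogs count), classified as
*conserved* (≥ 6 of 8 datasets), *clade-conserved*, *species-specific*
(exactly 1), or *shared-partial*, and annotated with the specificity index

    S = 100 · mean_target / Σ_clusters mean_cluster

(the percent of a gene's mRNA attributable to the target cluster; sums to
100 across clusters).

**Regionalization.** Per-gene correlation to an anchor gene (e.g. *otop2*)
within one cluster, permutation p values with add-one correction, and
calls `correlated` / `anti_correlated` at p < 0.05.

**Fate bias.** Diffusion map of secretory derivatives (kNN graph with
k = 30 on 30 PCs, locally scaled Gaussian kernel, α = 1 density
normalization), Euclidean distance of each progenitor to the wild-type
best4+ centroid in DC1–DC2, selection of the closest 25% per genotype, and
differential expression among the selected sets.

**pH quantification.** Background-shifted ROI colors → HCL (polar CIE
L\*u\*v\*, D65) → 180°-shifted hue traces with t-based 95% CIs, quartic
hue–chroma/hue–luminance fits, relaxation-time recovery through a monotone
hue↔pH calibration, plus the ratiometric 405/488 readout and
`CTCF = IntDen − Area × mean background`.

Every generator in `simulate_*()` plants known ground truth (conserved
families, pseudotime and bias flags, regional signs, pH curves), so the
whole pipeline is validated by recovery, not by fixtures.

## Worked example

```r
library(iectools)

sim <- simulate_multispecies(sim_spec(seed = 1))   # 8 species, planted truth
res <- build_program_table(sim$datasets, sim$orth,
                           conservation_config(clade_labels = sim$truth$clades))
res
#> <conservation_result> 30 families across 8 datasets
#>   conserved: 20, species_specific: 10

dplyr::select(res$records, family, n_marked, class) |> head(4)
#> # A tibble: 4 × 3
#>   family n_marked class
#> 1 FAM001        6 conserved
#> 2 FAM002        8 conserved
#> 3 FAM003        7 conserved
#> 4 FAM004        7 conserved
```

All 20 planted conserved families are recovered as `conserved` (flagged in
≥ 6 of 8 datasets) and the 10 planted species-specific families as
`species_specific`; no background family is called conserved. Per-dataset
marker calls behind the table:

```r
ds <- log_normalize(sim$datasets$dataset1)
find_markers(ds, "best4") |>
  dplyr::select(gene, lfc, p, p_adj, pct_in, pct_out) |> head(3)
#> # A tibble: 3 × 6
#>   gene               lfc        p    p_adj pct_in pct_out
#> 1 species1-fam006a  1.86 1.22e-19 2.24e-17  1       0.36
#> 2 species1-fam014a  1.70 1.67e-17 3.07e-15  0.975   0.395
#> 3 species1-fam017b  1.73 7.08e-17 1.30e-14  0.975   0.385

specificity_index(ds, "species1-fam006a", "best4")
#> [1] 57.1
```

The top marker is ~6.4-fold up (`e^1.86`) in best4+ cells and carries 57%
of that gene's normalized mRNA. A pH relaxation recovered from a simulated
indicator trace (planted: pH 4 → 7.5, τ = 5 min):

```r
ser <- simulate_ph_series(seed = 1)
fit_hue_relaxation(hue_records(ser), ph_standards(seq(3, 9.5, 0.25)))
#> # A tibble: 1 × 3
#>     ph0 ph_home   tau
#> 1  4.11    7.50  5.08
```

Result types are tibbles; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures (`autoplot(dm)` for diffusion maps,
`plot_conservation(res)` for the specificity heatmap,
`plot_hue_timeseries()` for hue traces).

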