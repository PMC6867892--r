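# rotshift

Comparative decay-stage transcriptomics of brown- and white-rot wood-decay
fungi.

Wood-decay basidiomycetes grown directionally along wood wafers create a
spatial decay gradient: the section at the advancing hyphal front
(0–5 mm) is colonized but undecayed "early" wood, while sections 15–20 mm
and 30–35 mm behind the front are progressively older. Sampling the
transcriptome along this gradient turns space into a decay time series.
`rotshift` is for researchers comparing such gradients across species and
nutritional modes — brown rot (reactive-oxygen pretreatment, selective
carbohydrate extraction) versus white rot (enzymatic lignin degradation) —
who want to know which genes are decay-stage-dependent, which of those are
unique to one rot type, and how transcription is partitioned between
lignocellulose-oxidizing (LOX) and glycoside hydrolase (GH) functions.

## What the package computes

Given gene-level count matrices (genes × samples), a sample sheet, a
functional annotation and an ortholog-group table, the pipeline:

1. **Normalizes and tests.** RPKM = 10⁹·c/(L·N); expression evidence
   (RPKM > 5 in all/some/no sections → full/partial/none); and for each of
   the three section contrasts an exact conditional negative-binomial test
   with common dispersion φ (variance μ + φμ²; φ estimated by conditional
   maximum likelihood). Conditional on the two-group total *t*, the
   group-1 sum *k* is distributed as

   P(k | t) ∝ C(k + n₁/φ − 1, k) · C(t − k + n₂/φ − 1, t − k),

   binomial at φ = 0; the two-sided p sums all splits at most as probable
   as the observed one. DEGs require FDR < 0.05 (Benjamini–Hochberg) and
   FC > 4.
2. **Stages.** The direction triple over the three contrasts maps each
   gene to one of eight temporal subgroups; subgroups I–IV pool as
   **early**-upregulated (hyphal front), V–VIII as **late**.
3. **Compares across species.** Stage sets are lifted to ortholog-group
   ids (reciprocal-best-hit groups, or any externally supplied table) and
   partitioned by a four-way Venn into rot-type-unique and common cells.
   Sample similarity uses the early-to-late ratio
   r = log₂[RPKM₀₋₅ / avg(RPKM₁₅₋₂₀, RPKM₃₀₋₃₅)] per ortho-DEG group,
   Spearman correlation, and euclidean/complete hierarchical clustering.
4. **Quantifies investment.** Per-family early/late DEG counts with
   Fisher and paired-t shift tests, hypergeometric term enrichment, the
   GH:LOX transcription ratio Σ RPKM(GH)/Σ RPKM(LOX) per species and
   section, PCA of family-summed expression, and Z-score scaling.

A synthetic-data module (`sim_config()`, `simulate_decay_experiment()`)
generates the full four-species wafer design — negative-binomial counts
with stage-dependent fold multipliers, orthology structure and LOX/GH
class labels — with known ground truth, so the entire pipeline can be
exercised and calibrated without external data.

## Worked example

Simulate the default study design (2 brown-rot + 2 white-rot species ×
3 sections × 3 replicates, 2 000 ortholog groups) and run the pipeline:

```r
library(rotshift)
cfg <- sim_config(seed = 7)
sim <- simulate_decay_experiment(cfg)
res <- run_decay_pipeline(sim$counts, sim$design, sim$annotation,
                          sim$orthogroups)
res
#> decay_pipeline: 4 species; 336 early / 455 late stage DEGs
#>   brown-unique ortho-DEGs: 69 early, 98 late
#>   LOX shift Fisher p = 0.000596; paired t p = 0.078
```

336 genes across the four species are early-upregulated (peak at the
hyphal front) and 455 late-upregulated; 69 + 98 ortholog groups are
stage-DEGs in both brown-rot species but neither white-rot species. The
LOX shift test shows brown-rot LOX differential expression concentrated in
early decay:

```r
res$shift_tests$fisher$table
#>       early late
#> brown     8    0
#> white    14   28
```

The transcriptional-investment ratio at the late (30–35 mm) section
separates the rot types — brown-rot fungi spend an order of magnitude more
transcription on GH than LOX, white-rot fungi the reverse:

```r
subset(res$investment, section == "30-35mm")
#>  species section   gh_rpkm  lox_rpkm gh_lox_ratio
#>      Ppl 30-35mm 177245.44  14965.21   11.8438292
#>      Gtr 30-35mm 177885.03  13977.85   12.7262071
#>      Tve 30-35mm  58796.37 202614.33    0.2901886
#>      Pos 30-35mm  44632.72 270893.84    0.1647609
```

Clustering the Spearman correlations of per-replicate early-to-late
ratios splits the twelve samples into a brown-rot and a white-rot clade:

```r
clusters_by_rot_type(res$clustering, res$rot_type)
#> [1] TRUE
```

The published table of brown-rot-unique decay-stage-dependent DEGs ships
as a plain-text fixture:

```r
count_brown_unique_degs()
#> $early
#> [1] 34
#> $late
#> [1] 18
#> $total
#> [1] 52
```

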