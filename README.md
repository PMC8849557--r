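# lineageFidelity

Quantification of **loss of epithelial lineage fidelity** from keratin
immunofluorescence. In healthy young mammary ducts, inner luminal cells
(LEps) express keratin 19 and outer myoepithelial cells (MEps) express
keratin 14 almost exclusively; in aged tissue and in carriers of germline
*BRCA1*/*BRCA2*/*PALB2* mutations, LEps gain KRT14 while keeping KRT19.
This package implements the three quantitative readouts of that
phenotype, plus a calibrated synthetic-data generator so the whole
pipeline is testable without patient data:

- **Tissue quantification** — Otsu thresholding of the KRT14/KRT19
  channels, AND/OR mask algebra, and the three coexpression area ratios

  r_LEp = AND/KRT19, r_all = AND/OR, r_MEp = AND/KRT14,

  aggregated per sample and compared between groups by Mann–Whitney /
  Kruskal–Wallis + Dunn.
- **Differentiation readout** — marker-based watershed segmentation of
  progenitor-colony images, per-cell mean keratin intensities, four-state
  gating (undifferentiated / K14-only / K19-only / double-positive) and
  chi-square comparison of state distributions.
- **Signature overlaps** — lineage-specific and aging gene sets filtered
  from DE tables (fold-change and BH-FDR cutoffs), with one-sided Fisher
  overlap statistics: sample odds ratio OR = ad/bc, log2(OR), and the
  hypergeometric upper-tail p-value.
- **Synthetic data** — duct images with per-cell ground truth whose
  archetype parameters map onto the expected ratios in closed form,
  four-state colony intensity mixtures, DE tables with planted effects,
  and gene-list pairs realising any 2×2 contingency.

The methods, calibration derivations and design decisions are documented
in the vignette: `vignettes/lineage-fidelity-methods.Rmd`.

## Worked example

```r
library(lineageFidelity)

# one synthetic duct image: 25% of luminal cells coexpress KRT14
img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 0.25), seed = 1)
quantifyImage(img)
#> FidelityRecord [NA/NA]: r_lep = 0.1992, r_all = 0.0999, r_mep = 0.1671
```

About 20% of the KRT19-positive area is also KRT14-positive (the planted
25% dilutes against myoepithelial KRT19 area in the denominator —
`truthFidelity(img)` shows the ground-truth counterpart). A full cohort
comparison:

```r
rep <- runDemo("demo_out", seed = 7)   # 5 HR + 5 AR samples, 3 images each
jsonlite::read_json("demo_out/tissue_comparison.json")
#> $metric    "r_lep"
#> $group_means$AR 0.076   $group_means$HR 0.323
#> $omnibus: Mann-Whitney U, U1 = 0, p = 0.00794 (exact enumeration)
```

The HR cohort mean r_LEp (32%) sits far above the AR mean (7.6%), and the
exact Mann–Whitney test separates the groups. The demo also writes
per-image and per-sample CSVs, colony state distributions with their
chi-square comparison, signature GMTs and overlap JSONs, plus a
`run_report.json` with an MD5 manifest of every output.

```r
# gene-set overlap arithmetic
l <- constructOverlapLists(77, 100, 100, 1000)
overlapTest(l$A, l$B, l$universe)
#> OverlapResult: a=77 b=100 c=100 d=1000 | OR = 7.7 (log2 2.945), p = 8.575e-27
```

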