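---
title: "Quantifying loss of epithelial lineage fidelity: models and methods"
author: "lineageFidelity package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loss of epithelial lineage fidelity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageFidelity)
```

## The scientific problem

The mammary duct is a bilayered epithelium: an inner layer of luminal
epithelial cells (LEps) canonically expressing keratin 19 (KRT19), wrapped
by an outer layer of basal/myoepithelial cells (MEps) expressing keratin 14
(KRT14). In healthy young tissue the two markers are close to mutually
exclusive. With age, and in carriers of germline *BRCA1*, *BRCA2* or
*PALB2* mutations, LEps begin to coexpress KRT14 while retaining KRT19 — a
*loss of lineage fidelity* that this package quantifies from three angles:

1. **Tissue images** — how much of the KRT19-positive area is also
   KRT14-positive (`keratin_quant` functions)?
2. **Progenitor differentiation** — what fraction of cKit-positive
   progenitor progeny stays undifferentiated or differentiates with a
   basal (KRT14-positive) bias (`differentiation` functions)?
3. **Transcriptomes** — do genes upregulated in high-risk epithelia
   overlap the opposite lineage's signature or an aging signature
   (`signatures` functions)?

Since the package must be testable without patient material, a calibrated
synthetic-data generator produces all three kinds of input with per-cell
ground truth.

## Mask-based coexpression quantification

For each image the KRT14 and KRT19 channels are thresholded independently
by Otsu's criterion (the threshold maximising between-class variance of a
256-bin intensity histogram; pixels strictly above the threshold are
foreground). From the two binary masks we form the intersection (AND) and
union (OR) masks and record four pixel areas $a_{14}, a_{19},
a_{\mathrm{AND}}, a_{\mathrm{OR}}$ with the exact identity
$a_{\mathrm{OR}} = a_{14} + a_{19} - a_{\mathrm{AND}}$. The three
lineage-fidelity statistics are area ratios:

$$
r_{\mathrm{LEp}} = \frac{a_{\mathrm{AND}}}{a_{19}}, \qquad
r_{\mathrm{all}} = \frac{a_{\mathrm{AND}}}{a_{\mathrm{OR}}}, \qquad
r_{\mathrm{MEp}} = \frac{a_{\mathrm{AND}}}{a_{14}},
$$

interpreted as the fraction of KRT19⁺ cells also expressing KRT14, the
double-positive fraction of all epithelium, and the fraction of KRT14⁺
cells also expressing KRT19. Because synthetic cells have equal expected
area, area ratios and cell-count percentages coincide in expectation, which
is how the package reads the ratios as "% of cells".

Choices worth knowing:

* **"Automated thresholding" is Otsu.** Several automated schemes exist in
  common imaging software; Otsu is deterministic, standard and close to
  ImageJ's default. It is confined to `autoThreshold()` so it can be
  swapped.
* **Per-image thresholds.** Each image is thresholded on its own
  histogram, not per staining batch.
* **Zero denominators are missing values.** A ratio with an empty
  denominator mask is flagged missing (`NA`) and excluded from per-sample
  means rather than coerced to 0, which would bias sparse images.
  Constant channels yield an empty mask with a degenerate flag.
* **Aggregation is per sample.** Group statistics run on per-sample means
  of per-image ratios (one dot per donor), not on pooled images.
* **No automatic stromal segmentation.** An optional user-supplied ROI
  mask restricts both threshold fitting and mask areas; by default the
  whole frame is epithelium, which is true of the synthetic images.

```{r quantify-demo}
img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 0.25), seed = 1)
quantifyImage(img)
truthFidelity(img)  # ground-truth counterpart from the generator truth
```

## The synthetic duct generator and its calibration

`generateDuctImage()` renders each duct as a ring of MEp disks enclosing
rings of LEp disks on a dark background (16-bit-like intensity scale:
background 100, foreground 3000, Gaussian noise SD 50 — a high but
realistic immunofluorescence contrast that keeps Otsu segmentation
essentially exact). An archetype is the triple $(x, \alpha, \beta)$:
luminal area fraction, probability that a luminal cell coexpresses KRT14,
probability that a myoepithelial cell coexpresses KRT19. Writing
$A = \alpha x + \beta(1-x)$ for the expected AND fraction, the expected
ratios are closed-form:

$$
E\,r_{\mathrm{LEp}} = \frac{A}{x + \beta(1-x)},\quad
E\,r_{\mathrm{all}} = A,\quad
E\,r_{\mathrm{MEp}} = \frac{A}{(1-x) + \alpha x},
$$

which imply $1/r_{\mathrm{all}} = 1/r_{\mathrm{LEp}} +
1/r_{\mathrm{MEp}} - 1$. The calibration targets for a high-risk (HR)
cohort are the printed cohort means $(r_{\mathrm{LEp}}, r_{\mathrm{MEp}},
r_{\mathrm{all}}) = (0.31, 0.18, 0.11)$ — and these *violate* the identity
above ($1/0.31 + 1/0.18 - 1 = 7.78 \ne 1/0.11 = 9.09$). No single
homogeneous archetype can reproduce all three at once; biologically, the
cohort is heterogeneous. The HR preset is therefore a three-archetype
mixture solved so the weighted means hit all three targets:

```{r presets}
sapply(tissuePreset("HR")@archetypes, expectedRatios)
tissuePreset("HR")@weights
expectedRatios(tissuePreset("AR")@archetypes[[1]])
```

The average-risk (AR) pair (7%, 3%) *is* self-consistent, so the AR preset
is a single archetype. Tests verify the calibration by Monte-Carlo over
520 simulated samples (truth fast path, `render = FALSE`), requiring every
cohort mean within 0.01 of its target.

Two design points deserve emphasis:

* **Archetypes are apportioned, not drawn.** With 23 samples and archetype
  $r_{\mathrm{LEp}}$ values of 0.50/0.12/0.31, drawing each sample's
  archetype independently would give the cohort mean a standard error of
  about 2.8 percentage points — larger than the recovery tolerance itself.
  `generateTissueCohort()` instead allocates archetype counts by largest
  remainder (assignment order randomised), so the cohort composition
  matches the weights exactly and only binomial coexpression noise
  remains.
* **Geometry is non-overlapping by construction.** Cells in a ring are
  spaced by chord (not arc) distance so disks never overlap; overlapping
  disks would otherwise leak pixels between neighbouring cells and bias
  the AND mask upward.

The generator does **not** attempt realistic tissue texture: no stroma,
adipose, uneven illumination, out-of-focus light, partial-volume edges or
lesion morphology, and no 3D stacks. Passing recovery tests therefore
shows the *measurement pipeline* is unbiased on geometrically clean input
with known truth; it does not validate robustness to the artefacts of real
sections.

## Single-cell differentiation readout

`generateColonyCells()` draws each cell's state from a four-state mixture
(undifferentiated, K14-only, K19-only, double-positive) and its two
keratin intensities from per-state log-normal distributions; the default
model separates "low" (median 50) and "high" (median 1000) modes 20-fold
with `sdlog` 0.35, so the modes are ~4 SD apart on the log scale and
gating error is well under 2%. The paper-calibrated mixtures are the
day-2 undifferentiated fractions (AR 0.29, HR 0.50) and the day-7
KRT14-positive totals (K14-only + double-positive: AR 0.34, HR 0.51); the
remaining splits within each preset are the package's own invented
choices, fixed once:

```{r colony-presets}
rbind("AR-day2" = colonyPreset("AR-day2")@stateProportions,
      "HR-day2" = colonyPreset("HR-day2")@stateProportions,
      "AR-day7" = colonyPreset("AR-day7")@stateProportions,
      "HR-day7" = colonyPreset("HR-day7")@stateProportions)
```

On images, `segmentCells()` is a marker-based watershed: Otsu threshold of
the nuclei channel, distance-transform watershed of the nuclear mask for
seeds, then seeded propagation (EBImage) over the summed keratin signal
restricted to the cell mask. `measureCells()` averages each keratin
channel within each label.

**Gates.** The assay defines "undifferentiated" as low in both markers but
gives no numeric gate. `fitGates()` fits, per channel, an Otsu threshold
on log-transformed per-cell means; if the best split explains less than
half the variance the channel is treated as effectively unimodal and the
gate falls back to the 75th percentile (flagged). Note the 50% rule is a
coarse unimodality screen: a tight single Gaussian mode can still split at
~64% explained variance, so the fallback mainly catches heavy-tailed or
degenerate channels. On the bimodal preset mixtures the Otsu gate is the
one used. Cells *at* a gate count as positive. Gates are fitted per
experiment (pooled over that experiment's cells), since staining batches
differ; state percentages are pooled per experiment, not per colony.

Distributions are compared by Pearson's chi-square on the count
contingency without continuity correction (cell counts in this assay are
in the hundreds to thousands); all-zero state columns are dropped, and any
expected count below 5 sets a warning flag rather than switching tests.
"KRT14⁺ progeny" counts K14-only plus double-positive cells.

## Gene-signature overlap statistics

Signatures come from DE tables by the stated filters: lineage-specific
sets keep genes with `log2fc >= 1` (twofold, inclusive) and BH-adjusted
`padj < 0.001`; aging signatures keep upregulated genes with
`padj < 0.05`. Both filters are row-order invariant and record their
parameters in the set's provenance.

Overlap between sets $A$ and $B$ in universe $U$ uses the 2×2 membership
table $(a, b, c, d)$ and reports the **sample odds ratio**
$\mathrm{OR} = ad/bc$ with $\log_2(\mathrm{OR})$, tested one-sided by
Fisher's exact test, i.e. the hypergeometric upper tail
$P(X \ge a)$, $X \sim \mathrm{Hypergeom}(N{=}|U|, K{=}|A|, n{=}|B|)$,
evaluated on the log scale. Conventions:

* The sample OR (not the conditional-MLE OR that `fisher.test()`
  estimates) is the primary estimate: it is exact, closed-form and matches
  the worked-example arithmetic (e.g. $(77 \cdot 1000)/(100 \cdot 100) =
  7.7$); the two estimators agree to printed precision for large tables.
* $bc = 0$ with $ad > 0$ is flagged infinite rather than silently capped;
  an optional Haldane +0.5 correction is available.
* The universe defaults to all genes of the DE table(s) under comparison,
  overridable — published overlap ORs depend on the universe choice, so
  absolute published values are only reproducible as worked-example
  arithmetic unless the original lists are supplied.

`constructOverlapLists()` inverts the test (it builds lists realising any
chosen table), which gives the suite an exact round-trip property.

## Statistical core

The nonparametric tests the pipeline depends on are implemented in the
package with exact small-sample branches, each cross-checked in the test
suite against enumeration oracles and the corresponding base-R routine:

* `mannWhitney()`: exact two-sided p by enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments when both groups are ≤ 8 without
  ties; otherwise normal approximation with tie and continuity
  correction. Both U conventions are reported since software differs.
* `chiSquareIndependence()`: Pearson statistic from marginal expected
  counts, no Yates correction.
* `spearmanTest()`: midrank correlation with the two-sided t
  approximation; perfectly monotone pairings report p = 0 with an
  exact-monotone note; constant input is flagged undefined.
* `bhAdjust()`: BH step-up. It never decreases a p-value and preserves the
  raw-p ordering; note re-applying it to an already adjusted vector is
  *not* a no-op in general (only constant vectors are fixed points).
* `dunnPosthoc()`: pairwise z-tests on mean midranks with tie-corrected
  variance and Bonferroni adjustment, following the convention of common
  analysis software; the Kruskal-Wallis omnibus is delegated to
  `stats::kruskal.test`.
* The parametric branch (ANOVA/Tukey, Welch/Dunnett) used elsewhere in
  such studies is deliberately left to standard implementations and is
  not part of this package's tested surface.

`compareGroups()` picks Mann-Whitney for two groups and Kruskal-Wallis +
Dunn for three or more, always on per-sample means. Age groups default to
young ≤ 35, middle 36–54, old ≥ 55 years (the boundary variant "old >
55" appears in some figure conventions; the boundaries are parameters of
`.ageGroup()` and the pipeline config).

## Problem sizes, runtimes and reproducibility

The shipped study sizes are those of the calibrated cohorts: 23 HR and 26
AR samples × 3 images (288×288 px, 3 ducts each) for tissue recovery, and
2000 cells per colony preset for differentiation recovery. These sizes
make three standard errors of each recovered quantity smaller than its
recovery tolerance while keeping a full cohort round trip in tens of
seconds on one CPU; calibration Monte-Carlo uses the truth-only fast path
(`render = FALSE`, 520 samples). Every generator takes an explicit
integer seed, restores the caller's RNG state, and is byte-identical on
reruns; `runPipeline()` hashes every output file into its run report so a
rerun from the echoed config can be verified against the manifest.

## Known limitations

* Synthetic ducts are geometric idealisations; recovery results bound
  pipeline bias, not robustness to real-section artefacts.
* The colony intensity model draws the two channels independently within
  a state; real double-positive cells may show correlated intensities.
* The unimodality screen in `fitGates()` is conservative only for
  well-separated modes (see above).
* Overlap ORs depend on the universe; cross-study comparison requires the
  same universe definition.
* Tissue quantification is area-based; no per-cell counting is attempted
  in tissue mode (by design, matching the mask-ratio definition of the
  statistics).
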