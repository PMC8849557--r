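Package: lineageFidelity
Title: Quantification of Epithelial Lineage Fidelity from Keratin
    Immunofluorescence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify loss of lineage fidelity in bilayered
    epithelia from multichannel keratin immunofluorescence. Implements
    mask-based KRT14/KRT19 coexpression ratios (Otsu thresholding, AND/OR
    mask algebra, per-sample aggregation, nonparametric group comparison),
    marker-based watershed single-cell segmentation with four-state
    differentiation gating and chi-square comparison of state
    distributions, gene-signature construction from differential
    expression tables with Fisher one-sided overlap odds ratios, and a
    calibrated synthetic-data generator (duct images, colony images,
    DE tables, gene-list pairs) with per-cell ground truth so the whole
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    fgsea,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, ImmunoOncology, Software, SingleCell
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'differentiation.R'
    'io.R'
    'keratin-quant.R'
    'lineageFidelity-package.R'
    'pipeline.R'
    'presets.R'
    'signatures.R'
    'stats-core.R'
    'synthetic-colony.R'
    'synthetic-de.R'
    'synthetic-tissue.R'
    'utils.R'
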