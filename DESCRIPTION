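Package: isletTraffic
Title: Quantitative Analysis of T-Cell Trafficking into Inflamed Pancreatic Islets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how T cells enter inflamed pancreatic islets
    across the islet vasculature, driven by a synthetic-data generator with
    known ground truth. Builds labeled 3D islet phantoms (vessel lumen,
    perivascular CD11c+ cells, T cells) at intravital two-photon imaging
    geometry, extracts voxel vascular surfaces and CD11c-vascular contact
    zones, tests spatial enrichment of arrested intravascular T cells against
    binomial and area-weighted permutation nulls, classifies per-track
    extravasation fates (remain arrested, release, complete extravasation)
    with censoring and summarises event-time medians by islet infiltration
    state, implements co-transfer homing statistics (per-islet normalisation,
    treated:control ratio tests, percent impairment, depletion inclusion
    filter), and ranks chemokine ligands against their receptors from
    median-of-ratios normalised expression counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    xml2,
    Matrix,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Spatial, SingleCell, ImmunoOncology
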