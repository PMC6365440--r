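# isletTraffic

Quantitative analysis of T-cell trafficking into inflamed pancreatic
islets, for immunologists working with intravital two-photon imaging,
co-transfer homing experiments and sorted-population RNA counts in the NOD
mouse model of type 1 diabetes.

Before T cells can destroy the insulin-producing beta cells they must cross
the islet vasculature: arrest on the endothelium, then extravasate into the
parenchyma. This package implements the analyses that characterize that
bottleneck:

* **Contact-zone geometry.** From a labeled 3D volume (vessel lumen,
  perivascular CD11c⁺ cells, T cells) it extracts a voxel vascular surface
  with anisotropy-aware area weights and flags the surface inside
  *CD11c-vascular contact zones* — within δ_z (1.5 µm) of a CD11c voxel.
  The area-weighted zone fraction is the random-placement expectation for
  where an arrested cell should sit.
* **Spatial enrichment.** Each T cell is assigned a compartment by the sign
  of its centroid's distance to the surface (negative = intravascular),
  zone membership, and nearest-CD11c surface-to-surface distance. Observed
  in-zone fractions are tested against the null with an exact binomial tail
  P(X ≥ k), X ~ Bin(n, zone fraction), or an area-weighted permutation null
  with the add-one estimator p = (1 + #{perm ≥ obs}) / (1 + B).
* **Extravasation kinetics.** Leading-edge signed-distance trajectories are
  classified into *remain arrested / release / complete extravasation*
  (arrest: speed < 2 µm/min sustained ≥ 2 min; completion: distance > 5 µm
  for 3 frames), with left/right censoring, and summarized as event-time
  medians stratified by islet infiltration state (mild 0.1–30%, advanced
  30–60% T-cell volume fraction).
* **Co-transfer statistics.** Per-mouse treated:control ratios tested
  against 1 (one-sample t), paired and pooled-variance two-sample t tests,
  percent impairment (1 − mean_treated/mean_control) × 100 on per-islet
  normalized counts, and the ≥ 90% CD11c-depletion inclusion filter.
* **Chemokine ligand–receptor pairing.** Median-of-ratios size factors
  (factor_j = median_g count_gj / geomean_g), expressed-chemokine calling
  in CD11c samples, and top-ligand ranking paired with receptor expression
  in T-cell samples via a curated murine pairing map (TSV resource).

No raw imaging or sequencing data are deposited for this system, so the
package ships a first-class **synthetic-data generator**: islet phantoms at
the imaging geometry (0.994 µm/pixel xy, 3 µm z), arrest/release/
extravasation track tables, co-transfer count tables and gene × sample
count matrices — each with ground truth re-measured on the emitted
artifact, so every analysis is validated by parameter recovery.

## Worked example

```r
library(isletTraffic)

res <- generateIsletPhantom(geometryPreset("fig2_geometry", seed = 1))
res$phantom
#> IsletPhantom 115 x 115 x 38 voxels, spacing (0.994, 0.994, 3) um
#>   lumen voxels: 27181 | CD11c cells: 26 | T cells: 117
res$zone_map
#> ContactZoneMap: 5900 surface voxels, deltaZ 1.50 um, zone fraction 0.183

loc <- localizeCells(res$phantom, res$surface, res$zone_map)
s <- summarizeContactEnrichment(loc, res$zone_map)
#> zone: 18.3% of vasculature | in-zone T cells: 84.2% | direct contact: 76.3%

et <- enrichmentTest(loc, res$zone_map, method = "binomial")
#> observed 0.842 vs expected 0.183, p = 1.84e-35
```

18.3% of this phantom's vascular surface lies in CD11c contact zones, so a
randomly placed intravascular cell would be in zone 18.3% of the time; the
observed 84.2% (and 76.3% in direct CD11c contact) is the strong enrichment
the imaging experiments report, and the binomial tail quantifies it.

```r
tc <- generateTraffickingCounts(countsPreset("ptx_effect", seed = 3))
rt <- ratioTest(tc, "CD4", "islets")
imp <- percentImpairment(tc, "CD4", "islets")
#> islet CD4 treated:control ratio 0.037 (t = -276.3, p = 1.5e-13); impairment 96.3%
```

A treated:control ratio far below the hypothetical value 1 and a ~96%
impairment of islet homing after chemokine-receptor blockade, recovered
from a simulated 7-mouse co-transfer.

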