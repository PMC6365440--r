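---
title: "Quantifying T-cell entry into inflamed pancreatic islets: models and design choices"
author: "isletTraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T-cell entry into inflamed islets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In autoimmune (type 1) diabetes, T cells destroy the insulin-producing beta
cells of the pancreatic islets, but before they can do so they must leave the
blood: arrest on the islet vascular endothelium, and extravasate into the
islet parenchyma. Intravital two-photon imaging of inflamed islets shows this
to be a slow, selective process in which arrested T cells sit in close
proximity to perivascular CD11c^+^ mononuclear phagocytes, and co-transfer
experiments show that chemokine-receptor signalling and the CD11c^+^
compartment are required for efficient entry.

`isletTraffic` packages the quantitative analyses behind that picture as
reusable, tested components:

1. **Geometry** — extract a voxel vascular surface from a labeled 3D volume,
   compute CD11c–vascular contact zones and signed leading-edge distances,
   and classify islet infiltration state.
2. **Enrichment** — localize T cells (intravascular vs extravascular, in or
   out of contact zones, in direct CD11c contact) and test enrichment
   against a random-placement null.
3. **Kinetics** — classify per-track fates (remain arrested / release /
   complete extravasation) with censoring, and summarize event-time medians.
4. **Trafficking statistics** — co-transfer homing ratios, one-sample and
   paired/two-sample t tests, percent impairment, per-islet normalization
   and the depletion inclusion filter.
5. **Expression pairing** — median-of-ratios normalization of islet CD11c /
   T-cell count matrices and chemokine ligand–receptor ranking.

No imaging or sequencing data are deposited for this system, so the sixth
component — a **synthetic-data generator** — is first-class: it emits every
input the pipeline consumes, with ground truth *re-measured on the emitted
artifact*, so every downstream module can be validated by parameter
recovery.

# The islet phantom

`generateIsletPhantom()` builds a labeled voxel volume at the imaging
geometry of the experimental system: 0.994 µm/pixel in *xy* and 3 µm z
steps. Voxel `i` (0-based) spans `[i, i+1] * spacing`; physical voxel
centers are `(i + 0.5) * spacing`. The scene is:

* a spherical islet (default radius 55 µm);
* a connected tubular lumen: a piecewise-cylindrical random walk of capsules
  (default 7 segments of radius 13 µm) kept inside the islet. The literature
  gives no vascular network model for islets; a capsule chain is the
  simplest geometry with a controllable, connected wall;
* perivascular CD11c blobs (spheres, radius 6 µm) rejection-sampled at wall
  distance below one blob radius and accepted one at a time until the
  *realized* area-weighted contact-zone fraction is within ±0.01 of the
  preset target (18.7% of the vascular surface for the advanced-islet
  preset). If the blob budget cannot reach the target the generator fails,
  naming the realized maximum;
* T-cell spheres (radius 4 µm). The cell count defaults to
  `infiltration_fraction * (R_islet / r_cell)^3`. A preset fraction is
  placed in the parenchyma; the rest are wall-adherent intravascular cells
  placed in or out of contact zones with probability `p_in_zone` (0.866),
  and — conditional on being in zone — in direct CD11c contact with
  probability `p_direct_contact` (0.750/0.866, so the marginal direct-contact
  fraction is 75.0%).

Placement is *verified, not assumed*: each candidate cell is measured with
the same rules the analysis modules use (centroid signed distance,
nearest-surface-voxel zone membership, voxel surface-to-surface contact
distance) and re-sampled until the intent is met, so recorded ground truth
equals a re-measurement of the emitted volume. Arrested cells are allowed to
pack: a later cell may be carved by earlier neighbours as long as most of
its body remains (the intent check runs on the carved shape). At the default
study scale the intent failure rate is zero; in deliberately overcrowded
small vessels the generator degrades gracefully and flags non-achieved
intents in the ground-truth record.

## Surface area weighting

The vascular surface is the set of lumen voxels with at least one of their
six faces exposed to non-lumen. Raw exposed-face ("Manhattan") area
over-estimates smooth surfaces — a voxelized cylinder wall by 4/π — so each
voxel's weight is the magnitude of its net signed exposed-face vector plus
the full area of cancelling opposite-face pairs. An isolated voxel keeps its
closed-box area `2(xy + xz + yz)`; a smooth wall is estimated without
staircase inflation (an axis-aligned cylinder's lateral area lands within a
few percent of `2πrL`). All zone fractions are ratios of these weights.

## Distance thresholds

* `deltaZ = 1.5` µm defines the contact zone: a surface voxel within 1.5 µm
  (about one xy voxel plus margin) of a CD11c voxel. The imaging analysis
  that inspired it called contacts visually in rendering software and never
  published a threshold; 1.5 µm operationalizes "in direct contact with the
  vessel wall" at sub-cellular precision and is configurable everywhere.
* `deltaC = 1.0` µm defines *direct cell contact*: the voxel
  surface-to-surface distance between a T cell and its nearest CD11c cell
  (0 when label masks overlap). It is deliberately stricter than `deltaZ`.
* Compartment is decided by the **sign of the centroid's** distance to the
  surface (negative = intravascular). Transmigrating cells straddle the
  wall, so whole-cell containment would be ambiguous; the centroid rule is
  deterministic and testable.

# Enrichment nulls

Under random placement, the probability that an intravascular cell sits in a
contact zone equals the area-weighted zone fraction — so the *expected*
in-zone fraction is the zone fraction identically. Two tests are provided:

* **binomial**: exact upper-tail `P(X >= k)`, `X ~ Binomial(n, zone fraction)`;
* **permutation**: `n` pseudo-cells placed uniformly over surface voxels
  with probability proportional to area weight, `B = 10^4` times, with the
  add-one estimator `p = (1 + #{perm >= obs}) / (1 + B)` so p-values are
  never zero. The null places cells *on the wall*, not in the lumen volume,
  because arrested cells are wall-adherent by definition.

The two p-values agree within Monte-Carlo error; the test suite asserts
this, plus the tail identity against direct pmf summation.

# Track kinetics

`generateTracks()` writes per-frame leading-edge positions along the local
outward wall normal of an arrest site. The observation window is 2 h; the
frame interval defaults to 20 s (the source experiments report 30-min
imaging segments with sub-minute time stamps but no frame rate; 20 s is a
typical two-photon volume rate and is configurable). Fates are drawn per
track — release (0.5), completed extravasation (0.3), remain arrested
(0.2) for the advanced-islet preset; the mild-islet preset sets
extravasation to zero, matching the observation that completion occurs only
in heavily infiltrated islets. The fate split is not published numerically;
the values above respect the qualitative ordering (release more frequent
than completion) and are preset fields, not constants.

Waiting times from arrest follow a log-normal parameterized by its median
(43 min for release, 63 min for completed extravasation) with `sigma_log =
0.5`; only medians are published, so the family and spread are package
choices, both configurable. A preset fraction of tracks (default 0.5) is
*left-censored*: already arrested at the session start, with an unknown
elapsed arrest time modeled as a uniform fraction of the drawn waiting time.

`classifyFate()` operationalizes the visual calls of the original analysis:

* **arrest**: instantaneous 3D speed below 2 µm/min sustained for at least
  2 min;
* **completed extravasation**: signed leading-edge distance above 5 µm
  (about one cell radius — the body has cleared the wall) for 3 consecutive
  frames; event time at the first frame of that run;
* **release**: the track terminates before the end of the window while the
  distance is still negative (the cell re-enters flow and leaves the field);
* otherwise **remain arrested**, right-censored. Tracks that never arrest
  are excluded with an explicit status rather than silently dropped.

Medians are computed over observed events only. Two consequences are worth
stating plainly: left-censored cells contribute *underestimated* event
times, and events longer than the window are never observed, so the
extravasation median recovered from a 2-h session sits a few minutes below
the generating median (about 59 min when generating at 63). This mirrors the
underestimate the experimental analyses themselves acknowledge; the test
suite asserts the direction of the bias rather than pretending it away.

# Co-transfer statistics

The co-transfer design makes each mouse its own control: two differentially
labeled populations in the same animal, counted per tissue by flow
cytometry. The generator draws Poisson counts (negative-binomial by config)
around `baseline * effect_multiplier[population, tissue]`. Baseline
recoveries per mouse (ILN 2000, PLN 2500, blood 1500, islets 400; 25 islets
harvested per mouse) are not published; these are typical flow-cytometry
recoveries for these tissues and only set the counting noise scale —
effects are multiplicative and scale-invariant (a tested invariant). Named
presets encode the study effects: chemokine-receptor blockade (islet
multipliers 0.044/0.087 for CD4/CD8, lymph-node impairment, blood
enrichment) and CD11c depletion (islet multipliers 0.08–0.25 by population;
lymph nodes unaffected).

Statistics follow the form in which the quantities are reported:

* per-mouse treated:control **ratios on the raw scale** tested against a
  hypothetical value of 1 (one-sample t, two-sided); a log-scale variant is
  a flag. Zero-control pairs are excluded with a warning, not imputed.
* **percent impairment** `(1 - mean_treated / mean_control) * 100` from
  group means of per-islet-normalized counts — the way a single headline
  percentage arises from grouped data; a per-mouse variant is available.
* paired and **pooled-variance** two-sample t tests (Welch by flag);
  degenerate zero-variance inputs report `t = 0, p = 1` when the mean sits
  at the null and are flagged otherwise.
* the **depletion filter** includes a mouse only at >= 90% islet CD11c
  depletion relative to the intact-arm mean, boundary inclusive.
* No multiple-testing correction is applied by default — tissues are
  reported per-tissue as in the source analyses; `p.adjust` can be applied
  by the caller.

# Expression pairing

Gene counts are normalized by **median-of-ratios** size factors: for sample
*j*, the median over genes (positive in all samples) of
`count[g, j] / geomean(count[g, ])`. A pseudo-reference fallback for sparse
matrices is behind a flag. The implementation is authored here and is
cross-checked in the tests against an independent implementation on a
fixture with an odd number of all-positive genes (where median-of-ratios
and exp-median-of-log-ratios coincide exactly).

A ligand is *expressed* when its mean normalized count in the CD11c
population reaches 10 — the published claim ("over 20 chemokines") states no
cutoff, so the threshold is an explicit parameter and the simulation preset
keeps the expressed set stable under five-fold threshold changes in either
direction. The ligand→receptor map ships as an editable TSV
(`extdata/chemokine_pairing.tsv`) curated from standard murine chemokine
nomenclature (Cxcl16→Cxcr6, Cxcl9/10/11→Cxcr3, Ccl19/21→Ccr7, ...,
many-to-many). Ranking is by mean normalized CD11c expression with
lexicographic tie-breaks; the preset's negative-binomial means place Cxcl9
first and Cxcl16 third among ligands and Cxcr6 first among T-cell
receptors, as observed.

# Numerical and degenerate-input choices

* Nearest-distance queries run through one BLAS GEMM plus `max.col`
  (augmented-coordinate trick), with a bounding-box prefilter that is exact:
  filtered answers are accepted only when below the prefilter radius.
* The infiltration classifier partitions [0, 1] exactly: uninfiltrated
  below 0.1%, mild [0.1%, 30%), advanced [30%, 60%]; the 30% boundary
  belongs to the upper class (the source binning is silent on boundaries),
  and fractions above 60% return advanced with an out-of-range flag.
* Empty lumen, zero intravascular cells, zero control counts, absent track
  labels, unreachable zone targets: all are explicit errors or warnings with
  named quantities, never silent NA propagation.
* All generators consume exactly one seed (`withr::with_seed`), making every
  artifact bit-reproducible; file round trips (OME-TIFF + companion XML,
  CSV, TSV, MatrixMarket) are bit-exact and tested.

# Problem sizes

The shipped analyses use 5 phantom islets per condition (matching the
n = 5 islets of the imaging study), 200-cell snapshots, 10^4 permutation
draws, 7 mice for the paired co-transfer and 10 per arm for depletion. The
reproduction script simulates 1000 tracks to pin down the event-time sample
medians; the per-track model is identical at any count. The test suite
works on scaled-down phantoms (32 µm islets) wherever the property under
test does not depend on absolute scale, and on study-scale phantoms where
it does (placement-fidelity recovery).

# What passing tests do and do not show

The phantom emulates labeled, already-segmented volumes: sphere/capsule
morphology, no point-spread function, no detection noise, no bleed-through,
no segmentation errors, no vascular flow or hemodynamics. Parameter
recovery on phantoms therefore validates the *measurement pipeline* —
surfaces, distances, zones, fates, statistics — not the upstream microscopy
or segmentation. Real OME-TIFF label volumes, track CSVs and count tables
enter through the same readers and flow through identical code paths, but
their segmentation quality is the caller's responsibility. Likewise the
expression module validates normalization and ranking logic on
negative-binomial counts, not read alignment or quantification.
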