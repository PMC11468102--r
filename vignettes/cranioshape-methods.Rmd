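---
title: "Quantifying anterior craniofacial asymmetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anterior craniofacial asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioshape)
```

## The problem

Unilateral lambdoid synostosis (ULS) — premature fusion of one lambdoid
suture — deforms the whole skull: the occiput flattens on the fused
(ipsilateral) side, the mastoid bulges, and the contralateral parietal and
frontal bones boss outward. The posterior changes are well known; the
anterior face is harder to characterise. `cranioshape` implements a
quantitative protocol for that anterior asymmetry: landmark craniometrics of
the anterior fossa, orbit, zygoma, maxilla and mandible; plane-partitioned
volumetry of watertight region meshes; tragi-centered radial "heat maps" of
group shape differences; and the triplicate, two-rater measurement and
group-comparison statistics. Because clinical CT data of this rarest
single-suture synostosis are not publicly available, the package also ships a
synthetic skull-phantom generator that serves as its test bed: every
published summary value can be injected into a phantom and recovered through
the same code paths a real mesh would take.

## Coordinate frame and reference planes

All geometry lives in a right-handed RAS frame: +x anatomical right,
+y anterior, +z superior, millimetres. Slicer FCSV fiducials (RAS) map
directly; LPS files are converted on read.

The craniometric definitions reference two planes that a clinician holds
implicit but code must construct:

* **Midsagittal plane.** Primary rule: the plane through nasion, sella and
  basion. Nasion and sella anchor several angle measures, so they must lie in
  the plane for those measures to be well posed; basion is carried in the
  landmark registry solely as the third midline support point and enters no
  measure. When any of the three is missing, a fallback fits the best
  symmetry plane of the bilateral landmark pairs: the normal is the principal
  eigenvector of the left-to-right difference vectors and the plane passes
  through the mean of the pair midpoints. The normal is always oriented
  toward the anatomical right.
* **Axial plane.** Through sella, normal = (midsagittal normal) x (anterior
  direction), where anterior is sella-to-nasion projected into the
  midsagittal plane. Derivable from required landmarks only.

"Midsagittal plane–sella–X" angles (zygomatic, maxillary, mandibular) are
measured in the axial-plane projection, from the anterior midsagittal
direction, in [0, 180] degrees. This is a documented choice, not a claim
about how the original measurements were taken: the source protocol does not
say whether its angles were 3D or projected, but the reported contralateral
mandibular angle (102.51 degrees) exceeds 90, which a line-to-plane angle
(capped at 90) cannot produce, so a projected convention with an anterior
zero is the only reading consistent with the published values. The anterior
fossa angle likewise uses the axial projection of the lesser-wing line;
0 degrees means the wing points straight anterior, larger values a more
posterior sweep.

Midline deviations (nasion-ANS for the nose, ANS-symphysis for the chin) are
line-to-plane angles against the midsagittal plane, signed positive toward
the contralateral side, matching how the clinical literature reports
"contralateral deviation". The sign therefore requires a known affected
side; for controls the unsigned magnitude is reported with a warning.

## Volumetry

Volumes use the signed-tetrahedron (divergence theorem) sum over a watertight
triangle mesh, with the absolute value taken so a globally inverted mesh
cannot yield a negative volume; non-watertight input is rejected with the
open-edge count rather than silently patched. `split_by_plane()` subdivides
crossing triangles exactly at the plane, caps both halves with an
ear-clipped triangulation of the intersection loop(s), and reuses identical
intersection vertices on both sides — the cap triangles of the two halves
cancel in the signed sum, so the part volumes add to the whole at the level
of floating-point rounding (the test suite asserts 1e-9 relative).

The anterior fossa is partitioned into left and right by the plane through
the anterior nasal spine and sella. Two points do not determine a plane, so
the implementation takes the normal as the midsagittal normal projected
orthogonal to the ANS-sella direction; with midline ANS and sella this *is*
the midsagittal plane, and with a deviated ANS it stays the closest
left/right split containing both points. The mandible is split at the
symphysis with a plane parallel to the midsagittal plane. Manual
suture-following segmentation of the orbit and zygoma is out of scope: the
volumetric contract takes watertight region submeshes as input, and the
phantom generator produces them.

## Radial maps and composite heat maps

A head surface is parameterised by directions from the inter-tragi midpoint:
for each direction on an equal-angle azimuth x elevation grid (default
2-degree spacing, 180 x 90 directions; the spacing is a parameter), the
radius is the distance to the first ray-surface intersection. A farthest-hit
mode exists for surfaces that are not star-shaped about the center; the head
from an interior tragi midpoint is near-star-shaped, so first-hit is the
default. Directions that miss are flagged, never zero-filled, and a center
outside the surface is an error (parity test with an oblique ray).

Composites are per-direction arithmetic means over subjects sharing one
grid, after rigid landmark alignment (Kabsch, no scaling — size
normalisation is available behind a flag but off by default, since the
protocol does not describe normalisation) and after mirroring left-affected
subjects so asymmetry adds instead of cancelling. A heat map is the signed
difference of two group composites: positive = projection of group A,
negative = retrusion, defined only where both groups have coverage.
`export_heatmap_mesh()` bilinearly interpolates the per-direction difference
onto a reference mesh's vertices and writes an annotated PLY; colormap
styling is left to the viewer.

## Measurement protocol and statistics

Every craniometric distance and angle is recorded in triplicate by each of
two raters. `collapse_replicates()` averages the three replicates within
rater, then the two rater means, and reports the pooled within-cell
replicate SD as a noise diagnostic; incomplete replicate sets are an error,
never imputed. Group comparisons are two-sample unpaired Student t-tests
with pooled variance (Welch behind a flag), significance at p < 0.05, no
multiple-testing correction — the protocol's choices, reproduced as stated.
`ttest_from_summary()` computes the same statistic from printed means/SDs/n,
and is tested to agree with the raw-data test to 1e-10 on moment-matched
samples. The comparison table reports, per bilateral measure, ipsilateral vs
contralateral, ipsilateral vs control and contralateral vs control, plus
summaries of the two midline deviations, grouped by facial third.

Two published-table subtleties are handled deliberately. First, the control
column does not state whether left and right sides were averaged or pooled
per subject; both are supported (`control_sides = "averaged"` is the
default). Second, exact printed p-values other than "<0.001" bounds are not
reproducible from the printed summary statistics alone (the data layout
behind them is indeterminable), so the package's checks assert only the
sub-0.001 bounds, which the summary moments do reproduce.

## The phantom generator

The generator's guiding design decision: **truth is injected at the landmark
level**. `inverse_place_landmarks()` is a constructive inverse of every
measure definition — lengths are realized by scaling along the defining
segment, projected angles by placing the target point on the target ray in
the axial frame (keeping its default in-plane distance and off-plane
offset), paired angle + length constraints (orbital height with vertical
angle, width with horizontal angle) by a closed-form cone/sphere
intersection, and deviations by rotating ANS and the symphysis off the
midsagittal plane. Re-measuring a built phantom returns the targets to
numerical precision (1e-6 or better), which makes parameter recovery sharp
rather than approximate.

Region solids are deformed unit spheres (latitude/longitude meshes) whose
*discrete* mesh volume is scaled onto the target: uniformly for single
solids, per half for the fossa and mandible. The fossa and mandible bases
are built with a vertex ring lying exactly in their split plane, so a
piecewise-linear scaling of each side along the plane normal changes each
half's volume exactly linearly and the plane-partitioned volumes hit their
targets to floating-point precision — comfortably inside the 0.5%
discretization allowance the recovery checks permit. The head surface is an
ellipsoid (default semi-axes 65 x 82 x 60 mm, an infant head around the
cohort's mean age of 1.8 years) with smooth Gaussian radial bumps for the
clinical deformation fields: ipsilateral occipital flattening (default
-8 mm), occipitomastoid bulge (+6 mm), contralateral parietal bossing
(+7 mm), and frontal bossing (+5 mm contralateral, +2 mm ipsilateral).
The protocol reports no millimetre amplitudes for these; the defaults were
chosen once as clinically plausible magnitudes for an infant skull and are
spec parameters, not fitted values.

`simulate_cohort()` reproduces the study conditions as its defaults: 30
affected and 30 control subjects, 17 right- and 13 left-affected, per-measure
group means and SDs transcribed from the published summary table
(`uls_table1()`), normal sampling truncated at plus/minus 4 SD, replicate
noise SD 0.4 (mm or degrees) and rater bias SD 0.2 — the replicate/rater
magnitudes are unreported in the protocol and were fixed once at values small
against every measure SD. Left-affected subjects are built in the canonical
right-affected frame and mirrored, so laterality provably does not leak into
ipsilateral/contralateral tables (a property test swaps the mix against an
all-right cohort at the same seed).

One honest limitation of independent per-measure sampling: the realized
measures share landmarks, so they obey joint geometric constraints the
marginal normals do not know about — most prominently orbital height >=
orbital depth x sin(vertical orbital angle), a triangle inequality at the
optic foramen. Draws violating such a constraint are rejected and the
subject resampled (about 15% of subjects at the study moments). This
conditioning shifts the realized ipsilateral orbital-height mean upward by
roughly +0.2 mm — well inside the two-standard-error band (about 0.70 mm at
n = 30) used by the recovery checks, and a faithful reflection of the fact
that real anatomies satisfy these constraints through correlations the
published marginals cannot encode.

## What the phantoms do and do not show

The phantom cohort carries the full landmark registry, watertight region
solids with known volumes, the published group moments, the laterality mix,
and the two-rater triplicate noise structure. It does not emulate bone
texture, suture geometry, CT segmentation artifacts, landmark placement
error correlated with surface quality, or growth: passing tests demonstrate
that the *measurement and statistics machinery* is correct and
seed-reproducible, not that the package can segment or landmark a real CT.
Automatic landmark detection and nonrigid registration are explicit
non-goals.

## Numerical choices

* On-plane snapping tolerance in `split_by_plane()`: 1e-9 x bounding-box
  diagonal; plane-parallel degenerate triangles are assigned to the positive
  side.
* Cap triangulation: ear clipping that follows the boundary-loop winding,
  with a widest-convex-corner fallback for numerically degenerate corners;
  multiple intersection loops are supported.
* `acos`/`asin` arguments are clamped to [-1, 1]; collinear three-point
  angles are exact only to about 1e-6 degrees because acos amplifies rounding
  near 1.
* Quadratic solves in the cone/sphere constructions take the positive root
  nearest the default configuration; a negative discriminant raises a
  constructibility error naming the measure and its feasible range.
* Zero-pooled-variance t-tests: p = 1 on equal means, p = 0 otherwise, as an
  explicit edge contract.
* Mesh resolutions in tests and the pipeline default (latitude 24-32,
  longitude 48-64, about 2-4 thousand faces per solid) keep sphere volume
  within 0.5% of analytic and the whole suite within tens of seconds; the
  resolution is a `phantom_spec()` parameter.

## Reproducibility

Every stochastic step flows from one integer seed: cohort sampling,
replicate noise, rater biases. `run_pipeline()` writes CSVs, an annotated
heat-map PLY and a provenance log (seed, sizes, grid, config hash), and
rerunning with the same seed reproduces every output byte for byte — this is
asserted in the test suite.
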