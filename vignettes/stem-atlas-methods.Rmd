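---
title: "Statistical intensity atlases of vascular bundles in stem cross-sections"
author: "stemAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical intensity atlases of vascular bundles in stem cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemAtlas)
```

## The problem

Vascular bundles in a grass stem (maize is the motivating system) are
discrete strands of conducting tissue, visible in a transverse section as
~300 µm clusters of small thick-walled cells. Their spatial arrangement —
denser towards the periphery, sparser in the centre — shapes the mechanical
and degradation properties of the stem. A single section shows one noisy
realisation of this arrangement; to say anything statistical one must
combine many sections from many plants, which differ in size, in shape and
in orientation. `stemAtlas` implements the full chain that makes such
replicated sections comparable:

1. stem contours are extracted from scan images of stem slabs, aligned by
   bilateral symmetry and resampled to a fixed vertex count;
2. contour variability is decomposed by PCA and modelled per coordinate by
   a linear model whose intercepts define a *reference contour* — the atlas
   space;
3. bundles are detected in macroscopy section images as point objects;
4. each point pattern is projected onto the reference contour by a rigid
   rotation followed by a radial (polar) transform;
5. per-slice kernel intensity maps, in points/mm², are averaged pixel-wise,
   globally and per experimental factor level.

Each point pattern is treated as a realisation of a spatial point process;
the estimated quantity is its intensity λ(x), the expected number of
bundles per unit area at atlas position x.

## Contour descriptors and symmetry alignment

A slab contour is a closed polygon obtained by tracing the boundary pixels
of a binary mask (Moore neighbour tracing; the traced chain is a one-pixel
wide, 8-connected closed loop, so no separate thinning pass is needed).
Coordinates follow the mathematical convention — x right, y up, angles in
radians counter-clockwise from +x — with image rows converted on load.
Polygons are centred on their area centroid and oriented counter-clockwise.

Stem sections are approximately bilaterally symmetric. The symmetry axis is
found by mirroring the polygon about the y-axis and rotating the mirrored
copy to minimise the *asymmetry*: the sum over vertices of the minimal
distance to the boundary of the original polygon (vertex-to-edge, not
vertex-to-vertex). Half of the minimising rotation aligns the axis with the
vertical. The objective can be multimodal, so the optimiser is a coarse
1° scan over [0, 2π) followed by golden-section refinement in the
bracketing 2° interval. Two conventions close the remaining ambiguities:

* up/down (the axis is defined modulo π): the rotation is chosen so that
  the vertex farthest from the centroid has positive y;
* the vertex list is rolled so that vertex 1 is the top vertex (maximal y,
  ties broken by minimal x).

Aligned contours are resampled to `nV = 200` vertices at uniform arc
length, starting from the top vertex. Uniform arc length is used rather
than raw index subsampling: pixel chains are nearly uniformly spaced, so
the two coincide up to pixel noise, but arc-length placement is robust to
uneven chains. Each contour then contributes one row of 2 × 200 = 400
coordinates to the contour table, with vertices assumed in correspondence
across rows.

## Statistical contour model

With rows indexed by slab face and columns by coordinate, two analyses are
run.

**PCA.** The coordinate table is column-centred (not scaled — every column
is a coordinate in mm) and eigendecomposed. Inertia fractions report the
share of total variance per component. On synthetic stems the first
component captures size and the second elongation, mirroring the two modes
one expects from real stems.

**ANOVA of scores.** For each of the first five component scores the model
contains fixed genotype, cutting-position and genotype × cut effects and a
stem effect nested in genotype. The stem is biologically a random draw;
accordingly the genotype F statistic uses the stem-within-genotype mean
square as its denominator, while cut, interaction and stem are tested
against the residual. Under null simulation the type-I error of these
tests is calibrated at the nominal level (checked at 0.05 ± 0.02 over 500
replicates in the test suite).

**Per-coordinate linear model.** The simplified model drops the
interaction and fits, for every coordinate j,

  XY(i, j) = μ(j) + α_G(j) + β_C(j) + s_S(G)(j) + ε(i, j)

by least squares under sum-to-zero constraints (α sums to zero over
genotypes, β over cuts, s over stems within each genotype). The
sum-to-zero coding is essential: it makes the intercept vector μ the
*reference average contour*. The stem effect is estimated as a fixed
nested effect because the downstream normalisation needs per-stem contour
estimates, not just a variance component; the random-stem interpretation
survives in the ANOVA denominator choice described above. Predicted
contours are sums of μ with requested effect vectors; a *slab* effect (the
quantity needed for a macroscopy image, which comes from a slab rather
than a cut) is the mean of the effects of the two cutting positions
bounding the slab, and an end slab keeps its single available cut.
Stacking per-cut predictions gives a 3D stem model per genotype.

## Section segmentation and bundle detection

Macroscopy images show bright parenchyma cells separated by darker walls,
with bundles as compact darker clusters.

**Slice contour.** Cells are detected by a watershed on the Gaussian
pre-smoothed image (σ = 2 px); a basin is kept as a cell when it peaks
above the global Otsu threshold. The watershed runs on a 2× decimated
image for speed, the mask is re-expanded before further processing, so the
precision loss is bounded by the decimation factor (2 px ≈ 10 µm at the
fixture resolution, far below the later tolerances). Because the empty
background has no watershed maximum of its own, boundary-cell basins bleed
outwards; a per-pixel brightness floor at half the Otsu threshold trims
this spillover. The union of cell regions is hole-filled, closed with a
radius-30 px disk, traced, converted to mm, simplified by Douglas–Peucker
at 100 µm and centred. The marker policy and the brightness floor are
implementation choices of this package; the watershed/hole-fill/closing/
simplification chain and its parameters (radius 30, tolerance 100 µm) are
the method's.

**Bundles.** The image is enhanced by an alternate sequential filter:
openings and closings with discrete disks of radii 1..10 px, which erases
the cell-wall texture while bundles persist. Bundles are then extended
minima — regional minima of depth ≥ h after h-minima suppression,
computed by greyscale morphological reconstruction (8-connectivity, a
Vincent-style hybrid algorithm in compiled code) — at two depths, h = 30
for large and h = 20 for small bundles. A small-threshold detection whose
region overlaps a large-threshold region is merged into it, keeping the
large-threshold centroid. Touching bundles are separated by a watershed on
the distance map. Label centroids are converted to mm and translated by
the slice-contour centroid. Two guards handle degenerate inputs: a
completely flattened image (all minima shallower than h) yields no
detection rather than an all-image plateau, and detections larger than
0.3 mm² (the background is itself a deep minimum) are discarded. Bundles
brighter than their surroundings are covered by an `invert` flag.

## Spatial normalisation

A slice pattern reaches the atlas in two steps. First a rigid rotation:
the slice contour is rotated to minimise its asymmetry against the model
contour predicted for that slice (same coarse-scan + golden-section
optimiser). Then the radial transform: each point keeps its angle θ and
its radius is scaled by ρ_ref(θ) / ρ_slice(θ), the ratio of the distances
at which the ray at θ crosses the reference and the slice model contours.
The same map is applied to the observed window polygon. Ray distances are
computed by exact ray–segment intersection rather than an angular lookup
table, which removes interpolation error from the transform; contours are
assumed star-shaped about their centroid, and if a ray crosses the
boundary more than once the nearest crossing is used with a warning.

Points can sit marginally outside the *model* contour (the model is a
smoothed estimate; bark removal biases the observed rim). Up to 1 % of
points are tolerated and clamped radially onto the model boundary with a
warning; more than that is an error. A second, purely numerical clamp
handles points pushed outside the mapped window by chord discretisation
(the mapped window is a polygon; its chords dip below the mapped curve by
up to a few µm).

## Kernel intensity estimation

Intensity is estimated on a fixed grid — 128 × 128 pixels over the
reference contour's bounding box expanded by 5 % — shared by every map of
a study so that maps can be averaged pixel-wise. The estimator is an
isotropic Gaussian kernel sum with edge correction:

* `uniform` (default): λ̂(u) = Σ_i k_σ(u − x_i) / e(u), with
  e(u) = ∫_W k_σ(u − v) dv the kernel mass retained inside the window
  around the evaluation point;
* `per_point`: λ̂(u) = Σ_i k_σ(u − x_i) / e(x_i), dividing by the mass
  retained around each data point, which makes ∫_W λ̂ equal the point
  count exactly (up to grid discretisation; the test suite checks 0.5 %).

The default bandwidth is a rule of thumb depending only on the bounding
frame: one eighth of the shorter side of the window's bounding box. It is
deliberately simple and exposed as a parameter; simulations in this
package that target fine radial structure use smaller values (0.8–1.2 mm
on a ~20 mm stem), because the rule-of-thumb value smooths a quadratic
radial gradient noticeably (the smoothing bias is ≈ σ²∇²λ/2).

Averages are pixel-wise means over the maps whose mask covers the pixel;
the output mask requires coverage by at least half the maps (configurable).
Factor-level averages are the same restricted to one level, and
count-weighted level averages recompose the global mean exactly.

## The synthetic study generator

No raw images ship with the package, so every stage is validated against a
generator whose defaults emulate the study design: two genotypes (mutant
10 % larger than wild type), seven stems per genotype, seven cutting
positions ("ab".."gh") with elongation tapering from 1.2 to 1.0 down the
internode, two faces per cut (~196 contours of 10 mm nominal radius), a
smooth per-stem contour perturbation of 0.15 mm and 0.05 mm coordinate
noise.

The contour family is an ellipse with a height-dependent width modulation
(an egg) plus low-order cosine harmonics that are even functions of the
angular distance from the top, so mirror symmetry about the y-axis is
exact by construction. The width modulation is negative by default
(sections fatter at the bottom), which makes the far tip the top vertex
and keeps the generator consistent with the aligner's up/down tie-break.
Dataset rows are built *additively* on the coordinate scale —
μ + α + β + s + noise, with α and β centred differences within the family
— so the linear contour model recovers every effect vector exactly at
zero noise; an optional rigid jitter (random rotation and translation per
contour) gives the alignment stage work to undo.

Bundle patterns come from an inhomogeneous Poisson sampler (thinning) and
a Matérn-II hard-core sampler (dependent thinning by uniform marks; no two
retained points closer than the core distance), reflecting the visibly
regular spacing of real bundles. The default truth intensity increases
quadratically towards the periphery with a low-intensity outer collar.

Rendered section images place Voronoi parenchyma (hard-core cell seeds,
50–150 µm cells, walls along the Voronoi boundaries) inside the contour,
draw bundles as ~300 µm darker disks with a darker rim, add Gaussian
read-out noise, and leave a dark background. Fixture stems are 2.5 mm in
radius at 5 µm/px — a quarter of the linear scale of a real internode at
similar relative cell and bundle sizes — so a rendered image stays near
1300 × 1100 px: large enough to preserve the cell/bundle scale separation
the morphological chain relies on, small enough that the validation suite
remains quick to iterate on. The renderer emulates geometry and contrast,
not optics: no
dark-field shading, no sub-structure inside bundles, no bark. Passing
imaging tests therefore demonstrate the morphological chain on clean
geometry, not robustness to staining or illumination artefacts.

Every generator is deterministic given its seed, and ground truth is
returned next to the data.

## Numerical choices and degenerate inputs

* Polygons with zero signed area raise an error (orientation and centroid
  are undefined).
* `resamplePolygon` preserves the loop within the longest input edge
  (Hausdorff), and `simplifyDP` guarantees — and the tests verify by brute
  force — that every input vertex lies within the tolerance of the
  simplified loop; the closed loop is split at vertex 1 and the vertex
  farthest from it before the recursive subdivision.
* Ray casting uses a 10⁻⁹ slack in the edge parameter so rays through a
  vertex hit one adjacent edge instead of falling between two.
* The rotation objective is evaluated in compiled code; the golden-section
  tolerance is 10⁻⁷ rad, far below the 0.5° acceptance band.
* An empty point pattern yields an all-zero intensity map, not an error;
  a slice without detections is reported with a warning by the pipeline.
* The uniform edge correction clips e(u) below 10⁻⁶ to avoid division
  blow-ups in mask corners.

## Worked example

```{r example, eval = FALSE}
library(stemAtlas)

# simulate the contour study and fit the models
ds  <- synthContourDataset(stemDesign(), seed = 1)
tab <- buildContourTable(ds$polygons, ds$factors)
pca <- fitContourPCA(tab)
head(anovaPcScores(pca, contourFactors(tab)))
model <- fitContourModel(tab)
ref   <- referenceContour(model)

# normalise a simulated slice pattern onto the reference and map it
slice <- centrePolygon(predictContour(model, genotype = "M", slab = "A",
                                      stem = "s1"))$polygon
pat   <- sampleInhomPoisson(function(x, y) rep(2, length(x)), slice, seed = 2)
ra    <- rigidAlign(slice, pat, slice)
norm  <- polarNormalise(ra$pattern, slice, ref)
map   <- kdeIntensity(norm, intensityGridSpec(ref), correction = "per_point")
integrateIntensity(map)   # equals npoints(pat)
```

## Known limitations

* The polar transform assumes star-shaped contours; strongly lobed
  sections would need thin-plate or spline warps, which are out of scope.
* The bark region is absent from macroscopy sections, so intensity near
  the atlas rim is biased low; the uniform edge correction does not remove
  this (it corrects kernel mass, not missing observation area).
* The rule-of-thumb bandwidth is a stand-in exposed as a configuration
  value; no data-driven bandwidth selection is provided.
* Mosaic stitching of macroscopy tiles is not implemented; inputs are
  single images.
* Reported inertias and p-values depend on the data at hand; the package
  validates calibration and recovery on synthetic studies, not any
  particular empirical table.
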