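---
title: "Quantifying cardiac ultrastructure across scales: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac ultrastructure across scales: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

## Scope

`myoquant` implements the image-quantification side of a correlative
multiscale cardiac imaging workflow: serial block-face scanning electron
microscopy (SBF-SEM) stacks of ventricular wall tissue at nanometre
resolution, paired with micro-CT label volumes of the whole heart at
micrometre resolution. From aligned, denoised, segmented volumes it
computes:

* organelle area/volume fractions — the extracellular fraction
  $S_E/S_T$ and the per-cell organelle fractions $S_i/(S_T - S_E)$ for
  $i \in \{N, Mit, Myo\}$ (nuclei, mitochondria, myofibrils);
* per-myofibril orientation angles — the transmural angle $\theta$ (x–y
  plane, measured from the circumferential direction) and the elliptical
  angle $\Phi$ (x–z plane, from the same direction), with 18-bin histograms
  over 0–180° and summary statistics;
* ventricular lumen volumes and the RV/LV volume ratio from micro-CT-scale
  label volumes;
* landmark-based similarity transforms linking the micro-CT, semithin
  section and EM sub-ROI coordinate frames.

Deep-learning organelle segmentation is deliberately out of scope: external
per-voxel label volumes are ingested through `ingest_label_volume()` and
scored with `evaluate_segmentation()`; the in-package segmenter covers only
the extracellular space, which is separable by intensity alone.

## Coordinate conventions

A stack is stored as an array of dimension `(ny, nx, nz)`; voxel
`(i, j, k)` (0-based) sits at physical $(x, y, z) = (j s_x, i s_y, k s_z)$.
The default spacing is 10 nm in-plane and 40 nm between sections. Axis
semantics are fixed per volume: x is in-plane approximately parallel to the
ventricular wall (circumferential), y is the in-plane radial direction, z
is the stack (longitudinal) direction. All orientation estimation is done
in *physical* coordinates, so the 4:1 axial anisotropy never biases an
axis estimate through the index grid.

Angles are axial quantities: an axis and its negation are the same
myofibril, so every angle is folded modulo 180° into $[0°, 180°)$, and
axes are sign-normalized to $x \ge 0$ (ties broken by $y \ge 0$, then
$z \ge 0$) so the folded angle of an axis is unique.

## The synthetic phantom generator

No raw study volumes ship with the package; a seeded generator
(`generate_em_volume()`) produces EM-like phantoms with exact ground truth,
and `generate_heart_phantom()` produces two-chamber heart label phantoms.
The phantom definitions *are* the study conditions the pipeline is
validated against; they are not tuned per test.

The EM phantom contains, in placement order (largest first): ellipsoidal
nuclei; straight cylindrical myofibrils whose transmural and elliptical
angles are drawn from folded normal distributions
$\theta \sim \mathcal{N}(\mu_\theta, \sigma_\theta) \bmod 180°$,
$\Phi \sim \mathcal{N}(\mu_\Phi, \sigma_\Phi) \bmod 180°$ (an axis is
reconstructed as $(1, \tan\theta, \tan\Phi)/\|\cdot\|$, which inverts both
angle definitions exactly); and blob-like mitochondria (ellipsoids with
±30% semiaxis jitter). Placement uses bounded rejection sampling (100
retries per object); later objects never overwrite earlier ones, so every
voxel carries exactly one class, and a clearance of one maximal voxel
spacing (40 nm at default geometry) is enforced around each fibril so that
distinct fibrils never touch under 26-connectivity — without it,
connected-component splitting would merge adjacent fibrils and the
per-object ground truth would be ill-defined. Exhausted retries raise an
"infeasible packing" error naming the object class rather than silently
degrading the phantom.

The extracellular phase is carved from the remaining cytoplasm by
thresholding a smooth random field (a coarse Gaussian grid with cells of
roughly 80 nm laterally and 320 nm axially, upsampled trilinearly) at the
quantile that makes the realized extracellular fraction match
`ec_fraction_target` voxel-exactly. Trilinear (rather than blockwise)
upsampling matters for a subtle reason: it keeps adjacent sections
correlated, which the stack-alignment step relies on, just as real
extracellular structures extend smoothly across many 40 nm sections.

Intensity is rendered as per-class constant means (defaults: extracellular
200, cytoplasm 140, mitochondrion 110, myofibril 80, nucleus 50 grey
levels — bright resin, darker stained organelles) plus i.i.d. Gaussian
noise, an optional per-slice brightness offset (to exercise intensity
matching) and optional per-slice integer translation jitter (to exercise
alignment). Jitter is applied *circularly* to the intensity stack only:
circular shifts are exactly invertible, so the recorded jitter table is a
sharp ground truth for the aligner, and the label volume remains in the
specimen frame. Identical parameters and seed give bit-identical output,
and the caller's RNG state is restored afterwards.

Free parameters that the study itself does not constrain — myofibril
calibre and length at this developmental stage — default to 250 nm radius
and 2 µm length, plausible for maturing embryonic myocardium; they are
ordinary parameters, not measured values. The heart phantom uses
ellipsoidal lumens wrapped in a constant-thickness tissue shell: a
deliberate simplification (a real right ventricle is crescent-shaped) so
that analytic lumen volumes $\tfrac{4}{3}\pi abc$ exist to validate the
voxel-counting morphometry; `heart_phantom_for_ratio()` scales the RV
semiaxes isotropically to hit any analytic RV/LV ratio exactly.

## Preprocessing

**Alignment.** SBF-SEM sections drift in-plane; each slice is registered
to its predecessor by normalized cross-correlation (FFT-based, with
parabolic interpolation of the correlation peak for subvoxel estimates)
and the chained corrections are applied as rounded integer translations —
lossless for both intensity and label volumes, and within half a voxel of
the subvoxel estimate recorded in the shift table. Translation-only (no
rotation/scale) is assumed: block-face imaging moves the stage, not the
sample. An all-constant slice has no defined correlation and receives
shift (0, 0) with an `NA` score. Cumulative-drift detrending is *off*:
detrending would straighten genuinely oblique structures such as fibrils
crossing the stack at an angle.

**Denoising.** The classic non-local means filter, applied independently
per 2D slice (never across slices, which would smear the anisotropic z
axis). `strength` is the usual $h$ parameter in grey levels; 0 is the
identity by construction.

**Intensity matching.** A global affine grey map $aI + b$ matching mean
and SD to a reference volume — invertible and loggable, unlike histogram
equalization, and sufficient for the brightness offsets this pipeline
needs to correct. Label volumes are rejected: class codes are not
intensities.

## Segmentation and evaluation

The extracellular space is thresholded (`fixed`, `bimodal-valley`, or
`quantile` methods); the valley detector smooths the intensity density and
takes the minimum between the two dominant modes, refusing unimodal
histograms with advice to supply a fixed threshold. Cleanup applies, in
fixed order, morphological closing (Euclidean ball in index space), hole
filling (6-connected background components not reaching the volume
border), and small-object removal (26-connected), which makes the
operation idempotent in practice.

`evaluate_segmentation()` reports per-class accuracy as truth-class
recall (correct voxels of a class divided by the class's truth count, in
percent) *and* overall pixel accuracy plus the full confusion matrix. The
reference this mirrors reported single per-class percentages without
defining the metric; recall is implemented and labelled as such rather
than asserted to be the original computation. Classes absent from the
truth are reported as undefined, not 0.

## Quantification

**Slice sampling.** Fractions are quantified on evenly spaced slices:
indices $\{0, s, 2s, \dots\}$ plus the final slice when not already
included. This "multiples of the stride plus forced final slice" rule is
chosen because it reproduces both published sampling counts (17 slices
from an 800-slice stack, 21 from 1000 at stride 50), which plain multiples
(16, 20) would not.

**Fractions.** Exact integer voxel tallies; `outside` voxels are excluded
from $S_T$. When a region is pure extracellular space ($S_T = S_E$) the
organelle fractions are undefined and reported as `NA` — never as zero.
"Area" here means voxel counts on slices, matching per-image
quantification, not mesh surface area. Aggregation reports mean and
sample SD ($n-1$) per quantity; per-slice aggregation is the default, with
crops available and recorded in the report for provenance. Undefined
values are excluded with their count logged.

**Ventricle ratio.** Lumen volumes are voxel counts times the physical
voxel volume; missing lumen classes fail by name.

## Orientation estimation: two routes

The primary estimator computes each object's axis as the leading
eigenvector of the second-moment matrix of its voxels' physical
coordinates, then projects to the x–y and x–z planes for $\theta$ and
$\Phi$. It uses every voxel of the object and is exact for symmetric voxel
sets. Objects whose top two eigenvalues agree to within $10^{-9}$
(relative) have no preferred axis and are flagged indeterminate; axes
parallel to z (for $\theta$) or y (for $\Phi$) have an undefined projection
angle and are excluded rather than forced.

The second route mirrors the literal 2D procedure: `resample_to_xz()`
upsamples z to the lateral spacing by nearest neighbour (label sets are
preserved exactly; total physical extent is preserved to within one voxel
per axis) and restacks the volume into isotropic x–z slices, and
`angles_via_resample()` estimates each object's in-plane angle from the 2D
principal axis of its x–z-projected voxels. The two routes agree within a
few degrees for rod-like objects; they diverge, by geometry rather than by
bug, for fibrils running nearly along y, whose x–z projection is short.
Both are exported so the cross-check stays available.

**Linear vs circular-axial statistics.** The default summary is the
arithmetic mean and sample SD of folded angles, which matches how
per-sample angle summaries are conventionally reported on 0–180° data.
Near the 0°/180° wrap, linear statistics mislead: the sample {5°, 175°}
has linear mean 90° but describes two nearly-identical axes. The
`circular-axial` mode doubles the angles, computes the circular mean
direction and circular SD, and halves back — the unbiased summary for
folded-normal axial data at any location, and the one a TOF-like
distribution centred near 0° requires. `angle_summary()` flags results
whose linear mean sits near the wrap.

A practical note on anisotropic discretization: for cylinders much
thinner than the section spacing that also lie nearly in-plane (spanning
1–3 sections), the second-moment axis of the *rasterized* voxel set can
deviate from the continuous axis by a few degrees. At myofibril calibre
(radius ≳ 100 nm, several sections even in-plane) the estimator stays
well inside 2° of the generating axis in the package's own checks.

## Correlative registration

Frames are linked by least-squares similarity transforms
$q = sRp + t$ fitted in closed form (SVD of the cross-covariance;
reflections excluded), because physical sections rotate, translate and
shrink approximately isotropically; a full affine fit is available behind
`allow_affine = TRUE` for distorted sections, and its use is recorded in
the returned object. Landmark files carry explicit frame identifiers and
units — no unit inference. Degenerate configurations (coincident points,
collinear 3D landmarks) fail naming the degeneracy. Maps compose
associatively and invert exactly; `locate_subroi()` walks a sub-ROI
rectangle through a chain of frames to whole-heart coordinates.

## Numerical choices

* Cylinder rasterization includes voxel centres strictly inside the
  radius and in the half-open axial interval $[-L/2, L/2)$, so an
  axis-aligned cylinder of length $n \cdot s$ spans exactly $n$ voxels and
  a radius equal to the lateral spacing yields a one-voxel-thick row.
* Angle folding guards the floating-point edge where `%%` returns exactly
  180 for tiny negative inputs; 180° folds to 0° and lands in histogram
  bin 1.
* The histogram is fixed at 18 bins of 10° regardless of sample size.
* Connected components default to 26-connectivity (6 available), because
  oblique fibrils fragment under 6-connectivity across 40 nm sections;
  the minimum object size defaults to 100 voxels to suppress speckle
  objects whose axis would be noise.
* Tie-breaks in axis sign normalization and component ordering are
  deterministic, so identical inputs give identical tables.

## Problem sizes used in the checks

The package's own test suite and the reproduction script run at desk
scale, chosen as the smallest sizes at which the statistical checks are
meaningful: orientation-recovery phantoms of 200–400 fibrils on grids of
roughly $320$–$440 \times 320$–$440 \times 80$ voxels (3–4 µm of tissue at
10/40 nm spacing), twenty $96 \times 96 \times 32$ fraction-recovery
regions, heart phantoms of a few million voxels at 20 µm spacing, and 50–100
rasterized test cylinders. Full-scale stacks (800–1000 sections of
4000 × 6000 pixels) stream through the same code paths; nothing in the
implementation assumes the reduced sizes.

## What passing phantom checks does and does not show

The generator emulates the *statistical* structure the analysis assumes:
distinct grey levels per class, Gaussian noise, per-slice drift and
brightness offsets, unoriented fibril axes with folded-normal dispersion,
smooth extracellular blobs, disjoint organelles. It does not emulate
myofibril branching or curvature, sarcomere banding, membrane substructure,
charging or stain-penetration gradients, partial-volume mixing at class
boundaries, or anisotropic point-spread blur. Consequently the phantom
checks validate the estimators and bookkeeping — angle conventions,
fraction formulas, sampling rules, registration algebra — not the
segmentability of real tissue; on real stacks, segmentation quality is the
externally supplied ingredient, and the evaluator quantifies it against
annotated ground truth.

## Known limitations

* Alignment is translation-only; rotational drift, should it occur, would
  appear as a slowly varying residual and is not corrected.
* The extracellular segmenter is intensity-only by design; it will not
  separate organelles, and the valley detector needs a genuinely bimodal
  histogram.
* Connected-component splitting treats touching fibrils as one object;
  branching or merged myofibrils are not resolved into anatomical units.
* Ellipsoidal heart-phantom lumens validate volume bookkeeping, not
  chamber-shape realism.
* The NRRD reader covers raw-encoded 3D volumes only (the variant the
  pipeline writes), not gzip encodings or detached headers.
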