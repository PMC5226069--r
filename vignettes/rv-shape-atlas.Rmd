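---
title: "Shape atlases and strain for the systemic right ventricle: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape atlases and strain for the systemic right ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvatlas)
```

## The scientific problem

In hypoplastic left heart syndrome the right ventricle (RV) is surgically
recruited as the systemic pumping chamber. The two stage-I palliation
strategies — a modified Blalock–Taussig (MBT) shunt versus a
right-ventricle-to-pulmonary-artery (RVPA) conduit placed through a
ventriculotomy — load and scar the ventricle differently, and the resulting
remodelling is three-dimensional and subtle. Two complementary
quantifications are standard:

1. a **statistical shape atlas**: each segmented RV is personalised into a
   corresponded mesh, flattened to a shape vector, and the population
   covariance is decomposed by PCA into a few *anatomical modes* whose
   per-subject scores can be compared between groups; and
2. **feature-tracking strain**: endocardial boundaries are propagated
   through the cine and Lagrangian strain / strain rate are extracted in
   longitudinal, circumferential and radial directions.

Clinical CMR of this population is not publicly deposited, so the package
treats the *synthetic cohort generator* as a first-class module: it is the
stated world in which every downstream computation has an analytic recovery
target.

## The generative anatomy

The RV is idealised as a half-ellipsoid whose cross-sections are crescents
(limaçons, radius `r(θ) = R·f(t)·(1 − κ·cosθ)` with `κ = 0.3`, flat side
facing the left-ventricular remnant at +x). The epicardial surface is the
same section offset outward by a uniform wall (4 mm at template scale) and
extended apically by the wall thickness. Each surface is sampled on a fixed
24 × 24 ring grid; 1152 corresponded vertices give the 3456-entry shape
vector (the per-vertex x, y, z decomposition is this package's convention —
equally sized alternatives exist, and nothing downstream depends on the
choice beyond the fixed length).

Deformations apply in a fixed, documented order: wall-thickness adjustment,
global dilation, sphericity, basal widening, apex tilt (a volume-preserving
shear), and finally vertex noise.

Two modelling choices deserve justification:

- **Sphericity is volume-preserving** (long axis × s, in-plane × s^-1/2).
  A plain long-axis stretch is almost collinear with dilation (stretching a
  long chamber mostly makes it bigger), which would make "size" and "shape"
  unidentifiable as separate anatomical modes. With the volume-preserving
  form, dilation and sphericity are distinct generative axes, a singly
  injected group effect is recoverable as a single significant mode, and
  the length/diameter ratio responds monotonically (∝ s^3/2).
- **Vertex noise is a single smooth field** (iid draws Laplacian-smoothed
  over the ring grid, rescaled to the requested SD, default 0.8 mm, applied
  to both surfaces along their normals). Segmentation error in practice is
  smooth — breathing offsets, slice misregistration, boundary blur — and
  displaces the wall as a whole; independent per-vertex noise at sub-wall
  amplitude would routinely self-intersect thin walls. Residual degenerate
  draws are rejected and redrawn deterministically (seed + fixed offset).

Cohort defaults emulate the clinical setting: 93 subjects in four arms
(MBT 30 stage-I + 29 stage-II; RVPA 20 + 14), per-arm BSA distributions
(0.40/0.44 m² at stage I, 0.67/0.70 m² at stage II), body size entering as
cavity volume ∝ BSA^1.3 (so that indexed volumes are stable across age),
group effects on dilation (+7% at stage I, +9% at stage II) and sphericity
(−3% / −12%) that appear predominantly after stage II, and prescribed peak
strains around −17% (circumferential) and −15% (longitudinal) for MBT with
reduced magnitudes for RVPA. Heart rate is fixed at 120 bpm (0.5 s cycle,
25 frames, 35% systole). Where the defaults are not dictated by the
emulated tables they are one-time choices of what is realistic for infants
at these stages, and the tests do not depend on revisiting them.

Ground-truth volumes integrate the *polygonal-section* solid finely along
the long axis, down to the true apex. The mesh itself (24 rings, centroid-
fan caps) misses only the apical dome beyond its last ring, ≈ 0.3% of
cavity volume — which is why truth and divergence-theorem mesh volume agree
to 0.5%.

## Mesh personalization

Segmentation stacks carry labels 0/1/2/3 (background, RV myocardium, RV
cavity, LV landmark on the most basal slice). Boundaries are extracted as
half-voxel iso-contours per slice. Pose standardization is **rigid only**
— ventricular dilation is a finding, so size must survive into the atlas —
and maps the long axis to z and the landmark direction to +x. The long axis
is estimated from the per-slice epicardial centroid line rather than the
point-cloud principal axis: a dilated systemic RV can be wider than it is
long, and the centroid line is robust to that.

Template fitting replaces the proprietary mesh-personalization tooling used
with clinical data by a documented equivalent: template rings are mapped
affinely onto the subject's long-axis extent (slice centres ± half a
spacing), each vertex is matched along its polar ray to the interpolated
boundary radius about the per-slice cavity centroid (the closest-point rule
specialised to star-shaped short-axis sections), and the radius field is
Laplacian-smoothed with a strength that decreases over iterations. A step
is accepted only if the mean point-to-surface error does not increase, so
the recorded error log is monotone; a final bijective snap to the boundary
points makes self-fits exact. The reported `fittingError` is the mean
distance of all boundary points to the fitted surface, the same "average
fitting error" quality metric used with clinical data, and noiseless
synthetic stacks fit to sub-voxel error.

## The atlas

PCA is computed on the pooled, mean-centred shape vectors in raw mm
(units are homogeneous and size is signal; no per-feature standardization),
via SVD of the centred data matrix. K = 10 modes are retained by default,
truncated with a warning below rank. Mode signs are fixed by making the
largest-magnitude loading positive. Stage-stratified group comparisons
reuse the pooled modes: subset the score matrix and labels and call
`compareModes` again. Bonferroni multiplies raw ANOVA p-values by K and
caps at 1; degenerate zero-variance groups fall back to a seeded
10,000-permutation test. Mode indices are eigen-rank within *this* atlas
and are not comparable across cohorts.

## Strain

The commercial feature tracker is replaced by boundary propagation:
arc-length re-parameterisation to a fixed point count and, for closed
contours, the circular shift/orientation minimising the translation-
invariant squared displacement to frame 0 (end-diastole, the Lagrangian
reference). Segmental strain is `(L(t) − L(0))/L(0) × 100` on six equal
segments; global strain is the arithmetic mean of segments, asserted
exactly. Radial strain from endo-only contours uses the inverted
centroid-distance change so physiologic inward motion is positive;
when epicardial contours exist a thickness-based variant is provided, and
the two are labelled (`radialMethod`) because their magnitudes differ.
Strain rate is the finite-difference derivative of the strain *fraction*
(central in the interior, one-sided at the ends, keeping time reversal
antisymmetric), in 1/s. Systolic peaks are the largest-magnitude values in
[ED, ES] (ES from the volume curve); the diastolic peak is the single
largest-magnitude rate after ES — early and late diastole are not
distinguished, which is flagged here as a simplification. Short-axis levels
sit at the slices nearest 25/50/75% of the base-apex extent, with half-way
ties resolved by rounding so three slices map onto basal/mid/apical.

Note the prescribed longitudinal strain scales the long axis; the realised
4-chamber arc-length strain mixes in the in-plane contraction and is
therefore recorded from the generated contours themselves, keeping the
ground truth self-consistent by construction.

## Statistics

Group comparisons use the equal-variance (Student) t-test — the plain
"unpaired t-test" reading — with Welch available as an option; Shapiro–Wilk
normality is reported but does not trigger a nonparametric fallback. χ² is
Pearson without continuity correction, with expected-count warnings.
Reliability is single-rater two-way random absolute-agreement ICC(A,1),
estimated from the mean-squares decomposition with the F-based 95% CI.
The mass-indexing exponent is configurable (default 1.3, recorded in the
output) because volume-like and length-like conventions both appear in
practice for myocardial mass.

## Numerical choices and degenerate inputs

- EDV/ESV are volume-curve extremes, not fixed frame indices.
- Effective slice spacing is thickness + gap throughout Simpson summation.
- TR bin boundaries (15/25/45%) go to the lower-severity grade; fraction 0
  is "none".
- Myocardial density is 1.05 g/ml.
- Atlas orthonormality, eigenvalue ordering and score centring are typed
  validity invariants checked on every construction.
- Per-subject randomness derives from counter-based seed streams, so
  resizing one cohort arm cannot reshuffle another.

## What a green test does and does not establish

The generator produces label volumes and contours, not image intensities;
propagation is therefore exact up to resampling, and recovered strains sit
within a percentage point of truth. Real feature tracking contends with
image noise, through-plane motion and trabeculations, and is substantially
more variable — the tests validate the *analysis* machinery, not the
difficulty of tracking clinical images. Likewise the idealised anatomy
makes every geometric quantity analytically checkable but does not model
outflow-tract geometry, trabecular surfaces, or the ventriculotomy scar as
a localised material feature; group differences are injected as global
shape factors. Statistical power statements (mode recovery at d = 1.2,
n = 40/arm; family-wise error under the null) are properties of this stated
world at those sample sizes.
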