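---
title: "Nose-preserving de-identification and coregistration evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nose-preserving de-identification and coregistration evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, parameter defaults and
design decisions behind `noseguard`. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` compute.

## 1. The anonymization operators

**Face trimming.** The subject T1 volume is registered to a template
(affine, then nonlinear; Section 3), the template's tissue probability map
(TPM) is warped back into subject space with trilinear interpolation and
voxel-wise renormalization, and every voxel whose *face-class* probability
strictly exceeds the threshold (default 0.10) is set to background zero.
The face class is, by construction of the TPM, disjoint from the nose, so
the nose survives; the brain lies deep inside the head where face
probability is essentially zero. Removed voxels are zero-filled, not
noise-filled: this keeps the operator deterministic and idempotent, and
matches how a removed region renders in practice. The boundary case is
strict (`probability > threshold` removes; equality retains).

**Full de-facing (comparator).** The same warped-probability mechanism
applied to a face-*including*-nose class at the same threshold, so the
comparator removes a superset of the trimmed region. This emulates the
conventional condition — everything trimming removes, plus the nose —
without reproducing any specific third-party de-facer's internals, which
the evaluation does not require.

Trilinear (never nearest-neighbour) interpolation is used for probability
warping: nearest-neighbour would alias the 10% decision boundary into
voxel-sized steps.

## 2. Coregistration

**Head frame.** The MEG head frame is the Neuromag convention: x from LPA
to RPA, origin at the foot of the perpendicular from the nasion to the
LPA–RPA line, y toward the nasion, z up. The anterior-inferior exclusion
rule ("y > 0 and z < 0", strict inequalities, fiducials exempt) is defined
in this frame and only in this frame; the rule is how nose points are
removed when coregistering to a de-faced image.

**Two-step procedure.** Step 1 is the closed-form proper rigid transform
(centroid alignment + SVD with reflection correction) between the three
digitized fiducials and their MRI-marked counterparts. Step 2 refines with
ICP: alternate exact point-to-triangle closest-point correspondence and
rigid refitting until the RMS change falls below `tol = 1e-4` mm (well
below digitization noise) or 200 iterations. Ten initializations are used:
the step-1 transform plus nine random perturbations, uniform within ±15°
per axis and ±10 mm — the multi-start protocol's published description
does not fix these magnitudes, so they are declared defaults, exposed as
arguments. The lowest final RMS wins. Exact triangle distances (not
vertex-nearest) avoid the RMS bias a coarse mesh would otherwise introduce;
the distance queries run through a uniform-grid triangle index with an
expanding-shell search and a conservative termination bound, so they remain
exact. No outlier trimming of correspondences is applied.

**Error metrics.** The fiducial registration error is the mean Euclidean
distance of the three fiducial pairs after applying the estimated
transform — the field's standard proxy, computable on real data. Because
the proxy inherits the manual error of fiducial placement, the simulation
additionally reports a ground-truth error (mean displacement of the
digitized points under estimated vs true device transform), which only a
simulation can provide.

## 3. Atlas registration

The affine stage is 12-dof Gauss–Newton on the sum of squared intensity
differences, coarse-to-fine (downsample factor 2 then 1, smoothing σ = 2
then 1 voxels), initialized by intensity centre-of-mass alignment, with
step halving on non-improvement. The nonlinear stage is a demons-style
small-deformation registration on the template grid at factors 4/2/1
(40/25/15 iterations): symmetric forces (mean of fixed and warped-moving
gradients) with the standard normalization that caps each voxel's update
near half a voxel, Gaussian fluid smoothing (σ = 1 voxel) of the update
and diffusion smoothing (σ = 1.5 voxels) of the accumulated non-affine
field. The comparatively heavy diffusion reflects the character of
anatomical variability this package models — smooth, low-frequency shape
differences — and propagates boundary evidence into structure interiors,
where piecewise-constant intensities provide no signal of their own (the
aperture problem; Section 6). The field is inverted numerically by
fixed-point iteration; Jacobian positivity and forward∘inverse residuals
are asserted in the test suite. A persistent increase of the objective
(8 consecutive iterations above the running minimum) raises a divergence
error rather than returning a bad field.

The canonical inner-skull surface is the level-4 icosphere (2562 vertices)
fitted radially inside the template skull; subject-specific surfaces
displace the template vertices by the interpolated template-to-subject
field. The convention is fixed as *forward displacement applied to template
vertices*; topology is never altered, so surfaces correspond vertex-by-
vertex and are compared index-wise. For shape (rather than pose)
comparison, the rigid pose difference is removed first by corresponded
least squares — Procrustes without scaling, which with known
correspondence has a closed-form optimum, so a single solve suffices. The
least-squares pose minimizes the sum of squared distances; in the unusual
case where it does not reduce the *mean* distance, the identity alignment
is kept, so alignment never worsens the reported mean.

## 4. The phantom generator

Subjects are generated by deforming a shared synthetic template — not as
independent heads — precisely so that atlas-registration ground truth
exists and parameter-recovery tests are possible.

**Template geometry** (mm; 48³ grid at 4 mm voxels by default): a
superellipsoid head (radii 62/72/75, exponent 2.2, centre y = −8) with
concentric brain (scale 0.68) and skull (0.80) shells; a nose ellipsoid
protruding anteriorly at z = −22; ear bumps at x = ±64 carrying the
LPA/RPA fiducials at their lateral apices (the type contract places
fiducials on the head surface, so the apex — the natural preauricular
point — is used rather than the bump centre); an occipital bump, because
the external occipital protuberance is what keeps a real nose-less ICP fit
from slipping freely — without it the phantom's upper head is far more
rotationally symmetric than any real head. Intensities are
piecewise-constant tissue means (air 0, soft 0.7, skull 0.3, brain 1.0),
lightly smoothed (σ = 0.6 voxels) so registration has usable gradients.
The face region is the anterior soft-tissue shell (y > 15,
−55 < z < 28) minus an 8 mm collar around the nose; the five TPM classes
(background, soft, skull, brain, face-without-nose) are smoothed hard
labels (σ = 1 voxel) renormalized to sum to one, with the face class
zeroed on the nose.

**Deformations** are sums of three separable low-frequency sinusoid
products per component (0.5–1.25 cycles per field of view), scaled to a
peak magnitude (default 5 mm), redrawn up to 10 times if the grid-wide
Jacobian determinant is not safely positive, and inverted numerically.
Masks are carried through the deformation by nearest-neighbour resampling
of a single label volume, which preserves their disjointness exactly.

**Digitization** samples points area-uniformly on the true scalp mesh:
scalp points on the upper head (z > −30) excluding the face and nose
regions — real digitization covers the scalp and puts face points around
the nose, not on the cheeks — and nose points on the nose surface. The
study conditions are 100 scalp + 15 nose points, isotropic digitizer noise
of 2 mm, independent fiducial noise of 3 mm (manual fiducial placement is
known to err by several mm, which is also why the fiducial-error metric is
only a proxy), a random device pose within ±20°/±30 mm, and subject
deformations of 5 mm peak amplitude. These defaults are the conditions the
simulated cohort reports; they were chosen once as realistic for this
field and are exposed in `cohort_config()`.

**What the phantom does not model:** MRI physics (bias fields, sequences,
artifacts), real anatomical detail (hair, sinuses, individual noses),
digitizer error correlated along the scalp, or inter-scanner differences.
Passing tests therefore demonstrate the *mechanisms* — nose anchoring,
slippage, segmentation sensitivity to missing face context — not clinical
effect sizes; cohort error magnitudes are on the phantom's own scale
(coarse 4 mm grid, idealized surfaces), not the scale of published human
data.

## 5. Statistics

The Wilcoxon signed-rank test drops zero differences, mid-ranks ties, and
computes the exact null distribution of the positive-rank sum for n ≤ 25
by generating-function convolution over the realized (possibly tied) ranks
— equivalent to full 2ⁿ sign enumeration, which the tests verify — and a
normal approximation with continuity correction and tie-corrected variance
above. Two-sided p-values use the symmetry of the null distribution.
The Welch t follows the closed-form statistic and Welch–Satterthwaite
degrees of freedom (paired data reduce to a one-sample t on differences).
The JZS Bayes factor BF01 integrates the Cauchy-prior (scale r = √2/2 by
default, the conventional "medium" prior) marginal likelihood over the
g-mixture by adaptive quadrature in log space; an independent fixed-grid
quadrature serves as the oracle in the tests. Raw p-values are reported
throughout; no multiplicity correction is applied to the cohort's paired
comparisons.

## 6. Numerical choices and limitations

* Isosurfaces use marching tetrahedra (six tetrahedra per cube sharing the
  main diagonal) on the lightly smoothed binary mask at iso-level 0.5:
  simpler and ambiguity-free compared to tabulated marching cubes, at the
  cost of more (smaller) triangles. Vertices are welded on lattice edges,
  so closed level sets give watertight genus-0 meshes (Euler characteristic
  2, asserted in tests). Taubin λ/µ smoothing (10 iterations) removes
  staircase artifacts with negligible shrinkage.
* Gaussian smoothing of volumes is FFT-based and therefore periodic; all
  structures keep a ≥ 2-voxel margin from the grid boundary so wrap-around
  is inconsequential.
* The demons registration cannot recover displacement components tangent
  to intensity boundaries or deep inside homogeneous regions (the aperture
  problem); its recovery error is bounded in the tests on the head region
  as a whole, and occasional random fields are genuinely harder than
  others.
* Problem sizes were chosen to keep the full suite practical on a single
  CPU: 48³ grids, 30-subject cohorts, 50-phantom ICP recovery batches.
  The cohort (90 nonlinear registrations, 180 multi-start coregistrations)
  is the dominant cost at roughly ten minutes.
* `compare_surfaces` requires shared topology; it is not a general
  nearest-neighbour surface distance. This matches the vertex-corresponded
  canonical-mesh design throughout.
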