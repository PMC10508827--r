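---
title: "Physics-based non-rigid registration: model, parameters and design notes"
author: "pbnrr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based non-rigid registration: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a craniotomy the brain deforms — cerebrospinal fluid drains, pressure
changes, gravity acts, tissue is resected — so the rigid alignment between
the pre-operative MRI (with its functional overlays and surgical plan) and
the intra-operative anatomy degrades by several millimetres. Non-rigid
registration of the pre-op image to an intra-operative MRI restores the
correspondence. `pbnrr` implements the physics-based approach: a sparse
displacement field measured by block matching, regularised by a patient-
specific linear-elastic finite-element model of the brain, with robust
iterative rejection of faulty matches, plus extensions for resection
cavities, incremental adaptation, and registration-point-driven mesh
sizing.

## The model

**Sparse field.** Feature (registration) points are voxels of the floating
(pre-op) image whose surrounding block has high intensity variance. For
each point, every integer displacement $d$ with $|d_a| \le W_a$ is scored
by normalized cross-correlation (NCC) between the floating block of
half-extent $B$ and the displaced fixed block; the argmax is the match.
The per-point search cost is exactly $\prod_a (2W_a+1)$ NCC evaluations of
$\prod_a (2B_a+1)$ voxels, which the implementation exposes through an
instrumentation counter. NCC is affine-invariant in intensity, so the
matching is insensitive to global intensity rescaling between scans.

**Biomechanical regularisation.** The brain mask is tessellated into
4-node tetrahedra (internally with a body-centred-cubic lattice mesher);
each element carries a tissue label mapped to a Young's modulus $E$ and
Poisson ratio $\nu$. The element stiffness is the standard constant-strain
$K_e = V\,B^\top C(E,\nu)\,B$, assembled into the global sparse $K$. The
registration solves

$$[K + H^\top S H]\,U = H^\top S D (+ F),$$

where $H$ interpolates mesh displacements to the match points
(barycentric rows), $D$ stacks the matched displacements, and $S$ is
block-diagonal with $\max(c,0)^2 I_3$ per match ($c$ the NCC confidence):
higher-confidence matches pull harder; negative correlations get zero
weight. The pure system ($F=0$) is the interpolation formulation; adding
the internal-force term $F = K U_i$ and iterating relaxes the mesh stress
so the solution drifts toward the unregularised weighted least-squares fit
$\arg\min_U (HU-D)^\top S (HU-D)$.

**Outlier rejection.** Over $n_R$ iterations, the per-match error
$\xi_k = (H_k U - D_k)^\top S_k (H_k U - D_k)$ is computed and the
$\lfloor f_R n / n_R\rfloor$ worst active matches are discarded (remainder
in the last round, so exactly $\lfloor f_R n\rfloor$ in total; ties break
toward lower confidence, then match index). The relaxation loop then runs
until the relative change of $U$ falls below `relaxTol` or
`relaxMaxIter` is reached.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `B` | (3,3,3) voxels | block half-extent; texture context per match |
| `W` | (5,5,5) voxels | integer search half-range; must cover the expected shift (per increment) |
| `fraction` | 0.05 | top share of candidate blocks kept by variance |
| `minSpacing` | 3 voxels | greedy spacing of selected centres |
| `minConfidence` | 0.5 | NCC below which a match is dropped |
| `fR`, `nR` | 0.25, 5 | total rejected fraction and rejection rounds |
| `relaxTol`, `relaxMaxIter` | 1e-3, 50 | relaxation stopping rule |
| `stiffnessScale` | `"auto"` | sets trace(scale·K)/trace(HᵀSH) = 10 |
| `E`, `nu` | 3000/9000 Pa, 0.45 | parenchyma/tumour defaults of this package |
| `cellSize` | 8 mm | BCC cell edge |
| `bgThreshold`, `bgFraction` | Otsu, 0.8 | resection background rule |
| `k`, `a` | 5, 1.2 | sizing neighbours and ellipsoid inflation |

Only the *ratio* between $K$ and $S$ affects the solution path, so the
stiffness scale is an explicit dimensionless knob rather than a hidden
units convention; `"auto"` targets a trace ratio of 10 and the resolved
value is returned with every solve. Because a direct sparse Cholesky
factors the (verified positive definite) system, the inner-solve residual
contract (`linearTol`, default 1e-8) is met to machine precision and
results are bit-reproducible.

## Coordinate and field conventions

Voxel indices are 0-based with `world = origin + index * spacing`;
axis-aligned geometry only (no direction cosines) — the phantoms and the
method itself never need oblique orientations, and this removes a large
conformance surface. All displacements are world-space mm. Warping is
backward, `out(x) = img(x - u(x))`, so a dense field lives on the output
(intra-op) grid; the nodal solution, anchored at the match source points,
is interpreted as that backward field under the small-deformation
approximation (the discrepancy between anchoring at source and target
positions is second order in the displacement gradient).

The rasterised field is extrapolated a band of about one element outside
the mesh hull (iterative 6-neighbour mean fill). The hull of a
centroid-rule BCC mesh sits up to half a cell inside the object surface;
without the band, surface structures get zero displacement, which in
particular makes the 100% Hausdorff evaluation blind to any recovery at
the brain surface. Beyond the band the field is zero — a documented
limitation, visible when features of interest lie far outside the mesh.

## Resection handling and incremental adaptation

A resection cavity appears as background intensity *inside* the brain of
the intra-op image. An element is flagged when at least `bgFraction` of
its five samples (4 vertices + centroid, displaced by the current nodal
solution) fall below the background threshold (Otsu over the mesh
bounding box by default). The removed set `M_Rem` is grown iteratively
from the largest face-connected flagged component; growth is monotone and
stops when nothing face-adjacent is flagged any more. Two concretizations
are this package's own: connectivity is by shared triangular face (vertex
connectivity would leak through pinch points), and the seed component must
be *solid* — it must contain at least one tet whose four face neighbours
are all flagged. The solidity rule distinguishes a genuine cavity from
the thin film of surface slivers that a voxelised mask mesh always
produces, and makes "no cavity in the image" return an empty set.

The adaptive loop (`adaptiveRegister`) splits a large deformation into
`nIter` increments: re-mesh the warped labels, register the warped
floating image to the fixed image, detect and remove cavity elements
*using the registered displacements* (a tet that still lands on
background after following the brain is resected tissue; detecting before
registration would mistake the not-yet-recovered shift crescent for a
cavity), and compose the incremental field into the running total,
`u(x) = u_{inc}(x) + u_{prev}(x - u_{inc}(x))`. The composed field's
support is clamped to a band around the brain because the extrapolation
bands of successive increments would otherwise creep outward through
composition. Every intermediate mesh is rebuilt from the warped labels,
so inverted or sliver elements cannot accumulate — the reason to adapt
incrementally at all. With one iteration and no cavity the loop reduces
bit-for-bit to a single registration pass.

## Mesh sizing metrics

For mesh gradation driven by the registration points, the isotropic rule
sets the target spacing at a vertex to the distance of its $k$-th nearest
registration point (so an ideally sized mesh puts about $k$ points in each
vertex cell complex), clamped below by half the smallest voxel size to
avoid zero sizing at coincident points. The anisotropic rule replaces the
sphere with the minimum-volume enclosing ellipsoid (Khachiyan barycentric
coordinate descent, tolerance 1e-6, capped at 1e5 iterations) of the $k$
nearest points *and their point reflections through the vertex* — the
reflection trick forces the centre to the vertex exactly, by symmetry. A
common inflation constant $a \ge 1$ scales all semi-axes ($M \mapsto
M/a^2$), loosening the constraint uniformly. Coplanar point sets are
regularised by an isotropic jitter of $10^{-6}\times$ the bounding box on
the moment matrix and flagged. The exported VTK point-data field (scalar
`spacing` or 6-component symmetric `metric`) is the hand-off to an
external metric-driven remesher; performing the adaptation itself is out
of scope.

## Evaluation

Registration quality is summarised by the symmetric Hausdorff distance
between Canny edge points of the intra-op image and Canny points of the
pre-op image mapped through the computed field. Canny is a full-volume
3-D implementation (Gaussian smoothing, central-difference gradients,
non-maximum suppression along the gradient with trilinear magnitude
sampling, 26-connected hysteresis); thresholds default to 0.1/0.2 of the
maximum gradient magnitude. The untrimmed (100%) HD is the default, with
a percentile parameter for the 95% variant. This instrument supports
*relative* comparisons between methods only — the report says so — and
the 100% variant is brittle by construction: one unmatched edge point
sets the value. On strongly compressed textured phantoms the
relative-threshold extraction is asymmetric (compression sharpens weak
gradients into intra-op-only edges), so the phantom experiments use the
denser setting 0.05/0.1, which restores symmetric edge coverage; this is
an instrument setting, not a change to the package defaults. Landmark
errors (`landmarkErrors`) give the per-point min/max/mean alternative
when corresponding landmark pairs are available.

## The phantom generator

`makePhantom` builds the study substrate: an ellipsoidal brain (semi-axes
0.42 of the world extent, label 1) with an embedded spherical tumour
(label 2, radius 0.12 of the minimum extent), per-label base intensities
(0/60/120) plus band-limited Gaussian texture (amplitude 12, correlation
length 3 mm) — NCC is contrast-invariant, so the amplitude is chosen low
enough that Otsu-thresholded background detection never confuses dark
texture with background. The ground-truth field is a sum of radial
Gaussian bumps rescaled to peak magnitude `deformMax`; the default is one
broad bump (radius 0.9 of the minimum extent, centred on the brain),
emulating global gravity-induced brain shift — full strength throughout
the parenchyma and tapered to zero (cosine-squared over a 0.3-radius
shell) outside the brain surface. A brain-wide default matters because
integer-voxel matching has an irreducible quantisation floor of roughly
0.4–0.5 mm at 1 mm voxels: recovery-versus-baseline statements are
meaningful only when the mean true displacement is well above that floor.
The intra-op image is the pre-op warped backward by the truth field, with
the optional resection sphere zeroed afterwards so the cavity is an
intra-op-space feature, exactly what a threshold segmentation of the
intra-op image sees.

What the phantom does *not* emulate: anatomical structure (gyri,
ventricles, falx), MR physics (bias fields, noise correlations, partial
volume), multi-modal intensity relationships, and physically derived
deformations (the truth field is smooth and divergence-unconstrained).
Passing phantom tests therefore demonstrates the correctness of the
machinery — matching, assembly, solving, rejection, detection,
composition, evaluation — not clinical accuracy on real image pairs.

## Numerical choices and degenerate inputs

* Feature selection treats block variance below
  $10^{-12}(1+\text{mean}^2)$ as zero (constant blocks are never
  features); NCC with a zero-variance operand returns 0 with a
  `degenerate` flag and such matches are dropped.
* NCC argmax ties break toward the smaller displacement norm, then
  lexicographic $(d_z, d_y, d_x)$ — deterministic and biased toward no
  motion. Search candidates whose block would leave the fixed image are
  skipped; the pipeline selects features with margin $B + W$ by default so
  every candidate is evaluable (`margin = B` keeps near-border features
  when the expected shift exceeds the distance to the border).
* Tetrahedra are stored with positive signed volume (inputs are
  reoriented, exact degeneracies at $10^{-12}$ mm³ are errors); duplicate
  vertices within $10^{-9}$ mm are rejected.
* Point-in-tet tests accept barycentric weights down to $-10^{-9}$ and
  renormalise; points outside every tet are dropped with a warning.
* The system matrix is verified positive definite by its Cholesky
  factorisation; failure raises a conditioning error with a smallest-
  eigenvalue estimate for small systems.
* Per-iteration rejection counts, schedules and tie-breaks are exact
  integer arithmetic, making the whole solve bit-reproducible.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on generated
phantoms: 64³ voxels (1 mm) for translation, smooth-recovery, outlier and
resection studies; 48³ for the adaptive study; 16³–32³ for unit tests;
meshes between ~70 and ~35 000 elements (BCC cells 3–8 mm); 1 000–3 000
matches per registration. These sizes were chosen so each study finishes
in seconds to a couple of minutes while keeping every effect it measures
(quantisation floor, rejection dynamics, cavity growth) comfortably
resolved.

## Known limitations

* Small-strain linear elasticity; no contact with the skull, no
  hyperelasticity, no higher-order elements.
* Integer-voxel matching only — sub-voxel accuracy comes from the FE
  averaging, not the matcher, and a correlated ~half-voxel quantisation
  floor remains.
* The dense field is zero beyond the extrapolation band outside the mesh.
* The fuzzy-correspondence (inner-EM) variant of resection handling —
  simultaneous estimation of a point-correspondence matrix with the
  field — is not implemented; only the geometric outer rejection is.
* The 100% Hausdorff/Canny evaluation is a relative instrument; it is not
  a clinical accuracy measure and the report labels it accordingly.
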