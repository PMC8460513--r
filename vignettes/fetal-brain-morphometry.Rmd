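---
title: "Fetal brain surface morphometry with fetalmorph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal brain surface morphometry with fetalmorph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalmorph)
```

# Scope and model of the analysis

`fetalmorph` quantifies fetal brain development from labeled MRI
segmentations, the setting being longitudinal imaging of fetuses with
myelomeningocele (MMC) scanned before and after in-utero surgery and
compared to gestational-age-matched controls. The pipeline is hierarchical:

1. **Volumetry.** A structure's volume is its voxel count times the voxel
   volume (product of the three spacings). "Voxel dimension" is read as
   voxel *volume*, since the quantity must come out in mm^3^.
2. **Global shape.** Surfaces are iso-surfaced from the binary structure
   mask; the surface area is the sum of triangle areas and the *shape
   parameter* is area/volume (mm^-1^), a compactness measure (3/R for a
   sphere).
3. **Local shape.** Per-vertex principal curvatures \(k_1 \ge k_2\) give
   the *curvedness* \(C = \sqrt{(k_1^2 + k_2^2)/2}\) (how strongly the
   surface bends, mm^-1^) and the *shape index*
   \(SI = \tfrac{2}{\pi}\arctan\frac{k_1 + k_2}{k_1 - k_2} \in [-1, 1]\)
   (what kind of bend: +1 gyral dome, 0 saddle, -1 sulcal cup).
4. **Longitudinal correspondence.** Rigid coherent point drift (CPD)
   initialises an alignment of the post surface to the pre surface; joint
   spectral matching (JSM) produces a per-vertex correspondence through
   which post-operative curvature fields are pulled back to the
   pre-operative surface and differenced (post minus pre).
5. **Regional summaries.** The cortical (unmyelinated white matter)
   surface is split into 8 lobes (frontal/temporal/parietal/occipital by
   hemisphere) by nearest-neighbour label transfer from any fully labeled
   reference mesh, and fields are averaged area-weighted per region.
6. **Biometry.** TCD, VW, CHL and CSO are computed from named landmark
   coordinates; landmark placement (a manual step in practice) is out of
   scope and supplied by the user or the phantom generator.
7. **Statistics.** Growth is assumed linear between two scans, so paired
   changes are expressed per week of gestation. Group comparisons use the
   Kruskal-Wallis H test (tie-corrected; chi-squared p, exact permutation
   enumeration for small n), normality screens use the Anderson-Darling
   test, summaries are median/IQR (type-7 quantiles), and correlations are
   Pearson r with strength bins (|r| < 0.3 none/very weak, then weak,
   moderate at 0.5, strong above 0.7, boundaries assigned upward).

No patient data ship with the package; every claim is validated against
analytic shapes and a synthetic phantom family with known ground truth.

# The synthetic phantom family

`phantom_spec()` describes a star-shaped "brain": an ellipsoid radius
(default semi-axes 30, 25, 20 mm, the scale of a mid-gestation cerebrum)
modulated along each direction \(u\) by a band-limited fold pattern,

\[ r(u) = r_{\mathrm{ellipsoid}}(u) + A\, f(u), \]

where \(f\) is a seeded random combination of real spherical harmonics of
a single degree (default 6), normalized so \(\max |f| = 1\); the fold
amplitude \(A\) is therefore in mm. Ventricles are a concentric scaled
copy of the brain ellipsoid (default scale 0.25) and the cerebellum a
disjoint posterior-inferior ellipsoid (default semi-axes 12, 9, 8 mm).
Volumes are emitted at 0.8 mm isotropic spacing, the resolution of the
super-resolution reconstructions this pipeline is meant to consume.

**Ground truth.** Because the phantom is star-shaped, its interior volume
is an exact angular integral \(V = \tfrac13 \oint r(u)^3\, d\Omega\),
which the generator evaluates by quadrature on a subdivision-5 icosphere
(10,242 near-uniform nodes; the residual error is far below the 2%
voxelization tolerance the tests assert). This replaces oversampled-grid
truth: it is cheaper and more accurate, and it is mesh-free. Ventricle and
cerebellum volumes are closed-form ellipsoid volumes. Truth surfaces are
built on a shared icosphere parameterisation — vertex \(i\) of the pre and
post mesh corresponds by construction — giving exact correspondence ground
truth for the matching stage.

**Longitudinal pairs.** `generate_longitudinal_pair()` grows structure
volumes linearly at configurable mm^3^/week rates (defaults on the scale
of mid-gestation control growth: ventricles ~650, cerebellum ~770, white
matter ~8000 mm^3^/week) and the fold amplitude at
`fold_increase_per_week` (default 0.5 mm/week). The folding default is
deliberate: at mid-gestation, cortical folding outpaces global growth, so
mean curvedness rises between scans. Below roughly 0.3 mm/week the
phantom's global radial growth dilutes curvature faster than folding adds
it and that developmental signature disappears; 0.5 mm/week places the
phantom firmly in the folding-dominated regime the study population
occupies.

**Cohorts.** `generate_cohort()` emulates the study design: n affected
fetuses scanned twice (pre at ~23.9 ± 1.0 weeks, interval ~2.3 weeks) and
two cross-sectional control groups (early ~23.3, late ~28.9 weeks).
Per-subject growth rates are drawn per group; the affected defaults use
elevated ventricular growth (mean 3699 vs 648 mm^3^/week) and an elevated
folding rate. Biometrics are generated as noisy cube-root functions of the
corresponding structure volumes, so VW-ventricular-volume and
TCD-cerebellar-volume correlations are moderate-to-strong positive by
construction. `cohort_effects(zero_effect = TRUE)` removes all group
differences (null calibration); `ventricle_shift_sd = 5` injects a
location shift in control-SD units for power studies.

**What the phantom does not emulate.** MRI intensities, segmentation
error, the Chiari-II hindbrain geometry, brain-like base concavities
(insula, interhemispheric fissure), and asymmetric or regionally focal
folding. Passing tests therefore demonstrate correctness of the
*computational machinery* under known geometry, not clinical performance
on real segmentations. One concrete consequence: on this convex-base
phantom the gyral (SI > 0) area fraction *decreases* with folding — the
unfolded ellipsoid is convex everywhere, so the fraction starts at 1 and
folding can only carve sulci — whereas mean curvedness and the sulcal
area fraction increase strictly. In real fetal cortices, which are not
convex ellipsoids, mean SI is observed to rise with gestation; a phantom
would need built-in concave anatomy to reproduce that, which we judged
out of scope.

# Numerical choices

**Iso-surfacing.** No installed package provides marching cubes, so the
package implements marching *tetrahedra* (each grid cube split into six
tetrahedra sharing a main diagonal, crossing edges cut at the 0.5
iso-level midpoint). The variant needs no case tables, and always produces
watertight, consistently oriented meshes; triangle orientation is fixed
locally by pointing normals away from the inside corner of each
tetrahedron. Meshes are optionally smoothed with Taubin's non-shrinking
lambda/mu filter (0.5/-0.53, default 10 passes) — chosen over plain
Laplacian smoothing precisely because volumetry must not shrink. By
default only the largest 6-connected voxel component is meshed, guarding
against speckle labels.

**Curvature estimation.** A local quadric
\(h(x,y) = ax^2 + bxy + cy^2 + dx + ey\) is fit by least squares over the
2-ring vertex neighbourhood in the tangent frame of the area-weighted
vertex normal, and the principal curvatures are the eigenvalues of the
shape operator assembled from both fundamental forms at the origin. The
quadric fit was preferred to cotangent-formula discrete operators because
it is robust on the irregular, sometimes near-degenerate triangles that
iso-surfacing produces. Vertices with fewer than 5 neighbours are marked
invalid; SI is additionally undefined (NA) where curvedness falls below
`1e-4` mm^-1^ (planar points), and the umbilic case takes its continuity
limit sign(k1). The sign convention is fixed by outward normals: a convex
sphere has \(k_1 = k_2 = +1/R\), so gyri are positive.

**Laplacians and eigenmodes.** The spectral stage uses the cotangent
Laplacian with lumped (one-third-area) vertex mass; negative cotangent
sums from obtuse triangles are clamped to zero, keeping the operator
positive semi-definite (a combinatorial Laplacian is available). The
generalized eigenproblem is solved densely below 1,600 vertices and by
ARPACK shift-invert (via a sparse Cholesky factor) above, with a seeded
deterministic start vector; eigenvector signs are fixed by making the
largest-magnitude entry positive.

**CPD.** The rigid coherent point drift EM uses outlier weight `w = 0.1`,
tolerance 1e-6, at most 150 iterations, and subsamples clouds above 3,000
points (rigid stage only). Because the EM landscape is multimodal for
near-symmetric brains, the fit is initialised deterministically from the
best of 29 candidate rotations (identity, four principal-axes alignments,
and the 24 octahedral rotations), each scored by a 12-iteration EM run on
a 400-point subsample.

**Joint spectral matching.** Initial inter-layer links are mutual nearest
neighbours after CPD alignment, capped at N/10. Two embedding variants are
provided. The default (`method = "aligned"`) embeds each surface
separately and resolves the eigenmode sign/order ambiguity by greedily
pairing modes that maximise |correlation| through the links (with an
eigenvalue-similarity guard); paired modes are weighted by inverse square
root of the eigenvalue. The alternative (`method = "joint"`) assembles the
dual-layer graph (block mesh Laplacians plus links weighted `gamma = 1`
relative to the mean intra-layer weight) and keeps the link-coherent low
modes. The aligned variant is the default because, with the weak coupling
a capped link set provides, the joint spectrum contains quasi-degenerate
layer-symmetric/antisymmetric pairs whose uneven energy split between
layers biases nearest-neighbour matching; on phantom pairs the aligned
variant matches essentially exactly while the joint variant does not.
Matching coordinates are optionally augmented with CPD-aligned 3D
positions scaled to the spectral block's variance (`spatial_weight = 1`),
which stabilises assignment within symmetric fold patterns. Field
transfer is nearest-neighbour (values, not interpolants, so transferred
ranges never exceed the source range), and longitudinal change is post
minus pre.

**Parcellation.** Nearest-neighbour label transfer after rigid CPD
alignment replaces non-rigid atlas registration: the atlas is external
data, so any fully labeled reference mesh is accepted and accuracy is
validated against an analytic 8-sector phantom truth instead. Boundary
vertices are cleaned by a single-pass 1-ring majority filter that keeps
the current label on ties (making the filter idempotent on clean
labelings).

**Biometry.** CHL is the signed distance of the lowest cerebellar point
from the foramen-magnum plane with the normal oriented caudally, so
herniation is positive and surgical reversal is a decrease. CSO is
measured between rays leaving the mutual closest points of the two lines,
which makes it independent of point order within each line while still
reporting obtuse angles unfolded (the anatomical angle can exceed 90
degrees); exactly parallel lines report 0.

**Statistics.** Kruskal-Wallis always applies the tie correction; the
chi-squared approximation is default and full permutation enumeration is
used when the total n is at most 10 (at n = 4 + 4, 70 assignments). The
approximation and the exact p agree closely only in the tail — for
well-separated groups of four the difference is below 0.01, while
mid-range H values can differ by ~0.1, which is why small-cohort
significance calls use the exact p when it is available. Quantiles are
type-7 (linear interpolation), recorded in the run log. Control rates are
formed by pairing early and late control subjects by gestational-age rank,
the package's surrogate for the age-matched-pair design. Correlation
strength bins are applied to |r| with the sign reported separately, and
boundary values go to the stronger bin so labels are deterministic. No
multiple-testing correction is applied, matching the analysis the
pipeline reproduces.

# Validation suite sizes

The test and acceptance runs use problem sizes chosen to exercise every
claim at comfortable margins: voxel spheres at 0.5 mm (33k foreground
voxels), icospheres at subdivision 3-4 (642 / 2,562 vertices), phantom
truth surfaces at subdivision 3 for matching (mean edge ~3.8 mm) and 5
for quadrature, 10 seeded longitudinal pairs for correspondence accuracy,
200 null cohorts for type-I calibration and 100 shifted cohorts for
power. On one CPU the full test suite runs in a few minutes and the
acceptance script in ~2.5 minutes.

# Known limitations

- Marching tetrahedra produces ~2x more triangles than marching cubes for
  the same grid; curvature on raw (unsmoothed) iso-surfaces is noisy, and
  the analytic truth surfaces are the right substrate for curvature
  validation.
- The correspondence is vertex-to-vertex (no barycentric refinement); its
  error floor is the target mesh resolution.
- The ventricle is one merged compartment; sub-compartments (third/fourth
  ventricle, CSP) would need distinct codes and generator support.
- Landmark detection is intentionally absent; biometry is only as good as
  the supplied landmarks.
- `run_group_analysis()` assumes the early/late control pairing by GA rank
  approximates the matched design; with strongly unbalanced control GA
  distributions the pairing (and hence control rates) degrades.
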