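---
title: "Pair-matching bilateral bones by 3D-3D superimposition: methods and design"
author: "OsteoPair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-matching bilateral bones by 3D-3D superimposition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OsteoPair)
```

## The problem and the model

When skeletal remains from several individuals are commingled, a first step
of the sorting workflow is pair-matching: deciding whether a left and a
right bilateral element — here, pubic bones — come from the same person.
OsteoPair quantifies that decision through 3D-3D superimposition of surface
models. The premise is biological: within one individual, the left and
right elements are near mirror images (bilateral asymmetry is small), while
between individuals shape varies much more. If we mirror the left model,
rigidly align it onto a right model as well as possible, and measure how
far the two surfaces still are from each other, true pairs should produce
systematically smaller residuals than non-pairs.

The residual is summarised as the root-mean-square point-to-surface
distance

$$\mathrm{RMS} = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n} d_i^2},$$

where $d_i$ is the Euclidean distance from the $i$-th vertex of the moving
(mirrored left, registered) model to its closest point on the fixed (right)
surface, in millimetres. Squaring removes the sign, so receding and
prominent areas cannot cancel the way they would in an arithmetic mean.
The RMS is directional — the moving model's vertices against the fixed
surface — and no symmetric variant is used.

Registration is rigid throughout. Only shape is compared, never size: the
transform is constrained to a proper rotation ($R^\top R = I$,
$\det R = +1$) plus a translation. No scaling, affine or deformable mode
exists anywhere in the pipeline, and every ICP update asserts the
determinant condition, so a reflection or scale cannot slip in through
numerical error.

## The registration stage

Alignment happens in two steps, mirroring the usual operator protocol:

1. **Landmark seeding** (`landmarkAlign`). Three named anatomical points —
   the most superior and most inferior points of the pubic symphysis
   (`sym_sup`, `sym_inf`) and the most medial point of the obturator
   foramen (`obt_med`) — are matched by name and the least-squares rigid
   transform is computed in closed form (Kabsch: SVD of the 3×3 covariance,
   with the smallest singular direction flipped if the raw solution is a
   reflection). Three points are the minimum that determines a rigid pose;
   they must be non-collinear, which the `LandmarkSet` validity enforces
   (pairwise distances > 1e-6 mm, triangle area > 1e-9 mm²). A subtlety
   worth recording: three labelled points are always coplanar, so even
   correspondences generated by a reflection are fitted exactly by a
   proper rotation (compose the reflection with the mirror across the
   points' own plane). The reflection exclusion therefore never costs
   residual at the seeding stage; it matters in the ICP updates, where the
   correspondences are far from coplanar.
2. **ICP refinement** (`icpRegister`). Iterates (a) closest-point
   correspondence from every moving vertex to the fixed surface and (b)
   the closed-form rigid update for those correspondences, until the RMS
   improves by less than `tolMM` or `maxIterations` is reached. Each
   update minimises the distance to the current correspondence points, and
   re-projecting onto the surface can only shorten each distance, so the
   recorded RMS trajectory is monotonically non-increasing — this is
   asserted by the `RegistrationResult` validity method. Non-convergence
   within the cap is reported (`converged = FALSE`), never thrown: in an
   assemblage run a flagged, slightly unconverged cell is more useful than
   a hole in the matrix.

Correspondences target the closest point *on the fixed triangulated
surface* (point-to-triangle projection), not the closest vertex. Surface
projection makes the distance independent of how densely the fixed model
happens to be sampled; a `correspondence = "vertex"` mode exists for
comparison. Ties between faces at exactly equal distance are broken by the
lowest face index, so runs are bit-reproducible.

Defaults that matter, all exposed through `icpParams()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `maxIterations` | 100 | – | converges in 20–80 iterations at fixture resolution |
| `tolMM` | 1e-6 | mm | far below any biological signal (~0.1 mm) |
| `maxCorrespondenceDistance` | `Inf` | mm | whole surfaces are compared; no trimming |
| `sampleSize` | all vertices | – | models at this resolution need no subsampling |

The fine-registration internals of the commercial tools this workflow is
usually run in are unpublished, so these values are this package's own
reasoned choices, exposed as configuration rather than asserted as
equivalent to any particular product.

## Preprocessing

**Mirroring** reflects across a coordinate plane (default $x = 0$) and
reverses the face winding so the surface stays outward-oriented. The choice
of plane is immaterial: any two mirror planes differ by a rigid motion,
which the subsequent registration absorbs — this invariance is tested.

**Hollowing** (`hollowMesh`) removes interior trabecular remnants that
survive segmentation and would corrupt a surface comparison. The
reimplementation casts rays from `nDirections` viewpoints placed
quasi-uniformly (Fibonacci lattice) on a sphere of `offsetFactor` times the
bounding-sphere radius; a face is retained when any of its three vertices
or its centroid is reached unobstructed from any viewpoint. Partially
occluded faces therefore count as visible — conservative retention avoids
punching holes in the cortical shell. Whether the original "select by
visibility" tools remove faces or whole components is not documented;
face-level removal is the default here, and `componentwise = TRUE` retains
entire connected components containing a visible face instead. With 256
directions, closed shells at fixture resolution are classified exactly
(the concentric-spheres oracle test passes from 16 directions upward).

## Classification and statistics

`buildComparisonMatrix` arranges the all-against-all design: per group, all
lefts (paired and unpaired) against all paired rights. Comparisons are
made within groups only — the workflow assumes a prior sex assessment, both
because size differences between the sexes would contaminate the RMS and
because it halves the comparison space. The pooled ("combined") analysis is
the union of the within-group comparisons, so its grid contains empty
(`NA`) cells for cross-group combinations that were never superimposed;
all counts and rates run over filled cells only.

`classify` uses an **inclusive** threshold: a cell is a match iff
RMS ≤ t. The rule matters at the boundary — a true pair sitting exactly at
the threshold counts as detected, which is the behaviour needed for a
cut-off placed at the largest match RMS to report 100% sensitivity.
`sweepThresholds` evaluates every observed RMS value as a candidate
threshold and recommends, among thresholds with zero false negatives, the
one with fewest false positives (ties towards the larger threshold). In
forensic practice false positives are the tolerable error: a suggested
pair can be double-checked by other methods, while a falsely rejected true
pair is discarded outright. Zero-miss thresholds are therefore the
candidate set, and the sweep exposes the full curve for anyone who weighs
the errors differently.

Match and mismatch RMS distributions are compared with a Mann–Whitney
rank-sum test (`rankSumTest`), exact when the combined sample is ≤ 20 and
tie-free, normal approximation with continuity and tie correction
otherwise. Repeatability uses the standard anthropometric technical error
of measurement, $\mathrm{TEM} = \sqrt{\sum_i d_i^2 / 2n}$ over repeated
measurement pairs, and $\mathrm{rTEM} = 100\,\mathrm{TEM}/\bar{x}$ with
the grand mean of both runs as denominator (the usual convention; the
qualitative "good/acceptable" rating bands vary between authors and are
deliberately not hard-coded).

## The synthetic assemblage generator

No CT-derived models ship with the package, so every pipeline stage is
validated on synthetic assemblages (`generateAssemblage`). The generator
does not attempt anatomical realism; it emulates the *variance structure*
that makes pair-matching work.

The template is a curved, plate-like open shell of roughly 40 × 30 × 15 mm
(a bent rectangular grid) with a disc-shaped notch cut out as a stand-in
for the obturator-foramen region, and three fixed template vertices as
landmarks, tracked through all deformations. Each individual is the
template deformed by a smooth random field shared by both sides
(amplitude `sigmaBetween`, default 2.0 mm); the right side additionally
receives an independent field of amplitude `sigmaAsym` (default 0.3 mm) —
the bilateral asymmetry. The left model is the mirror of the individual's
left-side shape, and each exported model receives a random rigid pose
(undone by registration). With `sigmaAsym = 0` and pose randomisation off,
re-mirroring the left reproduces the right bitwise.

Deformation fields are sums of 10 random trigonometric basis terms with
wavelengths drawn from 15–45 mm — comparable to the template extent, so the
fields carry genuine shape content rather than near-rigid drift. The
amplitude is normalised on the field's *non-rigid* content: the best-fit
rigid motion of the displaced template is removed before scaling to the
requested sigma, because any rigid component is invisible to registration
and would otherwise make the effective asymmetry erratic across seeds.
Under these defaults the end-to-end match RMS sits around 0.15–0.25 mm and
mismatches around 1.2–2.0 mm — the same qualitative regime reported for
real pubic bones (matches ≈ 0.4–0.9 mm, mismatches up to ≈ 5.6 mm), with
complete separation at desk-scale sample sizes.

A master seed spawns per-individual seeds deterministically, so
assemblages are reproducible file-for-file while individuals remain
independent. The default design is 20 paired individuals plus 2 unpaired
lefts per group, two groups: 440 superimpositions per group, 880 in
total, 40 matches and 840 mismatches.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: segmentation noise and CT partial-volume
artefacts, taphonomic damage and fragmentation, size allometry between
groups, and real pelvic shape variation (the between-individual field is
isotropic and stationary, real variation is neither). The synthetic
separation between matches and mismatches is cleaner than the published
real-data separation, where a few mismatches dip below the zero-miss
threshold; conclusions about real sorting performance must come from real
assemblages.

**Repeatability caveat.** The repeatability protocol
(`repeatabilityProtocol`) models operator variation as Gaussian jitter of
the landmark coordinates (default σ = 0.5 mm), landmark placement being
the only manual step of this pipeline. The observed TEM is then close to
zero: ICP converges to the same optimum from any reasonably seeded start,
so landmark error is almost entirely absorbed. Published inter-observer
rTEM values of a few percent for the CT workflow must therefore stem
mostly from the segmentation stage, which is out of scope here. The
protocol still verifies the chain end-to-end: zero jitter gives exactly
zero TEM (the pipeline is deterministic), and jittered runs stay well
under a 10% rTEM.

## Numerical choices and degenerate inputs

- Vertex merge tolerance on mesh read is 1e-9 mm (coordinate snap): STL
  repeats vertices per facet, and merging is required to recover
  connectivity without altering geometry. Zero-area faces are dropped with
  a message; an empty mesh after cleaning is an error.
- Binary STL stores 32-bit floats; round-trips are exact to ~1e-4 mm at
  bone scale. ASCII STL and PLY are written with 9 significant digits
  (~1e-6 mm). Units are millimetres everywhere; the formats carry no unit
  metadata, so nothing else is accepted.
- Face winding is checked on read (an edge traversed twice in the same
  direction betrays a flip) and repaired by breadth-first flipping.
- The closest-point query prunes triangles by the bounding-sphere lower
  bound $|p - c_j| - r_j$ against the current best distance, after seeding
  with the nearest-centroid triangle; results are identical to the
  brute-force scan (oracle-tested to 1e-9 mm) at a fraction of the cost.
- The sign of a signed distance comes from the interpolated
  (area-weighted, barycentric) target vertex normal at the closest point;
  exact-zero distances are signed 0. Signs affect only the chromatic maps,
  never the RMS.
- Distance-map colours follow a diverging blue–green–red map clipped at
  `colorRange` (default 2.0 mm, covering the observed match/mismatch
  range): blue = receding, green = coincident, red = prominent.

## Problem sizes

The shipped tests run the registration oracles on shells of about 60–650
vertices, the distance oracle against a brute-force all-triangles scan on
meshes ≤ 200 faces, and the end-to-end property on five full assemblages
(880 superimpositions each) at the default template resolution
(`meshSubdivisions = 4`, ≈ 220 vertices per model) — the resolution at
which the whole suite completes in a few minutes on a single core. The
acceptance script runs one full assemblage plus the 10-subject
repeatability protocol. Mesh resolution is a free parameter of the
generator; the statistical behaviour reported above is stable from about
`meshSubdivisions = 3` upward.

## Known limitations

- Entry point is a surface mesh: no DICOM/CT segmentation.
- Rigid-only by design; specimens with strong size disparity between
  sides (pathology, juvenile remains) violate the model's premise.
- Fragmented or taphonomically damaged elements are untested here; partial
  overlap would require correspondence trimming
  (`maxCorrespondenceDistance`), whose interaction with the monotone-RMS
  guarantee is not characterised.
- The RMS threshold is assemblage-specific. The sweep recommends the
  zero-miss threshold *for the data at hand*; transferring a numeric
  threshold between populations, scanners or segmentation protocols is not
  supported by anything in this package.
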