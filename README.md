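# OsteoPair

Digital pair-matching of bilateral bones by 3D-3D surface superimposition.

## The problem

Sorting commingled skeletal remains — intermixed bones from several
individuals — starts with pair-matching: deciding whether a left and a
right bilateral element (here, pubic bones) belong to the same person.
Visual matching is subjective and osteometric methods are tied to reference
populations. OsteoPair implements the virtual-anthropology alternative: the
left bone's 3D surface model is mirrored and rigidly superimposed onto the
right one, and the residual distance between the two surfaces quantifies
how plausible the pair is. It is aimed at forensic anthropologists and
bioarchaeologists working with CT- or scanner-derived surface models, and
at methodologists who want a fully scriptable, reproducible version of a
workflow usually run through GUI tools.

## The method

For a mirrored left model with vertices $x_i$ registered onto a right
model's surface $S$:

- **Coarse alignment**: the least-squares proper rigid transform (Kabsch)
  mapping three named anatomical landmarks — superior and inferior
  symphyseal points, most medial obturator-foramen point — onto their
  counterparts.
- **Fine registration**: iterative closest point. Repeat
  $y_i \leftarrow \arg\min_{y \in S} \lVert R x_i + t - y \rVert$ and
  $(R, t) \leftarrow \arg\min_{R \in SO(3),\, t} \sum_i \lVert R x_i + t - y_i \rVert^2$
  until the residual stabilises. The transform is always a proper rotation
  plus translation — shape only, never scale or reflection.
- **Similarity**: the RMS point-to-surface distance
  $\mathrm{RMS} = \sqrt{\frac{1}{n} \sum_i d_i^2}$ (mm), where $d_i$ is
  the distance from the $i$-th registered vertex to the fixed surface.
- **Decision**: in an all-against-all comparison of an assemblage, a pair
  is called a match iff its RMS is ≤ a threshold; `sweepThresholds()`
  recommends the zero-false-negative threshold with fewest false
  positives, and sensitivity/specificity, Mann–Whitney match-vs-mismatch
  testing and TEM/rTEM repeatability statistics summarise the sorting
  performance.

Because no real CT models are distributed, the package includes a
first-class synthetic generator (`generateAssemblage()`) producing
left/right shell pairs whose bilateral asymmetry (default 0.3 mm) is small
against between-individual variation (default 2.0 mm) — the variance
structure the method relies on.

## Worked example

```r
library(OsteoPair)

dir <- file.path(tempdir(), "demo")
cfg <- assemblageConfig(nPaired = 4, nUnpairedLeft = 1,
                        groups = c("m", "f"), seed = 42)
generateAssemblage(cfg, dir)   # writes meshes/, landmarks/, truth.csv, manifest.json

res <- runPipeline(dir)
res$m$classification
#> ClassificationReport at 0.1833 mm: tp=4 fp=0 tn=16 fn=0 | sensitivity 100.0%, specificity 100.0%
round(sort(matchRMS(res$m$matrix)), 3)
#> [1] 0.149 0.178 0.182 0.183
round(range(mismatchRMS(res$m$matrix)), 3)
#> [1] 1.233 1.765
signif(res$m$ranksum$p_two_sided, 3)
#> [1] 0.000413
```

Reading: the male group's 5 lefts × 4 rights give 20 superimpositions; the
four true pairs produce RMS residuals of 0.15–0.18 mm while the sixteen
mismatches sit at 1.2–1.8 mm, so the sweep-recommended threshold
(0.183 mm, the largest match RMS) separates them perfectly, and the
rank-sum test confirms the match distribution is significantly lower.

A single comparison, step by step:

```r
ind <- generateIndividual(7, cfg)
sup <- superimpose(mirrorMesh(ind$left), ind$right,
                   mirrorLandmarks(ind$leftLm), ind$rightLm)
sup$registration
#> RegistrationResult: 36 iterations (converged), final RMS 0.185414 mm
writeDistanceMap(sup$registered, sup$field, "map.ply")  # chromatic map
```

Real data enter through `readMesh()` (STL binary/ASCII, PLY) and
`readLandmarks()` (sidecar JSON); `hollowMesh()` strips interior
trabecular geometry from segmented shells before comparison. A thin
command-line front end is installed as `exec/osteopair`
(`osteopair simulate | mirror | hollow | register | distance | classify |
sweep | repeatability | pipeline`).

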