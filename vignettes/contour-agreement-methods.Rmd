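---
title: "Methods: 3D contour agreement analysis for ultrasound-guided radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D contour agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adaptive radiotherapy for cervical cancer needs the uterus outlined on 3D
transabdominal ultrasound at every treatment fraction. Semiautomated
segmentation tools can do this in minutes, but their output must be judged
against the only available truth: contours drawn by experts, whose own
mutual disagreement (interobserver variability) sets the bar an algorithm
has to meet. `uscontour` implements the evaluation machinery for this kind
of study: geometric agreement metrics between closed 3D contours, the
pairwise-comparison bookkeeping of a multi-observer cohort, image-quality
stratification, group statistics, and a fully synthetic cohort generator so
that every stage is testable without patient data.

All geometry lives in the patient frame (+x Left, +y Anterior, +z Superior),
coordinates in mm. A contour is a watertight triangle mesh: every edge
shared by exactly two faces, consistent outward winding, positive enclosed
volume.

## The four agreement metrics

For an ordered pair of contours $(A, B)$:

* **DC** — Euclidean distance between the *volume* centroids (mm). The
  centroid is the first moment of the enclosed volume, computed exactly
  from the surface by the divergence theorem; a vertex average would be
  biased wherever the tessellation is denser. 0 mm is perfect.
* **DSC** — Dice similarity coefficient $2|A \cap B| / (|A| + |B|)$.
  Volumes and overlap are realized on a voxel grid shared by both
  contours: a voxel belongs to a contour iff its center is inside the
  mesh (even-odd ray parity). 1 is perfect overlap.
* **MSSD** — directed mean surface-to-surface distance: the mean, over
  the vertices of $A$, of the distance to the nearest *vertex* of $B$
  (mm). Vertex-to-vertex is the definition used in the source study; a
  point-to-triangle variant is available (`mssd(..., target = "surface")`)
  for sensitivity analysis but is not the default. The accelerated
  spatial-index implementation returns bit-identical values to an
  exhaustive scan.
* **UM95** — the smallest uniform margin $m$ (mm) such that expanding $A$
  by $m$ contains at least 95% of the volume of $B$. Computed as the
  0.95-quantile (nearest rank, ceiling) of the Euclidean distance field of
  $A$ sampled at $B$'s occupied voxels; this is the minimal
  grid-realizable margin, so the coverage certificate
  $|B \cap \mathrm{expand}(A, m)| \ge 0.95\,|B|$ holds exactly.

DC and DSC are symmetric; MSSD and UM95 are directed and are recorded per
ordered pair. For algorithm-vs-manual pairs the algorithm contour is $A$.

### Numerical choices

* **Voxel spacing** defaults to 1 mm (isotropic); the organ measures tens
  of mm, so grid error is well below the spread of the metrics. The grid
  is the bounding box of both meshes padded by `max(5, 2*spacing)` mm so
  expansions never clip; the pad is recorded in the mask.
* **Distance fields** use the exact squared Euclidean distance transform
  (lower-envelope / parabola algorithm), matching a brute-force
  nearest-occupied-voxel scan to round-off.
* **Ray-parity voxelization** jitters the sample lattice by ~1e-6 of a
  voxel so rays through mesh edges or vertices are measure-zero; columns
  with an odd crossing count (degenerate geometry) drop the last crossing
  and raise a warning.
* **Ties/quantiles**: UM95 uses the nearest-rank (ceiling) quantile so the
  certificate above is exact; summary IQRs use linear interpolation
  (type 7), reported as a width (Q3 − Q1).

## Cohort pipeline

Images are rated twice on a 0–3 quality scale. An image rated 0 in either
session is excluded; otherwise the final rating is the session mean rounded
to the nearest integer. A mean of *k*.5 rounds **up** (1.5 → 2); the
convention is recorded in every report's provenance block.

Per retained image with $n$ manual contours and $s$ successful algorithm
contours, the pipeline evaluates all $n(n-1)$ ordered manual pairs (4
observers → 12) and the $s \times n$ algorithm-vs-manual cross product
(4 × 4 → 16). Failed segmentation attempts contribute no pairs but are
tallied in a failure ledger (counts and percentages to one decimal).
Summaries pool all pairwise records within each group (All Images /
Rating 1 / 2 / 3, per comparison kind) and report median [IQR]. Pooling is
the default because the study design feeds pairwise comparisons directly
into the group statistics; per-image aggregation is available
(`summarize_agreement(per_image = TRUE)`).

Group differences use the two-sided Wilcoxon rank sum test: exact
enumeration when both samples have ≤ 20 untied observations, the normal
approximation with tie correction otherwise. The three rating-group
pairings per metric are Bonferroni-corrected by a factor 3 (capped at 1);
the overall algorithm-vs-manual comparison on all images is uncorrected.
Significance is declared at adjusted p < 0.05.

A known caveat: pooled pairwise records are clustered (12 manual records
derive from only 4 contours), so the rank-sum test on pooled records is
mildly anticonservative under the null — in the synthetic world we measure
per-metric rejection rates of roughly 6–12% at nominal 5%. Conclusions that
hinge on borderline p-values should be checked with per-image aggregation.

## The synthetic cohort

The generator emulates the *structure* of a real study — it is a stated
world calibrated to reported scales, not a model of patient statistics.

* **True shapes**: a superellipsoid body (exponent 2.5,
  anterior-posterior axis 0.9 of the transverse axis) blended with an
  ellipsoidal cervical tube by a smooth maximum of the two radial maps on
  an icosphere parameterization. Both lobes are star-shaped, so the union
  is watertight and self-intersection-free by construction. Anteversion
  is a cylindrical bend of the long axis toward anterior; its Jacobian is
  linear in the bending coordinate, so volume is preserved to first order
  (measured < 0.1% at 45°). Default parameter ranges (body length 60–100
  mm, fundal width 30–60 mm, cervix length 20–35 mm, radius 8–15 mm,
  anteversion 0–90°) give volumes of roughly 35–210 cm³, inside the
  plausible 30–300 cm³ organ range.
* **Manual contours**: vertices displaced along outward normals by a
  smooth random field — spherical harmonics to degree 6 with a Gaussian
  degree-weighting set by a correlation length (default 25 mm) —
  normalized to RMS `sigma_obs` and boosted (×1.8) at the lateral edges
  and cervix base, where experts disagree most. `sigma_obs = 2.6` mm was
  calibrated once so the cohort median manual-manual MSSD lands near the
  reported interobserver scale (≈ 3.2 mm; the generator gives ≈ 3.4 mm).
  `calibrate_sigma()` exposes the calibration map (monotonized by a
  running maximum, because nearest-vertex distances saturate at high
  amplitude).
* **Algorithm contours**: per attempt, Bernoulli failure with
  rating-dependent probability (defaults 0.5 / 0.2 / 0 for ratings
  1 / 2 / 3 — expected overall failure ≈ 19% under the default 6/18/11
  rating mix; the 1-vs-2 split is a free parameter, only "failures occur
  on degraded images" is fixed). Successes are corrupted by the same kind
  of smooth field at rating-dependent amplitude (defaults 6.5 / 4.5 /
  2.6 mm — rating-3 equal to the observers, so excellent images are
  statistically indistinguishable from experts), plus a Poisson number of
  thin radial spikes (length 20 mm, angular width 0.05 rad) emulating
  shadow- and speckle-driven artifacts. Each spike deflects the contour
  outward or inward with equal probability: shadowing pulls a
  gradient-based contour to either side of the boundary, and the random
  sign keeps the artifacts centroid-neutral in expectation — which is what
  makes DC and DSC insensitive to them while MSSD and UM95 respond, the
  qualitative signature the evaluation is designed to detect.
* **Reproducibility**: every artifact's seed is derived from the master
  seed by a counter scheme (`image`, `observer`, `role`), so any subset
  regenerates bit-exactly in isolation and two runs with the same seed
  produce identical manifests.

What a green test establishes: the bookkeeping, metric engine and
statistics behave correctly on contours whose error structure (smooth
fields, thin artifacts, quality-dependent failure) mimics the study's
qualitative findings. What it does not establish: anything about real
ultrasound image quality, real observer bias (the synthetic observers are
unbiased, so synthetic DC runs lower than reported interobserver DC), or
the behavior of any particular segmentation algorithm.

## Design choices where the design was open

* **MSSD/UM95 direction**: reported per ordered pair, directed (12 ordered
  manual pairs per image implies directed values are recorded twice per
  unordered pair); a symmetrized mean is an option, not the default.
* **Comparison grid**: contours of one image share one voxel grid; each
  source contour's distance field is computed once and reused across its
  pairs. Resolution is configurable; results at 0.5–2 mm differ by less
  than the reported IQRs.
* **Quality-rating rounding**: round half up. The alternative
  (round-half-even) changes only images rated (1,2) or (2,3); the choice
  is recorded in output provenance.
* **UM95 for a pair with an empty target mask** is an error
  (degenerate resolution), not 0 or NA: it means the grid cannot represent
  the contour and the spacing must be refined.
* **Reported UM95 for the source study**: the study's own tables print two
  different overall manual UM95 medians in different places (4.40 vs
  4.04 mm). The pipeline computes one number; the discrepancy in the
  source is documented here and left unresolved.

## Limitations

* Meshes must be closed 2-manifolds; repair is limited to winding
  (orientation) fixes on read. No DICOM-RT, no non-isotropic grids.
* The rank-sum clustering caveat above.
* Vertex-to-vertex MSSD depends on tessellation density; meshes compared
  against each other should be of comparable resolution (the generator's
  are). The `target = "surface"` variant removes this dependence at the
  cost of departing from the study definition.
* Thin-spike artifacts below the mesh edge length are realized as
  single-vertex needles; their volume floor is the one-ring tent.
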