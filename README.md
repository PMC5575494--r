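# uscontour

Contour agreement analysis for 3D ultrasound organ segmentation.

## What this is for

In ultrasound-guided adaptive radiotherapy for cervical cancer, the uterus
must be re-outlined on 3D transabdominal ultrasound at treatment time. A
semiautomated segmentation tool is clinically acceptable only if its
contours agree with expert manual contours about as well as the experts
agree with each other — interobserver variability is the benchmark.
`uscontour` is an R package for running exactly this kind of evaluation:

* **Geometry**: watertight triangle-mesh contours (mm, patient frame
  +x Left / +y Anterior / +z Superior), exact enclosed volume and volume
  centroid, point-in-mesh voxelization, exact Euclidean distance
  transforms, uniform margin expansion.
* **Agreement metrics** for an ordered contour pair (A, B):
  - `dc(a, b)` — distance between volume centroids (mm),
  - `dsc(a, b)` — Dice similarity coefficient 2|A∩B|/(|A|+|B|),
  - `mssd(a, b)` — directed mean of nearest-vertex surface distances (mm),
  - `um95(a, b)` — smallest uniform expansion of A covering ≥ 95% of B's
    volume (mm),
  plus `deviation_map()` per-vertex disagreement heatmaps (PLY export,
  10 mm display clamp).
* **Cohort pipeline**: two-session 0–3 image-quality ratings with
  exclusion (any 0) and mean-round-half-up finalization; enumeration of
  the n(n−1) ordered manual pairs and AGS×manual cross-product pairs per
  image; segmentation-failure ledger; median [IQR] summaries by quality
  group; Wilcoxon rank-sum group statistics with Bonferroni correction.
* **Synthetic cohort generator**: seeded uterus-like shapes
  (superellipsoid body + cervical tube, anteverted), observer-perturbed
  manual contours (spherical-harmonic fields calibrated to a ~3.2 mm
  interobserver MSSD scale), and quality-dependent semiautomated contours
  with Bernoulli failures (~19% overall) and thin spike artifacts — so the
  whole pipeline is testable end to end with no data download.

## Worked example

Simulate a small cohort (6 retained images, ratings 1/2/3 in a 2/2/2 mix,
4 observers), evaluate every contour pair, and compare the semiautomated
(AGS-style) contours against interobserver variability:

```r
library(uscontour)

cfg <- cohort_config(n_retained = 6, rating_mix = c(2, 2, 2), n_excluded = 2)
man <- generate_cohort(cfg, master_seed = 5)
res <- evaluate_cohort(man)   # 1 mm grid, 95% coverage

res$failures
#> AGS attempts: 24 (6 images x 4 observers): 19 succeeded (79.2%), 5 failed (20.8%)

summ <- summarize_agreement(res$records, res$ratings)
subset(summ, group == "All Images")
#>       metric      group             kind median iqr_width n_pairs
#> 1    DC (mm) All Images manual_vs_manual  4.262    3.4338      72
#> 2        DSC All Images manual_vs_manual  0.797    0.0598      72
#> 3  MSSD (mm) All Images manual_vs_manual  3.385    0.3833      72
#> 4  UM95 (mm) All Images manual_vs_manual  4.123    1.5607      72
#> 17   DC (mm) All Images    ags_vs_manual  3.540    3.4654      76
#> 18       DSC All Images    ags_vs_manual  0.755    0.0971      76
#> 19 MSSD (mm) All Images    ags_vs_manual  4.109    1.6140      76
#> 20 UM95 (mm) All Images    ags_vs_manual  4.899    2.4228      76

subset(compare_ags_manual(res$records, res$ratings), group == "All Images")
#>       metric      group n_manual n_ags    p_raw    p_adj significant skipped
#> 1    DC (mm) All Images       72    76 0.510560 0.510560       FALSE   FALSE
#> 5        DSC All Images       72    76 0.000138 0.000138        TRUE   FALSE
#> 9  MSSD (mm) All Images       72    76 0.000236 0.000236        TRUE   FALSE
#> 13 UM95 (mm) All Images       72    76 0.003742 0.003742        TRUE   FALSE
```

Reading the output: the 12 manual pairs per image give the interobserver
baseline (median MSSD 3.39 mm, DSC 0.80). The simulated algorithm fails on
5 of 24 attempts (all on degraded images) and, pooled over all image
qualities, is significantly worse than the experts on the shape-sensitive
metrics (DSC, MSSD, UM95) but indistinguishable on centroid position (DC) —
the qualitative signature of a tool whose centroid is fine but whose shape
degrades with image quality. `write_report(res, "out/")` writes the records,
summary and statistics tables as CSV, the failure ledger, a provenance
block, and per-metric boxplots (shaded manual vs white AGS, grouped by
rating).

A command-line front end covers the same flow
(`simulate`, `evaluate`, `summarize`, `stats`, `report`):

```sh
Rscript inst/cli/uscontour simulate --out cohort/ --seed 5
Rscript inst/cli/uscontour evaluate --manifest cohort/manifest.json --out report/
```

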