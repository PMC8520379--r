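# endostitch

Feature-based mosaicking of endoscopic image pairs, built around two cheap
geometric mismatch filters, plus a worked example reproducing the
descriptive statistics of a 111-patient gastric-polyp cohort.

## What it does

Endoscopy shows small, overlapping, unevenly lit views of the gastric
mucosa; stitching consecutive frames gives a wider and steadier view of a
lesion. `endostitch` implements the full pipeline in R:

1. **Scale space** — Gaussian pyramid (σ₀ = 1.6, 3 intervals/octave,
   k = 2^(1/3)) and difference-of-Gaussians stacks with reflective-boundary
   blurring.
2. **Keypoints** — strict 26-neighbourhood DoG extrema, 3-D quadratic
   refinement, contrast (0.03) and curvature-ratio (r = 10) tests, 36-bin
   orientation histograms, 128-D gradient-histogram descriptors.
3. **Matching** — nearest-neighbour ratio test (0.8), one-to-one.
4. **Mismatch filtering**, the method's core:
   * *slope pre-check*: in a side-by-side composite frame, every match line
     gets a slope `k = (y' − y) / ((x' + W) − x)`; the slope whose
     t-neighbourhood (t = 0.02) contains the most matches wins and only
     matches inside it survive;
   * *disparity-gradient constraint*: with disparities d and cyclopean
     midpoints c, `g(m,n) = ‖d(m) − d(n)‖ / ‖c(m) − c(n)‖` must be
     strictly below 2 (median over each match's 4 nearest neighbours).
5. **Model + mosaic** — seeded RANSAC homography (normalized DLT, symmetric
   transfer error, consensus refit) and feather-blended warping.

A seeded synthetic-fixture generator (`generate_pair()`) provides
endoscopic-like frame pairs with exact ground-truth transforms,
correspondences and controllable injected mismatches, so every stage is
benchmarked without any external data.

## Worked example

```r
library(endostitch)

pair <- generate_pair(fixture_preset("easy", seed = 1))  # 256x256, 2° + (30,10) px
res  <- stitch_images(pair$frame_a, pair$frame_b)

res$model
#> homography_model (projective): 62/62 inliers, RMS 0.106 px
#>          [,1]      [,2]      [,3]
#> [1,] 1.000188 -0.034653 34.489575
#> [2,] 0.035402  1.000501  5.511416
#> [3,] 0.000002  0.000002  1.000000

res$report$counts
#> $retained: 62   $rejected_slope: 0   $rejected_disparity: 12

res$mosaic
#> mosaic: 270 x 291 canvas, origin shift (-35, -14), 55445 blended px
```

The recovered matrix is the estimated source→target homography: the
off-diagonal ±0.035 terms are the 2° rotation, the last column the ~(34, 6)
px effective translation of this seed's transform. Of 74 coarse matches, 12
were rejected by the disparity-gradient filter and 62 survived; all 62 were
RANSAC inliers with 0.106 px RMS residual, and the corners of the true
transform are reproduced to 0.047 px. The mosaic canvas is the union
bounding box of both frames with feather-blended overlap.

The cohort example:

```r
marginal(cohort_table("age"), "columns")
#>            label count percent
#>     hyperplastic    45    40.5
#>     inflammatory    37    33.3
#>     fundic_gland     6     5.4
#>      metaplastic     2     1.8
#>        hamartoma     1     0.9
#>      adenomatous     4     3.6
#>   gastric_cancer    16    14.4
```

## Command line

A thin wrapper lives at `inst/scripts/endostitch.R`:

```sh
ES=$(Rscript -e 'cat(system.file("scripts/endostitch.R", package="endostitch"))')
Rscript $ES stitch a.png b.png -o mosaic.png --slope-t 0.02 --dg-max 2 \
        --seed 17 --report report.json
Rscript $ES make-fixtures --out fx --seed 1 --preset easy
Rscript $ES evaluate --fixture fx
Rscript $ES cohort --table age
```

## Layout

- `R/` — scale space, keypoints/descriptors, matching + filters, homography,
  stitcher, fixture generator, cohort summaries, CLI.
- `inst/extdata/` — the three cohort tables (CSV).
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles.
- `vignettes/endoscopic-mosaicking.Rmd` — models, parameter rationale,
  generator scope and limitations.
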