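# splenotex

Quantitative 3-D texture and volumetry analysis for optical computed
tomography (optical CT) image volumes of murine spleen.

Optical CT of optically cleared tissue, acquired at haemoglobin-absorbing
wavelengths, images the whole spleen in 3-D: blood-rich red pulp appears
bright, white-pulp nodules dark, and the marginal zone in between at
intermediate intensity. Drugs that disrupt established vasculature (e.g.
vascular disrupting agents) shrink the organ and its internal structures;
`splenotex` provides the analysis chain to detect and quantify such
changes: organ volumetry from sparse contours, and grey-level
co-occurrence texture statistics that are sensitive to the length scales
of internal structure. Because conventional 2-D slice-based texture
analysis is strongly slice-dependent, the core statistic is a
**three-reference-point 3-D grey-level co-occurrence matrix (GLCM)**.

## The statistic

For a displacement of `d` pixels at angle `θ`, integer offsets are

    Δx = Δz = round(d cos θ),   Δy = round(d sin θ).

For every voxel `(x, y, z)` of a quantised volume `I`, the grey levels

    i = I(x, y, z),  j = I(x + Δx, y + Δy, z),  k = I(x, y + Δy, z + Δz)

are counted into a three-way tensor `P_{d,θ}(i, j, k)` (unsymmetrised,
out-of-bounds triples skipped, normalised over valid triples, averaged
over θ ∈ {0°, 45°, 90°, 135°}). Two Haralick-style features summarise it:

    contrast    = Σ P(i,j,k) [ (i−j)² + (i−k)² + (j−k)² ]
    homogeneity = Σ P(i,j,k) / [ 1 + (i−j)² + (i−k)² + (j−k)² ]

Swept over `d`, contrast peaks near the characteristic length scale of
the tissue texture; the peak's displacement (refined to sub-pixel
precision by a quadratic fit) shifts to smaller `d` when internal
structures contract.

The package also implements the surrounding workflow:

* **phantom** — synthetic spleen generators with full ground truth:
  2-D three-level feature images (node 0, marginal zone 128, red pulp
  255) and 3-D ellipsoidal organs with white-pulp nodules, marginal-zone
  shells, bright vessels, Gaussian noise and streak artifacts, plus
  vehicle/treated cohort generation (treated: linear scale 0.896, i.e.
  ~28% volume loss).
* **volume_io** — multi-page TIFF, NIfTI-1 and image-directory volume
  I/O with a fixed `(z, y, x)` axis convention; CSV tables.
* **preprocess** — ROI extraction, linear 8-bit scaling, per-ROI
  histogram equalisation, width-3 median filter (Rcpp).
* **volumetry** — automatic keyframe contouring (Otsu threshold with an
  artifact intensity cap, largest component, hole filling), contour
  interpolation by signed-distance blending, voxel-count volumetry.
* **stats** — exact one-tailed Mann–Whitney U tests by complete
  enumeration (with n = 3 per group the smallest attainable one-tailed
  p is exactly 1/C(6,3) = 0.05), group mean curves and separation
  ranges, peak-displacement summaries, percent change.
* **pipeline** — `run_pipeline()` (cohort → preprocessing → texture →
  volumetry → statistics → report) and `reproduce_fig6()` (the 2-D
  feature-image simulation study).

## Worked example

```r
library(splenotex)
report <- run_pipeline(default_pipeline_config())
print(report)
```

```
Spleen texture/volumetry pipeline report
  seed 1, config hash 1e439846
  sample_id   label volume_mm3 peak_contrast_d
1        V1 vehicle   9.274715        22.60806
2        V2 vehicle   9.269002        17.08726
3        V3 vehicle   9.270953        26.50601
4        T1 treated   6.641601        15.32510
5        T2 treated   6.641918        18.54927
6        T3 treated   6.636047        17.50180
  volume ratio (treated/vehicle) = 0.7162; shrinkage 28.4% (means), 28.4% (medians)
Exact Mann-Whitney U test (one-tailed, 'greater')
  n = 3 vs 3, U = 9, p = 0.05 (over 20 assignments)
<separation_report> contrast: groups vehicle vs treated, separated at 17/40 displacements
  separated runs: [20, 26] [28, 37]
<separation_report> homogeneity: groups vehicle vs treated, separated at 0/40 displacements
  3-D contrast peak displacements:
  vehicle: peak d = 22.067 +/- 4.733 px (sd, n = 3)
  treated: peak d = 17.125 +/- 1.645 px (sd, n = 3)
  physical difference: 128.5 um
```

Reading the report: six phantom spleens (three per cohort) are measured
by keyframe-contour volumetry — the treated organs come out at 72% of
the vehicle volume (the generator's ground truth is 0.896³ ≈ 0.72), and
with complete separation of two groups of three the exact one-tailed
Mann–Whitney p-value is 0.05, the smallest value the design can attain.
The 3-D contrast curves separate the cohorts over a range of
displacements, and the group-mean contrast peak sits at smaller
displacement in the treated cohort — its internal structures are smaller
— here a shift of ~4.9 px (~128 µm at 26 µm voxels).

The 2-D simulation study isolates the two geometric drivers of those
texture changes:

```r
print(reproduce_fig6())
```

```
  sim i  : peak contrast 1.046e+04 at d = 24.58
  sim ii : peak contrast 7607 at d = 24.79
  sim iii: peak contrast 3.479e+04 at d = 34.26
  sim iv : peak contrast 3.105e+04 at d = 31.75
  smaller features peak at smaller d: TRUE
  thicker marginal zone lowers peak contrast: TRUE
```

A command-line wrapper for both is installed at
`inst/cli/splenotex.R` (`Rscript splenotex.R run --seed 1 --outdir out/`).

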