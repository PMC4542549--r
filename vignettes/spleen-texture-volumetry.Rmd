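---
title: "Three-point 3-D co-occurrence texture and keyframe volumetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-point 3-D co-occurrence texture and keyframe volumetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splenotex)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter and their defaults, what the
synthetic phantoms do and do not emulate, the numerical conventions,
and the known limitations. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Scientific setting

Optical CT of optically cleared murine spleen, acquired at wavelengths
where haemoglobin absorbs strongly, yields 512³-voxel volumes in which
blood-rich red pulp (RP) is bright, white-pulp (WP) nodules are dark,
and the marginal zone (MZ) around each nodule is intermediate; blood
vessels are very bright, and reconstruction can add bright streak
artifacts. Treatment with a vascular disrupting agent contracts the
organ (~28% volume loss) and its internal structures. Two quantitative
questions follow: *how large is the organ* (volumetry) and *how is its
internal texture organised across length scales* (co-occurrence
texture). Both are answered here on synthetic phantoms with known
ground truth, because the original scans are not publicly deposited;
the phantom generator is therefore a first-class, tested component.

## The three-reference-point 3-D GLCM

A standard 2-D grey-level co-occurrence matrix counts ordered pairs
`(I(x, y), I(x+Δx, y+Δy))` at a fixed displacement. Applied per slice,
it inherits the arbitrariness of the slice choice — a single slice
cannot represent the organ's 3-D architecture, and the pipeline
therefore emits per-slice 2-D curves alongside the 3-D ones so the
dependence can be inspected. The 3-D statistic reduces it by adding a
third reference point displaced in depth. For displacement `d` and
angle `θ`,

\[ \Delta x = \Delta z = \mathrm{round}(d\cos\theta),\qquad
   \Delta y = \mathrm{round}(d\sin\theta), \]

and each voxel contributes the grey-level triple

\[ i = I(x,y,z),\quad j = I(x+\Delta x,\, y+\Delta y,\, z),\quad
   k = I(x,\, y+\Delta y,\, z+\Delta z). \]

The tensor of triple counts, normalised over the triples that fall
entirely inside the volume, is `P_{d,θ}(i,j,k)`; matrices are averaged
over `θ ∈ {0°, 45°, 90°, 135°}` and summarised by

\[ \text{contrast} = \sum P\,[(i-j)^2 + (i-k)^2 + (j-k)^2], \qquad
   \text{homogeneity} = \sum \frac{P}{1 + (i-j)^2 + (i-k)^2 + (j-k)^2}. \]

Numerical conventions, each of which was a genuine design choice:

* **Offset rounding.** `d cos θ` is not an integer at the diagonal
  angles; components are rounded half away from zero. A "chessboard"
  alternative (`Δ = ±d` on both axes at 45°/135°) is available via
  `convention = "chessboard"` because the literature is not unanimous;
  the literal rounding is the default.
* **θ = 135°** gives negative `Δx = Δz`; it is applied literally, with
  out-of-bounds triples skipped (no padding, no wrapping — padding
  invents intensities).
* **θ = 90°** makes the second and third points coincide
  (`Δx = Δz = 0`), so that angle's tensor is degenerate with all mass
  on `j = k`; the identity `contrast3d = 2 × contrast2d` there is a
  tested invariant. The angle is retained in the default set for
  fidelity to the four-angle average.
* **Normalisation** divides by the valid-triple count, which is what
  makes homogeneity's (0, 1] range and the probability interpretation
  hold; unnormalised tensors are rejected by the feature functions.
* **No symmetrisation**: the statistic is directional; only angle
  averaging is performed.
* **Averaging order.** Both features are linear in `P`, so the feature
  of the angle-averaged matrix equals the average of per-angle
  features. The displacement-sweep code exploits this to stream over
  triples without materialising the `Ng³` tensor (for `Ng = 256` that
  tensor has 2²⁴ cells); `average = "feature"` is exposed for
  completeness and is exactly equal.
* **Grey depth.** `Ng` defaults to 256 (an 8-bit 2-D GLCM has 2¹⁶
  elements). Requantisation to smaller `Ng` rebins 0..255 linearly —
  except that inputs whose values already fit 0..Ng−1 are used as
  levels directly, so small test volumes keep their exact levels.
* **Peak localisation.** The sweep samples integer `d` (default 1..40,
  covering the length scales of interest); an interior argmax is
  refined by the vertex of the quadratic through the three surrounding
  points, which yields the fractional peak displacements reported
  (e.g. a shift of ~2 px at 10.4 µm voxels is ~21 µm); a peak at the
  sweep boundary is flagged and left unrefined.

Correctness is anchored by brute-force oracles: an independent
triple-loop enumeration must agree exactly with the implementation on
random volumes up to 10×10×6 at `Ng ≤ 8`, and the feature sums must
match dense triple-loop summation.

## Preprocessing

Each sample contributes one region of interest (ROI), preprocessed as:
linear scaling to 8-bit (`round(255·(v−min)/(max−min))`, half-up;
constant input maps to zero), per-ROI histogram equalisation
(`round(255·(cdf−cdf_min)/(N−cdf_min))`), and a width-3 median filter.
Points of note:

* Equalisation is **per ROI**: it preserves intra-sample contrast in
  the presence of very bright artifacts, at the cost of inter-sample
  comparability of absolute grey values (recorded in provenance).
* Equalisation can amplify noise, so the **median filter runs after
  it** by default; the order is a configuration switch because the
  alternative is defensible.
* The median filter matches the data dimensionality (3×3×3 cube on
  volumes, 3×3 on single slices), truncates windows at boundaries
  rather than padding, and uses the lower median for even-sized
  truncated windows — consequently it never introduces a value absent
  from the window. It is implemented in C++ for speed and verified
  against a gather-and-sort oracle.
* ROI placement: automatic placement centres the ROI on the mask
  centroid and shifts it minimally to stay inside the volume. The
  pipeline default ROI is 64×64×20 voxels: it must sit **interior** to
  the organ, because an ROI crossing the organ boundary lets the
  organ/background edge dominate long-range contrast and pushes the
  peak toward the sweep limit. (The study-scale analogue, a 200×200×30
  ROI inside a 512³ organ, satisfies the same interiority condition.)

## Volumetry

The organ is outlined on keyframe slices — anchored at the first and
last slices intersecting the object, then every `slice_step` slices
(default 20), with the final partial interval interpolated over its
actual gap — and intermediate slices are filled by linearly blending
the signed distance transforms (negative inside) of the bracketing
keyframe regions, thresholded at zero. Volume is the voxel count times
the voxel volume, e.g. (26 µm)³ = 1.7576×10⁻⁵ mm³.

Keyframe outlining is automatic: per-slice Otsu threshold — estimated
on the values **below** the artifact cap (the `artifact_percentile`
within-slice quantile, default 99.9), so a bright streak cannot drag
the threshold above tissue — then the largest connected component,
hole filling, and boundary tracing. Externally drawn polygons can be
supplied as JSON instead, mirroring a manual workflow. Rasterisation
uses the even-odd rule with one refinement: vertices lying exactly on
pixel centres are filled, so a traced boundary chain rasterises back
to its source component exactly, while analytic polygons (whose
vertices essentially never hit pixel centres) are unaffected.

SDF interpolation has two useful exact properties, both tested: equal
keyframes reproduce themselves on every intermediate slice, and any
region contained in both keyframes is contained in every interpolated
slice. Its accuracy is governed by the keyframe spacing *relative to
the organ height*: the study outlined ~400-slice organs every 20
slices (5% of the height). On an elongated phantom (~130 occupied
slices) the suite verifies error below 5% at a 7.5% spacing and below
2% at a 4% spacing, with monotone decay; desk-scale phantoms are
shorter than the study's organs, so the same relative sampling is
reached at proportionally smaller steps. Cohort *ratios* are more
accurate still, because the discretisation bias largely cancels
between groups.

## The phantom generator

The generator emulates the labelled anatomy of the scans: an
ellipsoidal organ of bright red pulp (intensity 1.0 in arbitrary
attenuation units), dark white-pulp nodules (0.15) wrapped in
intermediate marginal-zone shells (0.55) — the ordering rp > mz > wp is
enforced, since blood-rich tissue is bright — very bright vessel tubes
(1.35), additive Gaussian noise (sd 0.04) applied before quantisation,
and full-field bright streak lines (intensity +2.5) emulating
reconstruction artifacts. Nodules are placed by rejection sampling
with a minimum separation so shells never merge; placement failure
after bounded retries is an error reporting the achieved count.
Ground truth records the noiseless label volume, the spleen voxel
count (tissue labels: RP/MZ/WP/vessel — streaks outside the organ are
labelled separately and not counted as organ), and nodule geometry.

Default scale is a 128³ grid with semi-axes (52, 44, 56) voxels,
16 nodules of radius 7 ± 1.2, shells 3 voxels thick — a desk-scale
stand-in for the study's 512³ scans chosen so the full 3 vs 3 pipeline
runs in well under a minute. The treated cohort applies
`cohort_scale = 0.896` to organ and features (0.896³ ≈ 0.72, i.e. 28%
volume loss) and an additional `feature_scale = 0.9` to nodule radius
and shell thickness, expressing the hypothesis that marginal zones
contract under treatment. Cohort generation derives per-sample seeds
from one base seed and is bitwise reproducible.

What the phantoms do **not** emulate: optical physics (scattering,
refractive-index mismatch), clearing-induced differential shrinkage,
projection-space reconstruction (phantoms are built directly in
reconstructed-volume space), irregular organ shape, and spatially
correlated noise. Passing tests therefore demonstrate that the
*analysis chain* recovers known geometry and group differences under
controlled conditions — not that it would be robust to every
real-data pathology.

## The 2-D simulation study

Four single-slice feature images isolate the geometric drivers of the
texture statistics. Each has four features on a 2×2 grid: a node disc
(level 0) inside a marginal-zone annulus (level 128) on a red-pulp
background (the nominal level 256 is clamped to the 8-bit maximum 255
and the clamp recorded). Disc membership is centre-of-pixel Euclidean
distance, boundary inclusive. The four cases cross total feature size
with marginal-zone share: the feature's *outer* radius is fixed per
size class (defaults 10 and 20 px in a 120 px image) and the node
radius is `outer − mz` (mz defaults 2 and 4 px) — the marginal zone
grows at the expense of the node, holding the feature footprint fixed,
which is the reading of "varying the ratio of marginal zone area
within each feature" consistent with both qualitative laws. The exact
radii of the original simulations are not printed anywhere, so these
defaults are this package's choice, made once: features nearly fill
the frame, as in the published simulation images, which is what places
the contrast peaks inside the displacement sweep. The two laws —
smaller features shift peak contrast to smaller displacement; a larger
marginal-zone share lowers peak contrast — are asserted by the
acceptance suite, not assumed.

## Statistics

With three animals per group, asymptotic rank tests are meaningless;
the exact one-tailed Mann–Whitney U test enumerates all
`choose(nA+nB, nA)` group assignments of the (mid)ranked pooled data.
Tie handling keeps midranks inside the permutation distribution.
Consequences verified by the suite: tie-free p-values are multiples of
`1/choose(n, nA)`; complete separation at 3 vs 3 gives exactly
p = 0.05; and the implementation agrees with `stats::wilcox.test`'s
exact path on tie-free data. Enumeration is restricted to 20
observations; larger samples are out of scope.

Group curves report per-displacement means and *complete separation*
(one group's maximum below the other's minimum — a deliberately
conservative, assumption-free criterion), as maximal runs of
displacements. Peak summaries report per-group mean and sample SD
(SEM available; the spread convention for the published "± " values
is not stated, so SD was chosen as the default), plus the physical
shift `(mean₁ − mean₂) × voxel size`. Percent change is
`100·(ref − cmp)/ref`, reported for both means and medians since the
published text mixes the two.

## Pipeline and reproducibility

`run_pipeline()` executes cohort generation → ROI preprocessing → 3-D
(and per-slice 2-D) texture curves → volumetry → statistics, from one
configuration object (or YAML/JSON file) and one seed. The problem
sizes in the default configuration — 128³ phantoms, 64×64×20 ROI,
`Ng = 64`, `d = 1..40`, `slice_step = 10` — are the package's chosen
desk-scale study conditions; every report embeds the resolved
configuration, the seed, and a content hash of the configuration, and
re-running with the same inputs is byte-identical. Blinding, which a
human analysis would require, has no algorithmic counterpart; the
pipeline instead logs every convention in effect.

## Known limitations

* The human quality-control step of the original volumetry ("minor
  adjustments where necessary") has no algorithmic counterpart; the
  automatic contours go unreviewed.
* Measured volumes of cleared tissue may not map linearly to in-vivo
  volumes (clearing shrinks tissue); no correction is attempted.
* Per-ROI equalisation sacrifices absolute intensity comparability
  across samples by construction.
* JPEG slice input is accepted for workflow fidelity but is lossy;
  it is flagged in provenance.
* Exact tests are limited to 20 observations; no multiple-testing
  correction is applied across displacements (none was applied in the
  original analysis either).
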