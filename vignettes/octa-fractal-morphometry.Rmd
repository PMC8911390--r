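---
title: "Fractal morphometry of OCT-A neovascular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal morphometry of OCT-A neovascular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octafract)
```

# The measurement problem

En-face OCT angiography renders perfused vasculature as a grayscale slab.
For choroidal neovascular lesions complicating central serous
chorioretinopathy — type 1 networks and polypoidal choroidal vasculopathy
(PCV) — four scalar biomarkers summarize the lesion: its area (mm²), the
vascular perfusion density (VPD), the box-counting fractal dimension (FD,
a global index of branching complexity), and the gliding-box lacunarity
(LAC, an index of structural non-uniformity or "gappiness"). `octafract`
computes all four from a grayscale slab plus one physical calibration, the
isotropic pixel scale in mm/pixel, which is always supplied explicitly by
the operator (device metadata dialects are too unreliable to parse, and
the scale is a deliberate operator decision when mixing devices).

The pipeline assumes a single dominant lesion per slab, approximately
stationary speckle, and intensity units where vessels are brighter than
background. It does not attempt projection-artifact removal, vesselness
filtering, or multi-lesion segmentation.

# Binarization

`otsuThreshold()` builds a 256-bin histogram over the *observed* intensity
range (256 bins matches 8-bit exports exactly; 16-bit data are binned, and
the threshold is reported on the native scale — an 8-bit image scaled into
the 16-bit range yields the identically scaled threshold). Between-class
variance is computed from the exact per-bin intensity sums, not bin
centers, so for 8-bit data the selected cut is identical to exhaustive
search over all integer cut points — the test suite asserts this against a
brute-force oracle on 100 random images. Ties are broken toward the lower
threshold for determinism. The returned threshold is the largest intensity
assigned to background, and the mask is `intensity > threshold`. A
constant image has no threshold and is a degenerate-input error (in batch
mode it becomes an error record and the batch continues).

Despeckling follows binarization, in the order the clinical protocol
states: `medianDespeckle()` applies a majority vote over a *disk* of
radius 2 px ("radius" is read literally; a square window is available via
`squareMedian` for comparison, and a pre-threshold grayscale median via
`grayscaleMedian`). Borders are handled by symmetric reflection. On a
binary image a median filter is exactly a majority filter; the disk of
radius 2 contains 13 pixels, so no tie is possible. Finally,
`removeSmallComponents()` deletes connected components under 10 px
(8-connectivity by default — vessel strands connect diagonally; the
4-connected variant is a config switch). Defaults (radius 2, minimum 10)
are the published processing parameters.

# Lesion localization, area and VPD

`densityMap()` computes the local foreground fraction in a `k × k` window
(default `k = 15` px: large relative to residual speckle, small relative
to a lesion; exposed as `densityKernelPx`). `highestDensityZone()`
thresholds the map at half its maximum (`zoneLevel = 0.5`; there is no
published rule for delimiting the zone, so the level is a documented,
configurable choice) and keeps the connected component containing the
density argmax (first maximum in column-major order on ties). Lesion area
is that region's pixel count × (mm/px)².

VPD is the perfused-pixel fraction of a region of measurement. The
published VPD value ("0.52 ± 0.20%") is not consistent with any
fraction-of-area reading — a within-lesion perfused fraction is orders of
magnitude larger — so this package reports a plain fraction in [0, 1] and
makes no attempt to reproduce that magnitude. The normalization region
defaults to the whole analyzed slab, with `vpdRegion = "lesion"`
switching to the density zone; both conventions are exposed precisely
because the published normalization is not recoverable.

# Skeletonization

`skeletonize()` uses sequential topology-preserving thinning: border
pixels are peeled in four rotating directional subcycles (N, E, S, W).
Candidates are frozen at the start of each subcycle, so at most one
boundary layer is removed per direction per pass, and each deletion
re-tests the pixel at deletion time against a precomputed simple-point
table (a pixel is deletable only if removal preserves both 8-connected
foreground and 4-connected background topology of its 3×3 neighborhood);
endpoints (≤ 1 foreground neighbor) are kept. This gives three guarantees
the test suite asserts on hundreds of random masks: the skeleton is a
subset of its mask, 8-connected component count is exactly preserved, and
the operation is idempotent. No specific thinning algorithm is mandated by
the clinical protocol; different thinning variants shift FD slightly, so
the variant here is pinned by golden tests (a 3-px bar thins to its
centerline, a filled disk to ≤ 5 central pixels). Skeleton length is
reported as pixel count × scale (the √2 diagonal correction is available
behind a flag but no downstream metric consumes length).

# Box-counting FD at multiple origins

For box size `r`, the plane is tiled with `r × r` boxes and boxes
containing ≥ 1 skeleton pixel are counted. A single grid placement biases
the count, so counts are averaged over a deterministic stratified lattice
of `min(r², 16)` origin offsets in `[0, r)²` (the mean varies smoothly
with the pattern; the more conservative minimum over origins is available
as `originMode = "min"`). Origin shifts are applied *circularly*
(periodically): a padded shift systematically inflates counts at large
`r` — enough to bias the estimated dimension of a filled square well below
2 — whereas circular shifts make the count exactly translation-unbiased,
which is the point of using multiple origins in the first place.

`fractalDimension()` fits ordinary least squares to `log N(r)` vs
`log r` over the whole configured ladder — no automatic linear-range
selection, for determinism. The default ladder is powers of two from 2 to
`min(H, W)/4`, giving ≥ 4 fit points at 256 px, with a weak monotonicity
repair (`cummax` from the small-box end) against counting noise at
non-divisor sizes. Estimator accuracy is validated on fixtures of known
dimension: a line (1), a filled square (2), the Sierpinski triangle
(log 3/log 2 ≈ 1.585), the Sierpinski carpet (log 8/log 3 ≈ 1.893, the
hardest case since its base-3 structure is probed with base-2 boxes), and
random Cantor dust (expected dimension 2 + log₂ 0.7 ≈ 1.485 at the fixed
0.7 retention). Degenerate inputs — fewer than 10 skeleton pixels, or
fewer than 2 usable sizes — are errors, surfaced as flagged `NaN` in the
batch pipeline.

# Gliding-box lacunarity

`glidingBoxLacunarity()` slides an `r × r` window at unit step over all
positions fully inside the image and returns
`Λ(r) = E[M²]/E[M]² ≥ 1` for the window masses `M` (integral-image window
sums; the tests verify exact agreement with explicit window enumeration).
A uniform image has `Λ ≡ 1`; a single pixel on an `n × n` image has
`Λ(1) = n²`. The published scalar LAC states no aggregation rule, so
`lacunarity()` reports the unweighted mean of `Λ(r)` over the same
box-size ladder as FD — and always returns the full `Λ(r)` curve so any
other aggregation can be computed. LAC is computed on the skeleton, the
same input as FD, following the stated protocol. Note that skeleton LAC
of a sparse synthetic network is typically well above the clinical scalar
(thin skeletons are gappier than raw slabs); the aggregate is therefore a
relative, not an absolute, comparison index.

# Synthetic data: what it does and does not show

`makeVesselNetwork()` emulates the morphology the pipeline targets: a
stochastic binary branching tree entering from the slab edge (tips
bifurcate with probability `branchProb = 0.85`, otherwise continue, over
`levels = 10` generations; the first two generations always divide when
branching is enabled, since a neovascular complex is by definition
branched), geometric length decay 0.80, 12° angular jitter, 3 px caliber,
optional well-separated polyp-like terminal disks (the PCV phenotype),
rendered at 256 px ≈ a 3 mm slab at 0.01 mm/px with foreground/background
means 180/30 and multiplicative log-normal speckle (σ = 0.3), which keeps
the render Otsu-separable like real slab contrast. These defaults are
fixed study conditions, not fitting knobs; under them the full pipeline
yields skeleton FDs in the 1.2–1.7 band that brackets clinically reported
values, and denser trees yield higher mean FD than sparser ones.

What passing these tests does *not* show: the generator has no projection
artifacts, no flow-speed-dependent signal dropout (the known cause of
hyporeflective polyp lumina), no retinal background texture, and isotropic
speckle rather than device-specific noise. Results on real slabs therefore
depend on acquisition quality in ways the synthetic suite cannot certify.

`makeCohort()` draws eye-level records from per-group normal
distributions whose defaults encode the published cohort structure
(40 acute / 62 complex eyes; 11 type 1, 26 PCV; demographic and lesion
metric means and SDs as published; FD and area jointly normal with
correlation −0.056, the published value; polyp correspondence probability
20/26). Marginals are deliberately left unclipped — at the published SDs a
small fraction of draws is unphysically negative — because clipping would
distort the mean/SD recovery the generator is specified to have.

# Cohort statistics

`summarizeCohort()` reports counts with percentages rounded half-up to
two decimals within each stratum's own denominator (the printed
convention), and `twoSampleT()` accepts raw vectors or `(n, mean, sd)`
summaries — both reduce to the same summary-statistic formulas, so
published tables can be tested exactly. Welch is the default variant: the
protocol says only "t-test, as appropriate" and the group SDs differ;
Student's pooled test is available for reproduction attempts. Normality
screening is an advisory Shapiro-Wilk message only — the published
protocol names no test and no branch, so the package never silently
switches tests. Pearson correlation uses the `t = r√((n−2)/(1−r²))`
transform for its two-sided p-value. Calibration is asserted empirically:
type-I error within [0.03, 0.07] at α = 0.05 over 2,000 null replicates,
and correlation recovery within 0.03 at n = 10,000.

# Problem sizes and runtime choices

The validation suite runs canonical fixtures at 243–256 px, random-mask
oracle comparisons at 32–64 px (100–200 masks per property), 40–60
synthetic networks at 256 px for the discrimination and range properties,
and 2,000 statistical replicates — sizes at which every brute-force oracle
remains exact and the whole suite completes in a few minutes on one core.
The acceptance script re-derives its quantities at the same sizes with 10
freshly seeded networks.

# Known limitations

* Single-lesion assumption; multifocal disease needs cropping upstream.
* FD/LAC depend mildly on the thinning variant and box ladder; both are
  pinned and documented rather than standardized across software.
* The published VPD magnitude is not reproducible from its stated
  definition (units ambiguity documented above).
* 16-bit inputs are binned to 256 histogram levels for thresholding;
  intensities themselves are never rescaled.
* Lesion area is measured on the density zone, not a hand-drawn outline;
  on clinical data the two can differ for diffuse lesions.
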