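---
title: "Automated lipid-pool detection on NIRS chemograms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lipid-pool detection on NIRS chemograms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirslcbi)
```

## The measurement problem

Intravascular near-infrared spectroscopy (NIRS) maps the chemical
composition of a coronary artery during an automated catheter pullback. The
result is displayed as a *chemogram*: a two-dimensional raster whose x-axis
is millimetres of pullback, whose y-axis is degrees of catheter rotation,
and whose red-to-yellow colour scale encodes the probability that lipid
core plaque (LCP) is present at each interrogated location. The headline
summary is the Lipid Core Burden Index,

$$\mathrm{LCBI} = 1000 \cdot
  \frac{\mathrm{Area}_{\mathrm{lipid\ core\ plaque}}}
       {\mathrm{Area}_{\mathrm{valid}}},$$

the fraction of valid pixels whose LCP probability exceeds 0.6, scaled to
\[0, 1000\], together with its windowed maxima `maxLCBI_2mm` and
`maxLCBI_4mm` (the maximal LCBI over any 2 mm or 4 mm longitudinal
segment). `nirslcbi` implements a fully automated pipeline that recovers
these quantities from an exported chemogram raster, including lipid hidden
under black shadow artifacts, and provides the agreement statistics needed
to compare two measurement methods case by case.

Chemogram pixels that carry too little NIRS signal appear black: a
contiguous black band across the pullback is typically the guide-wire
shadow, and local black patches are shadows cast by calcium, which
near-infrared light penetrates poorly — often exactly over the lipid pools
of interest. The pipeline therefore has four stages: preprocessing,
artifact segmentation, two-stage lipid segmentation, and metric
computation.

## Coordinate conventions

Images are `H x W` matrices; row 1 is 0 degrees and column 1 is 0 mm.
Because the catheter rotates, **rows are cyclic**: a region touching the
first and last rows is one angular neighbourhood. Connectivity (artifact
and lipid components) is 8-connectivity in the plane plus wrap-around at
the 0/360 degree seam, and lipid-arc runs wrap the seam the same way.
Regions of interest along the pullback are half-open intervals
`[start_mm, end_mm)`; a pixel column belongs to the ROI if any part of its
mm extent does. Calibration (`mm_per_column`) is supplied by the user:
exported rasters carry no reliable pixel-pitch metadata, and acquisition
density (measurements per mm) does not determine the export's pixel pitch.

## Stage 1: preprocessing

The RGB image is split into channels. On the display colormap, artifacts
are dark in every channel but stand out best against the bright wall in the
**red** channel, while lipid (yellow) is carried by the **green** channel.
`adjust_intensity()` applies the classical contrast stretch: values at or
below the 1% quantile map to 0, at or above the 99% quantile to 255,
linearly in between (both saturated fractions configurable; quantiles use
linear interpolation between order statistics, also configurable, since no
single convention is canonical). Constant images pass through unchanged
with a degeneracy flag rather than erroring — an empty ROI must not crash a
batch run.

One property of this stretch matters for design: Otsu thresholding is
invariant under the *linear* part of the map, so contrast adjustment
influences an Otsu stage only through its saturation clip. For artifact
detection on the red channel the clip is harmless (shadows are far more
than 1% of a typical image) and the adjusted channel is used. For the lipid
stages the clip can be destructive: when visible lipid covers less than the
saturated 1%, the high cut-point falls inside the background-noise tail,
the background is stretched across the full range, and a threshold method
then segments noise; inside a dark shadow, the lipid trace is typically
among the image's brightest pixels, and clipping piles it onto one
histogram bin, corrupting the background-mode estimate described below.
The lipid stages therefore analyse the unsaturated channel. This is the
package's own design choice, made after observing both failure modes on
synthetic scenes.

## Stage 2: artifact segmentation

`otsu_threshold()` maximizes the between-class variance of the two-class
split of the 256-bin integer histogram (no smoothing). Ties are broken
toward the smallest threshold, and pixels with value `<= T` form the dark
class — both fixed conventions. A constant image returns its value with a
degeneracy flag, and `detect_artifacts()` then reports an empty mask: with
no contrast there is no dark class to separate.

Artifact candidates are the dark-class pixels of the adjusted red channel.
Connected components smaller than `min_area_px` (default 8, configurable;
size filtering is a denoising choice of this implementation) are discarded.
Components are computed on a pixel-adjacency graph with cyclic rows, so a
guide-wire band crossing the 0/360 seam is one region, and the whole
detection commutes with row rotation of the image.

## Stage 3: lipid segmentation

**Visible lipid.** The Otsu threshold is computed over the *non-artifact*
pixels of the green channel (including artifact pixels would bias the dark
class), and pixels strictly above it, outside artifacts, are visible lipid.
Otsu assumes a bimodal histogram; on a chemogram with little or no visible
lipid it will happily split the wall texture instead. `detect_visible_lipid()`
therefore checks the achieved separation: if the bright-class mean exceeds
the dark-class mean by less than `visible_min_contrast` gray levels
(default 80 in the pipeline; 0 disables), the split is rejected. In that
case the pipeline falls back to the LCBI pixel definition itself: pixels
whose approximate inverse-colormap probability exceeds 0.6 are lipid
(`lipid_fallback = "colormap"`, default; `"none"` leaves the mask empty).
The fallback is exact on the package's synthetic colormap and approximate
on real exports — see the colormap caveat below.

**Hidden lipid.** Each artifact region is analysed independently. The
highest peak of the region's intensity histogram gives the background level
of the shadow; pixels exceeding the background by more than
`delta_threshold` gray levels (default 25) are marked as hidden lipid. Two
numerical choices harden this: the peak is located on the histogram
smoothed with a moving window of `± mode_bandwidth` gray levels (default 5,
about the pixel-noise SD; with noise, the raw mode of a small region is a
high-variance estimate and can land on the lipid level by chance), and peak
ties resolve toward the lower gray level (the darker value is the safer
background guess for a shadow). Marking is per pixel, not per region, so a
lipid pool partially covered by a large shadow is recovered at its own
extent. The default threshold of 25 sits above three standard deviations of
the 8-gray-level pixel noise the synthetic scenes carry; it is exposed on
the command line because real exports may differ. Which channel to analyse
inside shadows is genuinely open; green (where lipid is most perceptible)
is the default and the channel is a configuration knob.

The combined lipid mask is the pixel-wise union; hidden detection can
reconnect a blob split by a shadow stripe into a single component, which
matters for lipid-arc computation.

## Stage 4: metrics

**Valid pixels.** The LCBI denominator is "valid" pixels. Two conventions
are defensible and both are reported: `reclaim` (default) counts
non-artifact pixels plus artifact pixels reclaimed as hidden lipid — they
demonstrably carry signal — while `strict` excludes all artifact pixels.

**Windows.** `maxLCBI_2mm`/`maxLCBI_4mm` are computed either over
consecutive non-overlapping tiles anchored at the ROI start (`blocked`,
how block-based console summaries work) or over every window position at a
configurable stride, default one pixel column (`sliding`). Blocked windows
are a subset of sliding windows, so the sliding maximum always dominates;
a lipid pool straddling a tile boundary can score up to twice as high under
sliding evaluation, which is why the two modes can disagree substantially
on the same pullback. A trailing partial tile is excluded from blocked
maxima (it is not a full-length segment). Ties go to the smallest window
start.

**Block chemogram.** Each 2 mm block's value is the 90th percentile
(linear-interpolation order statistic) of its pixel values on the
probability scale, classified into the four display classes: red
(`p < 0.57`), orange (`0.57 <= p <= 0.84`), tan (`0.84 < p <= 0.98`),
yellow (`p > 0.98`). The published class intervals overlap at 0.84 and
0.98; those boundary values are assigned to the lower class by fixed
convention. A trailing partial block is reported flagged, without a class.

**Lipid arc.** Per block, the arc is the maximum over the block's columns
of the angular extent of the largest cyclically-contiguous run of lipid
rows (a run crossing 0/360 degrees is one run). An alternative definition —
total angular coverage per column rather than the largest run — is exposed
as `arc_method = "union"`.

**Colormap caveat.** The probability scale comes from inverting the
display colormap. The package's synthetic colormap is linear red-to-yellow
(`green = round(255 p)`), exactly invertible to within 1/255. For real
exports the inverse is approximate: a pixel is accepted as on-colormap if
its red and blue channels are within `probability_tol` gray levels of the
locus (default 60, loose enough for noise, strict enough to exclude
near-black artifacts), and its green value is read as the probability.
Off-locus pixels yield `NA` and are excluded from block percentiles.

## Agreement statistics

For paired per-case metrics from two methods, `compare_methods()` reports,
per metric:

* **Paired Wilcoxon signed-rank test**, two-sided. Zero differences are
  dropped before ranking; absolute differences receive midranks under ties.
  For up to 25 non-zero pairs the p-value is exact, from the full
  distribution of the positive-rank sum over all $2^n$ sign assignments
  (computed by convolution over the doubled midranks, so ties are handled
  exactly); beyond that, a normal approximation with tie correction and
  continuity correction. The two-sided p is
  $\min(1,\, 2\min(P(T \le t), P(T \ge t)))$, symmetric in the two methods.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures — from the two-way ANOVA mean squares, with the standard F-based
  95% confidence interval (Satterthwaite degrees of freedom). Absolute
  agreement is the right form for method interchangeability: a constant
  offset between methods is penalised, where a consistency ICC would not
  see it. The form matching published near-1 clinical values cannot be
  verified from the outside; this choice is documented, not asserted as
  identical.
* **Bland–Altman** mean difference and limits of agreement at
  $\bar d \pm 2\,\mathrm{SD}(d)$ — the factor is 2, not 1.96, and the SD
  uses the sample ($n-1$) convention.
* Median and quartiles (linear interpolation) per method.

## The synthetic generator

No public chemogram corpus exists, so validation uses
`generate_chemogram()`: scenes with a known latent LCP-probability map and
full ground-truth masks. A scene is composed of

* a mottled arterial-wall baseline (LCP probability 0.08–0.28, smooth
  low-frequency modulation, cyclic across the row seam);
* 1–4 elliptical lipid pools, one per pullback segment, with plateau
  probability 0.85–1 and logistic rims about 1 px wide — the latent
  probability is near-binary, crossing the 0.6 truth cut steeply, as the
  sharp borders of displayed chemograms suggest. Pool sizes are set so that
  synthetic `LCBI_total` falls in the tens-to-low-hundreds, the range
  clinical cohorts report;
* one guide-wire band (15–30 degrees tall, full pullback length) and up to
  two calcification shadows placed over the upper half of a lipid pool and
  extending well beyond it — a calcium shadow darkens everything behind the
  calcium, lipid and wall alike, so shadow regions stay
  background-dominated, which is exactly the assumption the background-mode
  estimator rests on;
* artifact darkness 25 gray levels (near-black, but with enough headroom
  that additive noise is not clipped at zero, which would bias the region
  histogram), a hidden-lipid green trace of +60 gray levels where lipid
  lies under a shadow, and additive Gaussian noise (SD 8 gray levels)
  clipped to the 8-bit range;
* a single integer seed governing the whole scene; generation is
  bit-reproducible.

Truth masks are taken before noise: `lipid = p >= 0.6`,
`hidden = artifact & lipid`, `valid = !artifact | hidden`, and true LCBI
metrics are computed from these masks.

**What passing tests do and do not show.** The generator emulates the
geometry and contrast structure of chemograms, not NIR physics: real
exports have an unknown (non-linear) colormap, compression artifacts,
spatially correlated noise, graded shadow edges, and lipid probability
fields that are not plateaus. Segmentation recovery of Jaccard ≥ 0.9 and
near-1 ICC against synthetic truth demonstrate that the pipeline's logic is
self-consistent and robust to the modelled noise — they do not certify
clinical accuracy, which requires paired data from a reference system.

## Problem sizes and numerical choices

Synthetic scenes are 180 x 250 pixels (2 degrees per row, 0.2 mm per
column, 50 mm pullback), and end-to-end agreement uses 31-case datasets,
matching a typical single-centre study size; both are the package's chosen
test conditions. Degenerate inputs are handled explicitly rather than by
erroring where a batch pipeline must continue (constant channels, empty
artifact sets), and error where a number would be meaningless (LCBI with an
empty valid denominator raises rather than returning 0). All randomness is
confined to the generator and derived from explicit integer seeds.

## Known limitations

* Calibration must be supplied; nothing is inferred from image metadata.
* The inverse-colormap probability scale is exact only for the synthetic
  colormap; block values and the low-contrast fallback on real exports are
  approximations and flagged as such.
* Guide-wire and calcification shadows are treated as one artifact class;
  distinguishing them (e.g. with coregistered ultrasound) is out of scope.
* The hidden-lipid rule assumes the shadow background dominates its region;
  a shadow lying almost entirely within lipid would be misread. The
  smoothed-mode estimator reduces, but does not remove, this failure mode.
* No clinical thresholds are applied: the pipeline prints `maxLCBI_4mm`,
  it does not issue risk verdicts.
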