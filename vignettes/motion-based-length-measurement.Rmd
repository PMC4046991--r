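---
title: "Motion-based body-length measurement: model, parameters and validation"
author: "MotionMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based body-length measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotionMorph)
```

## The measurement problem

Springtails (*Folsomia candida* and relatives) are standard test organisms
in soil ecotoxicology, where body growth is an increasingly popular
sublethal endpoint. Measuring the animals is the bottleneck: they are
soft-bodied, weakly sclerotized and constantly curl, telescope and flatten,
so a single photograph rarely shows a measurable posture, and manual
head-to-abdomen measurement on screen is slow and error-prone.

MotionMorph implements an automated alternative. One live animal sits on a
fixed, backlit plate and is photographed repeatedly at fixed intervals
(the default protocol: ten frames, 3 s apart, at 24.6 µm/px). The key
observation is that in such a series, *the animal is the only thing that
moves*; sand grains, excrement and vegetal debris are static. Motion, not
appearance, separates animal from background.

## The pipeline

### Secondary difference images

For each interior frame $t$ the package computes the difference with the
previous frame and the difference with the next frame and combines them
into one *secondary difference image*

$$D_t = \min\left(\,|F_t - F_{t-1}|,\; |F_t - F_{t+1}|\,\right)
\quad (\text{pixelwise}),$$

so a series of $n$ frames yields $n-2$ secondary images (ten frames give
eight). A pixel is bright in $D_t$ only if it differs from **both**
neighbours. Static background cancels exactly; the animal's previous and
next positions ("ghosts") are each shared with one neighbour frame and are
suppressed by the minimum; what remains is the animal's footprint in frame
$t$. The rule is symmetric in $t-1$ and $t+1$, so reversing the frame
order permutes, but does not change, the secondary images — a property the
test suite checks.

The combination rule is a design choice: the minimum is the weakest
combination that still requires disagreement with both neighbours, and it
is what makes a *single* clean patch per secondary image possible. The
alternatives (sum, maximum) would keep all three positions visible and
require a second segmentation step to pick the central one.

### Thresholding and particle analysis

Each $D_t$ is binarized. By default the cutoff is Otsu's criterion on the
intensity histogram, with one guard: the cutoff is never allowed below a
`noiseFloor` (default 0.05). Otsu's method assumes the histogram is
meaningfully bimodal; when the animal occupies a few hundred of several
million pixels, the between-class criterion can maximize *inside* the
sensor-noise mode and admit the whole image. The floor — set at roughly
three standard deviations of a difference of two 8-bit frames with
noise σ ≈ 0.01 — makes the degenerate solution impossible while leaving
the normal Otsu solution (which typically lands near half the
animal–background contrast) untouched. A `fixed` method is provided for
users who need to reproduce a specific instrument level.

Foreground pixels are grouped into particles by 8-connected component
labeling (diagonal contact keeps thin appendages attached to the body),
and each particle's physical area — pixel count × (mm/px)² — must fall in
the inclusive **area gate** 0.01–10 mm². The gate removes residual noise
specks from below and merged or illumination artifacts from above; the
defaults are instrument constants and are configurable.

### The M statistic

Each surviving particle is summarized by the major axis $M$ of its moment
ellipse: orientation and axis ratio come from the second central moments
of the member pixels, and the absolute size is set by matching the ellipse
area to the particle pixel area. This is the convention of the particle
analysis in common image-processing tools, which matters because the
published length calibration was fitted against exactly this statistic.
Two numerical details:

* the diagonal central moments include the $1/12$ pixel-as-unit-square
  term, so collinear patches have a positive minor axis and a single pixel
  degrades gracefully to the area-matched disc ($M = 2/\sqrt{\pi}$ px);
* the area is always the pixel count, never the fitted ellipse's area.

### Filtering, calibration, averaging

All particles of all secondary images of one sequence are pooled into one
measurement set. Two error sources produce *too-small* M values: patches
split by insufficient motion, and curled or contracted postures. Since the
animals rarely stretch beyond their true length, the largest M values are
the trustworthy ones, but a single maximum is noisy for a soft-bodied
animal — hence the **critical-ratio filter**: discard every M below
$r_c \cdot M_{\max}$ (boundary retained), then average. The shipped
default $r_c = 0.939$ is the published instrument value, derived from 50
annotated animals; `determineCriticalRatio()` re-derives it for any
instrument from per-frame regular/irregular posture annotations (lowest
regular M divided by the individual's highest M, averaged over
individuals, sample SD reported).

The fitted ellipse includes antennae and furca, so M overestimates the
head-to-abdomen length, and more so for larger animals. An affine
calibration corrects this: the default, body length $= 0.930\,M - 0.070$
mm, is the published instrument equation; `fitCalibration()` refits it by
ordinary least squares from (manual length, M) pairs. The final estimate
is the mean of the filtered, calibrated M values; affinity guarantees this
equals slope × mean(kept M) + intercept, which the suite checks to
1e−12.

## The synthetic scene generator

Real validation imagery cannot ship with the package, so `generateScene()`
renders scenes with known ground truth: a dark **capsule** (rectangle of
length $L-W$ capped by two half-discs of diameter $W$) on a bright
background, at a new random pose each frame; immobile debris discs
rendered identically in every frame; i.i.d. Gaussian intensity noise per
pixel per frame. The capsule was chosen over an ellipse precisely so that
"true body length" is unambiguous — it is the end-to-end extent $L$, and
the rasterized extent is required (and tested) to match within one pixel.

Realism features, each exercising one pipeline stage:

* **disjoint motion** (default): each pose is kept clear of the two
  preceding poses, so every secondary image contains one whole patch —
  the ideal-capture condition;
* **curl**: bends the centerline along a circular arc of the same contour
  length, shortening the chord, which is how irregular postures produce
  the small M values the critical-ratio filter exists to remove;
* **appendages**: thin protruding segments at the head end reproduce the
  ellipse-overestimation bias that motivates a slope < 1 in the
  calibration;
* **staticAnimal**: a scene whose correct output is the no-motion error.

Everything is seed-driven; `generateCohort()` draws true lengths uniformly
over a range and gives individual $i$ the sub-seed `seed + i`, so cohorts
are reproducible element-wise. Because a full-size ten-frame sequence
occupies ~230 MB, `generateCohort()` accepts a `FUN` argument that maps
each individual to a summary as it is generated, allowing a 50-animal
cohort to run in constant memory.

What the generator does **not** emulate: JPEG compression artifacts,
illumination drift, animal deformation between frames beyond rigid pose
change plus curl, partial occlusion by debris (debris is placed clear of
the animal's path), and multiple animals. Passing tests therefore
demonstrate the correctness of the *algorithmic chain* under the stated
capture assumptions — stable lighting, one moving animal, static debris —
not robustness to capture-protocol violations.

## Choice of validation conditions

The accuracy analog in `scripts/acceptance.R` and the test suite runs 50
synthetic individuals with true lengths uniform in 0.3–2.5 mm (the
species' juvenile-to-adult span), capsule width 0.25 mm, no appendages,
disjoint motion, noise σ = 0.01, on the full-size 1504 × 1940 px field,
cohort seed 20140605. The pipeline is run with an identity calibration to
collect the mean filtered M per individual, a calibration is then refitted
by regressing the true lengths on M — mirroring how the instrument
constants were derived — and every individual must be recovered within
0.05 mm with a cohort Pearson correlation of at least 0.99. Synthetic
capsules carry no appendages, so the refit (slope ≈ 0.89, intercept ≈
0.035 for W = 0.25, matching the closed form `capsuleMomentMajor()`)
differs from the published constants, which encode the appendage bias of
real animals; applying the published equation to appendage-free capsules
would add a ~0.1 mm systematic error at the small end and would test the
wrong thing.

Module tests use the same physics on smaller fields of view (roughly
300 × 400 px) to keep the default suite fast; the cohort block is the one
intentionally expensive test.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `pixelScaleMm` | 0.0246 | mm/px | instrument resolution; every physical quantity scales from it |
| frame count / interval | 10 / 3 | – / s | capture protocol; n frames give n−2 secondary images |
| `noiseFloor` | 0.05 | intensity | lower bound on the Otsu cutoff |
| `AreaGate` | 0.01–10 | mm² | inclusive particle-area range |
| `criticalRatio` | 0.939 | – | filter cutoff as a fraction of max M |
| calibration | 0.930, −0.070 | –, mm | affine M → length map |

All defaults are instrument-specific and overridable per call, via the CLI
flags, or via a key–value config file (flags > config > defaults).

## Degenerate inputs and edge behavior

* Fewer than 3 frames, mixed frame sizes, undecodable files: input error.
* An animal that never moves: all secondary images cancel, no particle
  passes the gate, and the pipeline raises a distinct no-motion condition
  (CLI exit code 3) — in live use such animals are nudged with an air
  puff and re-photographed.
* A calibration that maps some M to a non-positive length raises rather
  than clamps.
* Ties at the filter boundary are kept (the rule discards strictly
  "less than" the cutoff); at ratio 1.0 exactly the argmax ties survive.
* Individuals without any regular-posture frame are skipped (with a
  warning) by the critical-ratio derivation, not fatal to the batch.

## Known limitations

One animal per sequence is assumed and enforced only statistically (a
second mover would contribute its own patches and corrupt the pooled M
set; scenes with several animals should be rejected upstream). The ellipse
statistic is posture-dependent; the filter removes most but not all
curled-posture bias, which is why the method, like the manual one, reports
an average over frames. The critical ratio and calibration shipped as
defaults travel with the instrument they were derived on; new hardware
should re-derive both with `determineCriticalRatio()` and
`fitCalibration()`.
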