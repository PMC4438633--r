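---
title: "Methods: quantifying myofibroblast-driven collagen matrix remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying myofibroblast-driven collagen matrix remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmquant)
```

## Scientific setting

Cardiac fibroblasts activated by pro-fibrotic stimuli such as TGF-β1 convert
into contractile, α-smooth-muscle-actin (α-SMA) expressing myofibroblasts
that remodel their surrounding type-I collagen matrix: they contract
free-floating collagen gels, degrade matrix through protease (MMP) activity,
realign collagen fibers along cell-induced strain fields, and adopt a
stellate morphology with long cytoplasmic extensions. ecmquant implements
the image-analysis read-outs used to quantify each of these phenotypes in 3D
collagen-gel assays, together with seeded synthetic-image generators that
carry exact ground truth, so every stage of the pipeline can be validated
end to end without microscope data.

## Collagen fiber alignment

The directionality read-out works on the 2D Fourier magnitude spectrum of a
confocal reflectance image. Texture oriented along an axis $\theta$
concentrates spectral energy along $\theta + 90^\circ$; summing spectrum
intensities along rays from the spectrum center at each angle ("oval
profile") therefore turns co-orientation of fibers into a peak of the
angular intensity curve. The curve of a treated image is divided pointwise
by the curve of a no-cell control image and rescaled to unit mean, so a
direction-free field maps to a flat curve at 1. The **alignment index** is
the trapezoidal area under the normalized curve within $\pm 10^\circ$ of its
peak; a flat curve scores exactly $2 \times 10 = 20$, and stronger
co-orientation scores higher because the curve concentrates mass near the
peak.

Numerical choices, all configurable:

* **Mean subtraction and Hann window** before the FFT (default on). Without
  the window, the frame edges contribute a strong axis-aligned cross that
  dominates the angular profile.
* **Radial band** of the ray sums: 2 %–45 % of half the smaller image
  dimension, excluding the DC neighbourhood (dominated by illumination
  structure) and the spectrum corners (sampled anisotropically).
* **Ray sampling**: 1-px radial steps, bilinear interpolation, rays at
  $\theta$ and $\theta + 180^\circ$ combined; the magnitude spectrum is
  centro-symmetric, so the profile is 180°-periodic by construction.
* **Speckle regularization.** The spectrum of a discrete fiber network is
  speckled (fiber phases interfere), which makes raw ray sums noisy at 1°
  resolution. Two smoothing steps stabilise the curve: a Gaussian blur of
  the spectrum (σ = 4 px) before sampling and a circular Gaussian smoothing
  of the sampled curve (σ = 5°). Both preserve the flat-curve identity
  (index exactly 20), intensity-scale invariance, and periodicity. σ = 5°
  is well below the narrowest angular feature the index integrates (a 20°
  window), so the index ordering across conditions is unaffected.
* **Peak estimation.** `find_peak()` is the plain argmax with ties broken
  toward the smaller angle; an all-flat curve returns 0° with a warning
  rather than an error, because a direction-free field is a legitimate
  observation. The pipeline additionally refines the argmax by the
  intensity-weighted circular mean of the curve within ±30° of it
  (baseline-subtracted). For the broad bumps produced by moderate
  concentration (κ ≈ 5 the angular SD is ~13°) the argmax jitters by
  several degrees between seeds while the weighted mean is stable; across
  validation sweeps the refined axis stays within ~4° of the generator
  truth for κ ≥ 5, with mean error near 1°.
* **Axis convention.** Angles are degrees in $[0, 180)$, 0° along the image
  x-axis, counter-clockwise. The 90° rotation from spectral peak to fiber
  axis is applied exactly once, in `fiber_alignment()`, so all
  profile-level functions stay in spectral coordinates.
* **Normalization.** The no-cell control could plausibly be divided out or
  subtracted; the ratio is the default because it cancels the radially
  varying gain of the imaging chain multiplicatively, which is how optical
  transfer acts; subtraction is available via
  `normalize_profile(method = "subtract")`. The index is refused on
  unnormalized curves so that indices are always on one scale.
* **Window endpoints.** The ±10° window is integrated as a closed interval
  with trapezoids; the window parameter must lie in (0°, 90°).

## In situ zymography

Cleaved DQ-gelatin fluoresces where proteases are active; activity is read
out from a z-stack as

$$\text{Total protease activity} = \text{MFI} \times
  \frac{\text{total volume of fluorescent objects}}
       {\text{total image volume}}$$

Objects are voxels above threshold (Otsu on a 256-level histogram by
default, or a fixed value) grouped by 26-connectivity, discarding components
below `min_voxels` (default 5) to suppress single-voxel noise. MFI is the
**unweighted mean of per-object mean intensities** — every object counts
equally regardless of size, matching the convention of averaging "the
fluorescent objects identified in the image". A voxel-weighted variant
(`weighted = TRUE`) pools all object voxels instead; the two differ whenever
bright and dim objects differ in size, and the unweighted form is the
default reported value. Per-field results from several random fields of one
gel are combined as an arithmetic mean (`summarize_gel_activity()`).

A fixed threshold above the stack maximum returns an empty object table
with a warning, not an error: "no digestion detected" is a valid result.

## Single-cell morphology

**Roundness** is the isoperimetric shape factor $4\pi A / P^2$, capped at 1:
1 for a disk, decreasing toward 0 for stellate shapes. The perimeter is the
chain-code length of the component boundary with the Vossepoel–Smeulders
correction (0.980 per axial step, 1.406 per diagonal step, −0.091 per
corner). The correction matters: the raw chain length of a rasterized circle
overestimates the true perimeter by ~5 %, which would bias a perfect disk
to roundness ≈ 0.90; with the correction, disks of radius 20–200 px all
score ≈ 1.00.

**Extension lengths** implement "distance from the center of the cell to the
tip of an extension". The mask is thinned to a 1-px skeleton (Zhang–Suen);
skeleton pixels with exactly one neighbour are candidate tips. Endpoints
inside the cell body are discarded. The cell center is the center of the
largest inscribed disk (the distance-transform argmax) rather than the mask
centroid: for a cell with one long arm the centroid shifts ~10 px toward
the arm, biasing every length, while the inscribed-disk center stays on the
body (the centroid is available via `center = "centroid"`). Because
thinning erodes about half an arm-width from the tip, the reported length is
measured to the farthest mask pixel within a ±15° cone around the endpoint
direction — i.e. to the actual tip. On synthetic stars this recovers arm
lengths of 40–100 px with mean error below 1 px for 1–6 arms at any arm
orientation.

**α-SMA positive fractions** are consumed as per-image count tables
(positive, total); positivity calling itself is manual counting in the
assay, so it is out of scope. Per-image percent positive is averaged
unweighted across images.

## Gel contraction

Gel silhouettes are thresholded (Otsu default; `polarity = "dark"` inverts
first), the largest component is kept and hole-filled, and percent
contraction is $100\,(1 - A_{24}/A_0)$ — the percent of surface area lost,
with the residual fraction reported alongside. Swelling (follow-up larger
than baseline) yields a negative value with a warning. Group values are
normalized to the **mean of the control group** (`normalize_to_control()`),
so controls have mean 1 and treatments are fold-of-control; statistics can
be run on raw or normalized values, and both orders are reported by the
pipeline when asked.

## Group statistics

Values are summarized as mean ± SD (sample SD, $n-1$). Two groups are
compared with the two-sided unpaired Student's t-test (equal variances, the
textbook form; Welch via `welch = TRUE`); three or more with one-way ANOVA
followed by all-pairs Tukey HSD ("appropriate post hoc" is unspecified in
the assay convention, and Tukey HSD is the standard all-pairs choice;
control-only contrasts via `dunnett_control`). Underflowing p-values are
floored at the smallest positive double so downstream comparisons never see
an exact 0.

## Synthetic data: what it emulates and what it does not

All generators are seeded and bit-reproducible at fixed parameters.

* **Fiber fields** render anti-aliased line segments with centers uniform
  over the frame and orientations drawn from a von Mises distribution on
  the doubled-angle circle (the standard treatment of axial data, where
  $\theta \equiv \theta + 180^\circ$), halved back to $[0, 180)$; κ = 0 is
  exactly uniform. Defaults — 256×256 px at 1 µm/px, 800 fibers of length
  80 px and width 2 px, intensity 100 over Gaussian noise SD 5 — emulate a
  dense gel reflectance field; sparser fields leave the realized angular
  density of a finite fiber sample ragged enough that no estimator can
  place its peak stably. Bit depth and pixel size are not standardized in
  the assay, so intensities are 8-bit-range floats and 1 µm/px,
  configurable.
* **Spot stacks** place solid constant-intensity balls on a uniform
  background with rejection sampling (retry cap 1000 per spot) so objects
  never overlap and per-object volume/MFI ground truth is exact. Constant
  intensity is chosen over Gaussian blobs deliberately: oracle precision
  over realism.
* **Cell masks** are a disk plus equally spaced rectangular arms reaching
  exactly `arm_length_px` from the center; `n_arms = 0` is the round
  control.
* **Gel series** are filled disks whose follow-up radius is
  $r_0\sqrt{1 - f}$ for area-contraction fraction $f$.
* **Count tables** draw positives per image from Binomial(total, p).

None of the generators simulate an optical PSF, spectral crosstalk, uneven
illumination, or the nylon grid of thin-gel platforms (analysis is done
within grid openings, so grid-free frames are equivalent). Passing tests on
these images therefore demonstrates correctness of the measurement
pipeline — geometry, spectra, segmentation, statistics — not robustness to
acquisition artifacts of real microscopes.

## Validation scale and degenerate inputs

The shipped test-suite checks run at desk scale, chosen as the smallest
sizes at which each property is informative: 20 seeds per condition for
profile flatness and index monotonicity over κ ∈ {0, 1, 2, 5, 10} at
256×256 px; orientation recovery over six mean angles × κ ∈ {5, 10}; ten
64×256×256 stacks for the zymography oracle identity; 2000 null datasets
(n = 10 per group) for the empirical size of the two-group test; 30 seeds
for the three-arm (untreated / TGF-β1-like / TGF-β1+FGF-2-like) experiment.

Degenerate inputs are handled explicitly rather than rejected wholesale: a
constant image yields a zero spectrum away from DC; a flat profile returns
peak 0° with a warning; an empty segmentation is a result, not an error;
`percent_contraction` warns on swelling; groups with fewer than two values
are refused by name.

## Known limitations

* Per-fiber tracing, 3D orientation tensors, and wavelet/curvelet
  directionality methods are out of scope; the FFT read-out reports one
  dominant axis and its concentration, not a full orientation distribution.
* MFI-based activity has arbitrary intensity units; values are comparable
  within an imaging session, which is why the no-cell/control
  normalizations exist.
* The extension measurement assumes arms are roughly radial and separated
  by more than twice the 15° tip-search cone.
* Two-timepoint contraction only; no time-course fitting.
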