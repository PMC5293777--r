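---
title: "Methods: transport maps, label ratios and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport maps, label ratios and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoquant)
```

## The measurement problem

In the rodent microbead occlusion model of glaucoma, one eye receives an
anterior-chamber injection of polystyrene microbeads that elevates
intraocular pressure (IOP) by roughly 30%; the fellow saline-injected eye is
the internal control. Early disease is read out not as cell death but as a
failure of anterograde axonal transport: a fluorophore-conjugated tracer
(cholera toxin subunit B, CTB) injected into the eye is carried by retinal
ganglion cell (RGC) axons to the superior colliculus (SC), and where
transport fails the collicular signal goes dark. This package implements the
quantification machinery for that readout and its companions:
immunolabel percent-area with per-animal microbead:saline ratios, NF-κB
nuclear-localization scoring, retinal morphometry, and the statistical
comparisons used to report them.

## Percent intact transport

Each coronal SC section contributes a mediolateral intensity profile of
background-subtracted CTB signal within an SC mask
(`normalize_background()`, `extract_section_profile()`). Profiles, ordered
rostral to caudal, are stacked and bilinearly interpolated onto a
100 × 100 grid (`assemble_retinotopic_map()`), then divided by the map's
reference maximum so the brightest valid cell reads 1.0. The statistic is

> percent intact = 100 · #\{valid cells with density ≥ θ\} / #\{valid cells\},

with θ = 0.70 by default and the tie counting as intact (the definition is
"at least 70% of the maximum"). Key choices:

* **Reference maximum.** "The maximum signal for that tissue" is ambiguous in
  the presence of hot pixels. The default reference is the 99th percentile of
  valid interpolated intensities; the exact maximum is available via
  `reference = "max"` and is what the oracle tests use. On clean synthetic
  maps the two agree.
* **Per-map normalization.** Normalization is per map (per tissue), not per
  section; a per-section variant would erase rostrocaudal deficit structure.
* **Mediolateral frame.** Profiles are binned over the full image width, so
  sections with different chord widths stay registered; empty bins become
  invalid map cells rather than being stretched.
* **Section spacing** is metadata only: area fractions of a uniformly stacked
  map are invariant to uniform spacing, so alternating 50 µm sections
  (100 µm spacing) need no geometric correction.
* **Masks are inputs.** SC masks come from the generator or an annotation
  file; automatic SC segmentation is out of scope.

## Immunolabel percent area and microbead:saline ratios

`percent_area_positive()` is an exact pixel-count ratio over an annotated
ROI. Thresholding (`threshold_positive_label()`) is the least-specified part
of the original macro-based workflow, so both a fixed configured intensity
(default) and Otsu derived from the pooled saline + microbead pair are
provided; pooling honours the guarantee that both eyes of an animal were
acquired under identical settings, and a per-eye threshold would bias the
ratio. Aggregation order is images → animal → group: each animal contributes
one microbead:saline ratio, and the group is reported as mean ± SEM. An
animal with a zero saline value has an undefined ratio and is excluded with
a warning.

## NF-κB nuclear localization

Nuclei are segmented on the DAPI channel (Otsu threshold, connected
components, distance-transform watershed for touching nuclei, area filter).
For each nucleus the score contrasts the signal mean inside the nucleus with
the mean over a perinuclear annulus (default width 3 px) that excludes all
nucleus pixels:

> nuclear fraction = nuclear mean / (nuclear mean + annulus mean).

This metric is monotone in the true nuclear partition, robust to cell-size
variation, and equals 0.5 under a spatially uniform signal. Because a
constant intensity offset pulls every fraction toward 0.5, background
normalization must precede scoring; a regression test asserts the direction
of that bias. The image-level score is the mean per-nucleus fraction by
default; a fraction-of-positive-nuclei alternative is selectable
(`metric = "positive_fraction"`) since the original macro's exact metric is
unpublished. Ratio analysis then reuses the microbead:saline machinery.

## Morphometry

Layer thickness is measured from annotated boundary polylines — not from
automatic segmentation, mirroring manual measurement practice — as the mean
perpendicular distance between curves at five equally spaced locations per
image. RGC counting detects DAPI objects in the ganglion-cell-layer ROI and
calls them CTB-positive when the object's mean CTB intensity exceeds a
configured cut; density is count / ROI area (µm²). A minimum of eight images
per animal is the conventional sampling depth; the pipeline logs image
counts and warns below the configured minimum rather than refusing.

## Statistical battery

* `compare_groups()`: Shapiro–Wilk on each sample at α = 0.05; both pass →
  two-sided pooled-variance t test, else Mann–Whitney. The route taken is
  recorded on the result, and constant samples short-circuit to the exact
  degenerate answers.
* `anova_holm_sidak()`: one-way ANOVA, then pairwise t statistics sharing
  the residual mean square with Holm–Šidák step-down adjustment
  (`1 − (1 − p)^k` with cumulative maxima); `stats::p.adjust` has no Šidák
  variant, so the adjustment is implemented here and property-tested for
  monotonicity.
* `test_vs_unity()`: one-sided t test against a hypothesized value
  (default 1). The reporting convention takes the alternative from the
  observed side of unity, matching per-panel usage where the direction of
  departure is known; that rule doubles the null rejection rate by
  construction (it is two 5% tails), so the calibration suite — which
  demands a 5% type-I error — supplies a fixed direction. Both behaviours
  are explicit arguments rather than hidden defaults.
* `observed_power()` reports post-hoc power for parity with legacy
  statistical software; it never gates inference.
* Percent changes are reported to one decimal for IOP and to the integer for
  marker-ratio changes, which is what makes the printed worked examples
  reproduce exactly.

## What the synthetic generator emulates — and what it does not

The generator family renders every input modality with recomputable ground
truth:

* **SC series** (`generate_sc_series()`): the flattened retinotopic surface
  is a disc; a transport deficit is an angular wedge whose angular extent
  equals the requested area fraction — deficits in this model fill complete
  retinotopic sectors. Sections are chords of the disc; intact tissue
  renders at 1000 intensity units, deficit at 30% of that, on a constant
  background of 100 with additive Gaussian noise (sd 5). The stored truth is
  the realized pixel fraction, which matches the request up to chord
  discretization (±0.01 at 96 px).
* **Immunolabel fields** (`generate_ihc_image()`): a Gaussian-correlated
  random field thresholded at its empirical quantile gives an exact positive
  pixel count at a generator-known threshold midway between the label levels
  (50/200); default noise cannot cross the gap.
* **Cell fields** (`generate_nuclei_image()`): non-overlapping disks
  (rejection sampling with bounded retries keeps the count truth exact) with
  nuclear mean `f·T` and annulus mean `(1−f)·T`, so the defined fraction is
  `f` exactly before noise.
* **Retina sections** (`generate_retina_section()`): parallel (optionally
  tilted) layer bands at stated depths; tilting inflates vertical spacing by
  `1/cos(tilt)` so perpendicular thickness stays the stated value; somas in
  the GCL are CTB+/DAPI+ with optional DAPI-only distractors.
* **IOP series** (`generate_iop_series()`): subject baselines
  N(20.2, 1.0²) mmHg, tonometry noise sd 1.5 mmHg, microbead eye at
  baseline × (1 + 0.30) from day 1. The noise defaults are free parameters
  the source experiments do not report; they were chosen once as realistic
  for awake rebound tonometry and are exposed in the spec object. Readings
  are daily rather than thrice-weekly; summaries use day means, so group
  means are unaffected.

All randomness flows from one spec-level seed through deterministic
sub-seeds, so identical spec + seed yields bit-identical images and any
sub-object can be regenerated independently.

The generator does **not** emulate optics (no PSF, no photobleaching, no 3D
stacks), tissue autofluorescence structure, section-to-section registration
error, or biological covariance between modalities. A green recovery test
therefore establishes that the measurement code inverts the stated rendering
model within tolerance — not that it would survive every pathology of real
microscopy.

## Numerical and degenerate-input choices

* Thresholds compare with a 1e-9 slack so the "≥ threshold" tie is intact
  under floating point.
* Otsu on a constant image is undefined; callers either fall back to a fixed
  threshold (with a warning) or treat the image as pure background.
* Empty masks/ROIs, all-invalid maps, crossing boundary curves, zero saline
  values, and sub-minimum sample sizes are rejected with named errors or
  flagged warnings, as the respective contracts specify.
* Images are serialized as plain-text TSV matrices plus a JSON sidecar. No
  TIFF reader/writer exists in the supported R dependency set, and the
  container format carries no scientific content; the layout
  (`cohort/<animal>/<tissue>/<eye>/...` + `manifest.json`) makes the eye
  pairing required by ratio analysis structural.

## Known limitations

* Watershed splitting is tuned for disk-like nuclei; highly irregular or
  densely clumped nuclei would need a more elaborate marker policy.
* The wedge-deficit geometry is a single contiguous sector; multifocal
  deficits are representable only as larger sectors.
* Exclusion of sections lacking tracer uptake is a manual config flag, not
  an automatic detector.
* Several percent changes printed in the source literature do not recompute
  from their printed group means (per-animal computation or rounding on the
  publication side); the worked-example suite covers exactly those that do.
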