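---
title: "Methods: power-sharing multifocal Raman MSI in simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power-sharing multifocal Raman MSI in simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmsi)
```

## Overview

`ramanmsi` models a two-stage tissue-diagnosis workflow for skin-cancer
resections: a fast autofluorescence (AF) image selects where to measure,
and multifocal Raman micro-spectroscopy measures batches of six points
simultaneously by splitting the excitation laser with a phase-only
hologram. Because no public data accompany this instrument concept, the
package ships a forward simulator for every physical stage, and all
claims the test suite makes are claims about that simulator.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic experiments do and do not
demonstrate.

## Hologram synthesis

The spatial light modulator is modelled as a 512×512 phase matrix; the
sample plane is its discrete Fourier transform. The far-field intensity is
normalized so total far-field power equals the SLM-plane power of the
unit-amplitude field (Parseval; conserved to 1e-9 relative in the tests).

- `gratings_and_lenses()` superposes one linear ramp per requested
  1st-order spot and takes the argument of the complex sum. The
  argument-of-sum rule is deterministic; random-mask superposition was
  rejected because reproducibility is a package-wide invariant. The
  0th-order beam is the phase-only approximation residual and is kept as a
  sampling beam rather than discarded.
- A perfectly balanced two-spot pattern makes the superposition a binary
  phase grating: the undiffracted order is then suppressed and odd
  harmonics appear. The tests assert what the Fourier oracle shows (the two
  requested spots are the brightest peaks) rather than assuming a visible
  0th order in that special case.
- `gerchberg_saxton()` alternates projections between uniform SLM
  amplitude and the square root of the target far-field intensity. The
  error metric is one minus the cosine similarity between achieved and
  target intensity on the target support; it is monitored per iteration
  and non-increasing within 1e-6 in the tests. Initial phase is uniform
  random under the caller's seed.
- `apply_blazing(h, b)` scales the phase excursion about the circular mean
  phase by `b` in [0, 1]; `b = 0` collapses to a uniform phase (all power
  undiffracted). Spot power is measured as the summed intensity in a 3×3
  far-field window at the nominal offset; `optimize_uniformity()` scans a
  `b` grid (default 0.40–1.00 in steps of 0.02) and minimizes the
  max/min spot-power ratio over all spots including the 0th order.

## Tissue phantom and spectral library

The library holds one noise-free basis spectrum per class on a shared
1 cm⁻¹ grid over 300–1900 cm⁻¹, built as sums of Gaussian bands (default
width 8 cm⁻¹ FWHM — band positions are the established tissue-Raman
assignments, widths are a modelling choice) plus a very broad background
hump per class. BCC carries the DNA backbone bands (788, 1098 cm⁻¹),
dermis the collagen proline/hydroxyproline bands (851, 950 cm⁻¹), fat the
lipid set (850, 1070, 1267, 1301, 1450, 1660 cm⁻¹), and every tissue
class the 1450 cm⁻¹ CH-deformation band. The dye class has no sharp
bands, only a broad emission.

Phantoms are rasterized region layouts (rectangles and ellipses, µm
coordinates, pixel centers at half-integers, x rightward / y downward).
Per-class AF intensities are drawn i.i.d. per pixel with means 20
(background), 60 (dermis) and 140–160 (epidermis, BCC, fat, dye) at SD
12: the three high-AF classes overlap by construction, encoding the
premise that AF is sensitive but not specific for tumour. A dye mask can
cover a configurable fraction of the tumour-adjacent rim, emulating the
surgical orientation dyes that fluoresce strongly.

## CCD forward model

Each beam's spectrum is the class basis under its sampling point, plus a
fluorescence baseline (a fixed 4th-order polynomial shape scaled per
class, with per-spectrum lognormal amplitude jitter of σ = 0.3 — tissue
autofluorescence varies point to point, and without this variability a
principal-component analysis of a spectra set degenerates), plus the MgF₂
substrate peak at 320 cm⁻¹, plus a strong broad emission at
dye-contaminated points. The spectrum is broadened by a Gaussian kernel
(default 8 cm⁻¹ FWHM, standing in for the pseudo-slit width), scaled by
beam weight × integration time × 250 counts/(basis unit·s·weight unit),
mapped to detector columns through the cubic wavenumber calibration with a
per-beam dispersion offset (≤ ±20 px), and written into two adjacent rows
of the 256×1024 detector. Poisson shot noise, 5-count RMS read noise per
track over a 100-count bias, Poisson-count cosmic-ray spikes and
full-well clipping (65535) follow.

Beam weights come in two modes. `"native"` gives the 0th order 10× the
power of a near-axis 1st-order beam, with 1st-order throughput falling
quadratically to 10 % at the FOV corner (hologram efficiency plus
vignetting). `"blazed"` models the blazing-optimized configuration used
for tissue work at ≤10 beams: the total budget of 10 weight units is
shared evenly, so 6 beams get 1.67 units each. One weight unit
corresponds to a single-beam-equivalent exposure (~120 mW). The count
scale, bias and read noise were set together so that a blazed single-unit
2 s tissue exposure lands in the SNR regime reported for diagnostic-quality
skin spectra (SNR of order tens by the 1450 cm⁻¹-height /
1500 cm⁻¹-RMS definition); the SNR acceptance runs then measure, not
assume, the margin over the bounds of 10 (chicken-skin-like tissue, 10
beams) and 7 (fat-rich human skin, 6 beams).

## AF segmentation and sampling points

"Maximum homogeneity" thresholding is implemented as multi-level Otsu:
thresholds minimizing the pooled within-class intensity variance, found
by dynamic programming over a 128-bin range-based histogram (hence
invariance to monotone affine intensity rescaling). Thresholded classes
are split into connected components (EBImage), and components under
`min_area` pixels are merged into the neighbor with the longest shared
border. The lowest-intensity class is background. A constant image
degenerates to a single segment with a warning.

Per-segment point counts follow `max(min_per_segment, round(area_mm² ×
density × priority))`, where priority is the segment's mean AF relative
to the non-background mean, raised to a configurable exponent (default 1;
the upstream idea of prioritizing high-AF segments is asserted but not
quantified anywhere, so the multiplier is a knob, not canon). Points are
placed by seeded best-candidate blue-noise sampling inside the segment
mask; a single-point request goes to the segment's distance-transform
pole. AF-to-stage registration is a 6-parameter least-squares affine fit
(stitched-image mappings may shear slightly, so similarity transforms
were not used); at least three non-collinear landmark pairs are required.

## Batch planning

Points are grouped by k-means with k starting at ⌈N/6⌉ and escalating
until every cluster is feasible; each infeasible cluster adds at least
one centroid per round. Initialization is deterministic farthest-point
seeding from the caller's seed — vanilla random restarts both break
reproducibility and fragment well-separated clusters. Feasibility is
anchored: the 0th-order member (closest to the centroid of AF-derived
members, ties to the lowest index; padding never moves the anchor) must
be able to sit at the FOV center with every member within ±90 µm
horizontally and ±30 µm vertically, pairwise vertical gaps ≥ 10 µm (the
CCD cross-talk constraint; the 60 µm FOV height packs exactly six points
at 10 µm), and enough residual vertical slots to pad to six. Vertically
conflicting AF points split the batch with both points preserved.

Padding draws uniform in-FOV positions rejection-sampled against the
separation constraint (200 attempts, then deterministic greedy slot
packing); an optional world-bounds argument keeps fills on the specimen.
Beams that still overhang the section edge sample bare substrate
(background class) rather than erroring, up to one FOV beyond the image.
Acquisition time is `batches × t_int × overhead`, with the overhead
multiplier defaulting to 1 (stage moves and readout typically double it).

## Readout and preprocessing

The chain is extract → cosmic-ray removal → calibrate → substrate-shift
correction → crop → saturation QC → SNV. Cosmic rays exploit the
two-track readout: pixels where the tracks disagree beyond 6 σ of the
shot-plus-read estimate are replaced by twice the lower track, and
coincident spikes fall back to a 5-point running median. The wavenumber
calibration is a least-squares cubic through five polystyrene reference
peaks (620.9, 1001.4, 1031.8, 1155.3, 1583.1 cm⁻¹ — conventional values,
configurable); monotonicity over the detector is a hard postcondition.
The per-beam residual shift is corrected by locating the MgF₂ 320 cm⁻¹
peak with quadratic sub-bin interpolation after removing the local
baseline slope; peaks below 5 MAD prominence flag the spectrum instead of
shifting it. Cropping resamples onto the shared 1 cm⁻¹ grid (linear
interpolation) — 520–1830 cm⁻¹ for storage, 600–1800 cm⁻¹ for
classification, both applied in that order. SNR uses the 1450 cm⁻¹ band
height over a 3-sample-edge linear baseline divided by the RMS of the
linearly detrended 1490–1510 cm⁻¹ region; height rather than area keeps
the ratio dimensionless against an RMS noise, and an (effectively) zero
noise region reports +Inf.

## Classifier

Band areas A₁–A₇ integrate fixed windows (772–800, 843–865, 825–946,
993–1022, 1070–1115, 1235–1279, 1279–1327 cm⁻¹) after subtracting the
line through the mean of the three samples at each window edge; A₂ lies
inside A₃ as printed and is integrated as defined. The five ratios
{A₁/A₄, A₂/A₄, A₃/A₄, A₅/A₄, A₆/A₇} are scale- and straight-line-
invariant; a zero denominator marks the spectrum unclassifiable.

The dye/fat screen thresholds principal-component scores at median ±
4 MAD. Which components carry the dye and fat contrasts depends on the
composition of the spectra set — with realistic baseline variability they
tend to be the second and third, but a homogeneous background pushes the
contrast onto the first — so the screen checks the leading three
components by default (configurable) and labels a flagged spectrum dye or
fat only when its own spectrum correlates best with the dye or lipid
reference signature; flagged spectra matching a tissue signature are
kept, because minority tissue classes also produce extreme scores.

The three-class model (BCC, epidermis, dermis — fat and dye having left
at the screen, which also defines "all other classes" for specificity) is
ridge-penalized multinomial logistic regression on the five ratios
(glmnet, α = 0, λ over 10⁻⁵…10⁰ in 12 log steps). Selection is 5-fold
stratified CV maximizing mean fold specificity subject to mean fold
sensitivity ≥ 95 %; within each fold the BCC-vs-rest threshold on P(BCC)
is tuned on the training portion: the threshold maximizing training
specificity subject to the sensitivity target, specificity ties breaking
toward higher sensitivity, and the final cut placed mid-gap between
adjacent candidate probabilities so separable data retain a
generalization margin. Segment-level diagnosis drops QC-failed spectra,
lets a dye/fat majority vote call the segment directly, and otherwise
averages the surviving spectra into one spectrum before classification;
segments with nothing left are reported unmeasured.

## What the synthetic experiments show — and what they do not

The generator reproduces the study conditions at desk scale: 318
isolated clusters of 794 points padded to 1908, 6-beam 2 s batches on
fat, 10-beam batches on bilayer tissue, 500 training spectra per class.
Problem sizes in the test suite (20 SNR replicates, 1000 random planner
instances, a 160×120 px demo phantom) are the package's own choices for
a reproducible desk-scale run. What passing tests demonstrate: the
algorithms are internally correct against independent oracles, the
pipeline is seed-deterministic end to end, and under the stated noise
model the SNR and sensitivity bounds are met.

What they cannot demonstrate: performance on real tissue. The simulator
draws every class from a single basis spectrum with stationary noise — no
inter-patient variability, no partial-volume mixing at class boundaries,
no focus drift, no real dye chemistry, and AF contrast reduced to
overlapping Gaussian intensities. The near-perfect synthetic
classification reflects that idealization, emphatically not an expected
clinical operating point; published patient-level figures are not
reproducible without patient spectra and are out of scope here. Other
limits: no optical point-spread or defocus model, 2-D phantoms only, no
ghost orders or SLM look-up-table nonlinearity, constant-bias detector
correction only, and batch order is construction order (no stage-travel
optimization).
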