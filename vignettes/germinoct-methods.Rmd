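---
title: "Methods: OCT-based monitoring of seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT-based monitoring of seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

germinoct implements a nondestructive monitoring pipeline for germinating
pea seeds: spectral-domain optical coherence tomography (SD-OCT) resolves
the seed's internal layering over time, a co-mounted camera tracks its
external shape, and seed weight — the gravimetric gold standard of
germination staging — anchors the validation. Because raw instrument
recordings of this kind are not publicly available, the package pairs the
analysis chain with a synthetic-data generator whose ground truth is known
exactly, so every estimator can be tested as a recovery problem.

## The forward model

An SD-OCT spectrometer records, for each lateral position, the spectral
interferogram

$$ S(\lambda) \;=\; G(\lambda)\,\Big(1 + \sum_i 2\sqrt{R_r R_i}\,
   \cos\!\big(2 k z_i\big)\Big) + \varepsilon(\lambda), \qquad k = 2\pi/\lambda, $$

where $G$ is the Gaussian source envelope (centre wavelength
$\lambda_0 = 840$ nm, FWHM bandwidth $\Delta\lambda = 50$ nm), $R_i$ and
$z_i$ are the reflectance and *optical* depth of the $i$-th interface, and
$\varepsilon$ is detector noise. Two closed-form system quantities follow
from the source and the spectrometer (sampling interval
$\delta\lambda = 0.09$ nm over 1024 pixels):

* axial resolution $(2\ln 2/\pi)\,\lambda_0^2/\Delta\lambda \approx 6.2\,\mu m$
  in air (divided by the tissue index inside a medium), and
* maximum imaging depth $\lambda_0^2/(4\,\delta\lambda) \approx 1.96$ mm.

The nominal B-scan depth axis spans 2.2 mm over 1024 rows. `germinoct`
treats that span as axis *metadata* (it sets the axial pixel size,
2.148 µm optical) and reports the formula value from
`max_imaging_depth()`; the two numbers are deliberately not reconciled
because they measure different things — a digitisation convention versus a
Nyquist bound.

Reconstruction (`reconstruct_ascan()`) follows the standard chain:
background/DC removal (reflect-padded moving average), cubic resampling
from uniform wavelength to uniform wavenumber, Hann apodization,
zero-padding to twice the record length, inverse FFT, one-sided magnitude
(1024 bins, matching the printed B-scan geometry), and 20·log10 compression
floored at −80 dB. The round trip synthesize → reconstruct localizes any
in-range reflector within one depth pixel; the test suite verifies this
against a brute-force discrete-Fourier oracle that never touches the FFT
path.

## The seed phantom

`phantom_config()` describes a layered seed in a 6 mm × 2.2 mm B-scan
window: a convex testa surface (apex 400 µm optical, curvature
12 µm/mm²), the coat/cotyledon interface at an optical distance of
*physical thickness × 1.42* below it (1.42 being the accepted refractive
index of pea seed coat), weak volume scatter inside coat and tissue, and
four time-gated features — surface wrinkles (camera), cotyledon layers on
both flanks, a central subsurface radicle blob whose amplitude is capped
at 0.9× the surface peak, and a seed-coat crack rendered as a 200 µm
surface gap beside a ≥5-pixel coat-flap displacement. Speckle is
multiplicative exponential-intensity noise applied on linear intensity
before log compression, parameterized by contrast (default 0.5);
attenuation is exponential in depth (0.9 mm⁻¹ on amplitude). Published
seed-OCT studies report no noise, attenuation, or reflectivity values, so
these are fixed once as plausible for seed tissue and are not fitted to
anything.

The default coat-thickness trajectory is a shape-preserving (PCHIP)
interpolation through the reference 3-hourly table of mean thicknesses
(112 µm at 3 h rising to 197 µm at 36 h), extended flat-ish to 0 h and
40 h; by construction it passes through every tabulated mean. Lateral
unevenness of the coat is a *frozen* per-seed random profile (six Fourier
modes, zero mean, unit variance across the seed span) whose amplitude
follows the tabulated per-time spread — largest at 9–15 h, when the
imbibing coat is most uneven. Freezing the profile and centring it to
zero mean keeps the lateral *mean* thickness exactly on the reference
curve, so spread and mean can be validated independently.

The gravimetric model is triphasic: saturating imbibition
$w_0 + A_1(1 - e^{-t/\tau_1})$ until the radicle event, a near-plateau
with a small drift during the lag phase, and renewed saturating uptake
after the crack. Defaults ($w_0 = 0.30$ g, $A_1 = 0.15$ g, $\tau_1 = 7$ h,
drift 0.004 g/h, post-crack gain 0.03 g with $\tau_3 = 6$ h, 0.5 %
multiplicative noise) were chosen under the generator's stated design
constraint: weight, coat thickness and diameter are all monotone
saturating curves, so that the cohort-level correlation of either
image-derived series with weight exceeds 0.95 — the structural property
the real measurements exhibit. Weighing follows the standard protocol:
every 30 minutes for the first 10 h, then every 5 h.

The camera model draws the seed disc (diameter growing from 5.0 to
6.6 mm) at 644 × 482 px over an 11 mm field (11/644 mm/px, square pixels
assumed — the nominal field implies slight anisotropy that the source
hardware description leaves unresolved), adds a water-surface shadow band
below the configured water line, and perturbs the disc boundary
sinusoidally once the wrinkle event occurs.

## Estimators

**Coat thickness.** The reference workflow marks 60 points on the surface
and 60 on the coat interface, equally spaced laterally, fits each set with
a PCHIP curve, and takes the distance between the curves divided by the refractive
index. `pick_boundary_points()` automates the marking:
at each position it averages 5 adjacent columns in linear intensity,
smooths axially over 3 pixels, and picks depth peaks by topographic
prominence (≥ 6 dB) with a minimum separation of one axial resolution;
sub-pixel positions come from a three-point parabola on the log profile
(exact for Gaussian line profiles). The surface is the first peak rising
10 dB above the air level; the interface is the next prominent peak at
least 30 µm (optical) below it — the minimum-gap rule prevents a
step-displaced second surface image beside a coat crack from being
mistaken for the interface, at the cost of declaring coats thinner than
~21 µm physical unresolvable (they are near the axial resolution limit
anyway); positions without a valid pair are flagged and excluded. Thickness is
measured *vertically* (along the depth axis), not normal to the surface:
an A-scan reports depth along the beam, so the between-arrow distance on
an averaged profile is inherently a vertical measure, and the boundary-fit
estimate keeps the same convention. Users can supply manually marked CSV
point files instead. Quartiles use linear-interpolation quantiles and
whiskers extend to the most extreme data within 2 × IQR of the quartile
box — the whisker convention of the boxplots this analysis produces.

**Indicators.** Four morphological events segment germination:
surface wrinkles (camera roughness exceeding the first-five-frame baseline
mean + 3 sd, strictly), cotyledon layers (a persistent new subsurface peak
at *both* flank positions, lateral fractions 0.25/0.75 of the seed span),
radicle emergence (a persistent new subsurface peak in the central
20-average A-scan, deeper than the surface peak and not exceeding its
amplitude), and coat cracking (a surface-pick discontinuity: ≥3
consecutive missing positions or an adjacent-position depth jump strictly
greater than 5 axial pixels). All detectors require the feature to persist
for 2 consecutive frames — the visual persistence a human rater applies,
made explicit —
so single-frame speckle transients are never called. Onset resolution is
therefore the acquisition cadence (10 min by default). Phase I runs to the
radicle onset, phase II to the crack onset, phase III to the end of the
record.

**Correlation.** Series sampled on different grids are aligned by linear
interpolation onto the *coarser* grid restricted to the common span
(weight is the coarsest, so image-derived series are brought to the
weighing schedule), and the product-moment coefficient is computed
directly from its definition; the suite checks it against a brute-force
two-pass oracle at 1e−12 relative and against `stats::cor`. Cohort-level
values use cohort means; whether the published single-number correlations
pooled seeds or averaged them first is unstated, so means were chosen and
per-seed values are also available. The pass flag demands r > 0.95 —
positive tracking — because an anti-correlated series, however strong,
does not validate the method.

## Numerical choices and degenerate inputs

* PCHIP is `pracma::pchip` (MATLAB-compatible Fritsch–Carlson
  derivatives); curves need ≥4 points, reject duplicate abscissae, and
  refuse extrapolation beyond the control-point span.
* Negative thickness (crossing curves) is flagged per position, never
  clipped silently.
* The log floor is −80 dB relative to the frame maximum; A-scan averaging
  always happens in linear intensity.
* The Canny chain (Gaussian σ = 1.4 px, Sobel pair, bilinear-interpolated
  non-maximum suppression, hysteresis at 0.1/0.2 of the maximum gradient
  with 8-connected linking) reproduces the reference implementation's
  edge maps exactly on rasterized discs; edge counts on a digital circle
  run ~10 % above 2πr, which is a property of rasterization, not an
  implementation defect.
* RGB segmentation uses inclusive per-channel bounds 62/45/30–255 ANDed
  together — the stricter reading of a mask "created from" three
  binarizations — followed by largest-component selection above the water
  line (default 70 % of image height).
* All randomness is derived from one 31-bit master seed; identical
  configurations render bit-identical frames.

## What the synthetic tests do and do not show

Passing recovery tests demonstrates that the estimators are unbiased and
event-accurate *under the generator's assumptions*: ideal Gaussian line
profiles, stationary speckle, a seed that never drifts laterally, and
events that switch on instantaneously. Real B-scans add refraction at the
curved surface, depth-dependent focus and sensitivity roll-off, motion,
and biological variability between seeds, none of which the generator
emulates (it is not a light-transport simulation). Published values
measured on real seeds — e.g. a weight–thickness correlation of 0.951 —
are therefore not reproducible from synthetic data; what the pipeline
reproduces is the *structure* of those results: thickness recovered to
within a few micrometres of its true trajectory, the 9–15 h spread excess,
indicator onsets at cadence resolution with zero false positives at
default thresholds, and cohort correlations above the 0.95 threshold.

## Problem sizes used by the tests

The packaged test-suite runs the full 240-frame, 40-hour schedule with
reduced image geometry (240 lateral columns; a 1.1 mm depth window at the
native 2.148 µm axial pixel for the long time-series properties, so every
depth-pixel threshold is unchanged), 20-phantom Monte-Carlo batches for
thickness recovery, and 100-replicate batches for speckled picking. The
acceptance script runs the full-size 1024 × 1000 geometry end to end.
These sizes are the package's own choice of desk-scale experiment; all
thresholds, tolerances and generator defaults are identical to the
full-size configuration.
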