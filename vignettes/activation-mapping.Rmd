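---
title: "3D activation mapping of cardiac organoids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D activation mapping of cardiac organoids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmea)
```

This vignette documents the models and numerical choices behind the
package: what each pipeline stage computes, which parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where the genuinely open design decisions
were made.

## The measurement model

A shell MEA wraps a roughly spherical cardiac organoid of radius $r$
(default 250 µm) with 16 unipolar electrodes on three rings: four near
the bottom, eight on the equator, four near the top. The polar rings sit
at ±45° latitude by default — the device geometry only fixes them "near"
the poles, so the ring latitude is a layout parameter
(`shell_layout(ring_lat_deg=)`), serialised explicitly in the layout
JSON (degrees, radius in µm).

Each electrode sees the extracellular field potential of the tissue
beneath it. When a depolarisation wavefront passes, the unipolar
waveform encodes the electrode's position relative to the front: at the
activation origin the deflection is purely negative, mid-path it is
biphasic (positive as the front approaches, negative as it recedes), and
distally it is predominantly positive. The **local activation time
(LAT)** is the steepest negative downstroke, which tracks the moment of
depolarisation regardless of waveform polarity or amplitude — this is
why the pipeline's default LAT detector is slope-based, with the
amplitude-extremum detector retained only for comparison.

## Electrophysiology pipeline

**Preprocessing.** Recordings at 30 kHz are anti-alias filtered
(4th-order Butterworth at 0.8× the output Nyquist), decimated to 10 kHz
(non-integer ratios fall back to linear-interpolation resampling), then
low-pass filtered (Butterworth order 4, default 1000 Hz; 100 Hz is the
documented alternative for recordings with strong interference) and
notch filtered at 60 Hz (biquad, Q = 30). All filters run zero-phase
(forward–backward): causal filtering would delay every LAT by the group
delay and corrupt activation ordering. Signals are odd-reflection padded
before filtering so the notch's long ring-down (≈ Q/πf₀ ≈ 0.16 s)
decays in the padding rather than in the data. Filter family, order and
phase handling are not dictated by the measurement itself; these are
this package's defaults, and all are configurable.

**Beat detection.** Beats are detected on the channel-summed nonlinear
energy operator, NEO[x](n) = x(n)² − x(n−1)x(n+1), which concentrates
the transient energy of the sharp depolarisation complex. The raw NEO of
broadband noise is heavy-tailed, so the trace is first smoothed with a
5 ms moving average, making its noise floor near-Gaussian; the detection
threshold is then `median + k·(MAD/0.6745)` with k = 8 by default, with
a floor of 5% of the trace maximum. The floor handles two degenerate
regimes honestly: in (near-)noiseless recordings the robust scale
collapses to zero and, without a floor, low-energy repolarisation humps
(four orders of magnitude below depolarisation NEO energy) would be
"detected"; in noisy recordings the signal×noise cross term elevates the
NEO around repolarisation above the noise-only robust scale. Detected
peaks are kept greedily by magnitude under a 200 ms refractory period;
each beat gets a [−50, +150] ms analysis window.

**LAT extraction and ordering.** Within each window, slope-LAT is the
argmin of the central-difference derivative (ties break to the earliest
sample; no extra smoothing — the low-pass filter is the smoother);
amplitude-LAT is the extremum of |x|. Relative latencies per beat are
referenced to the first-activating channel. The activation-order
*accuracy* is the fraction of (electrode, beat) pairs whose within-beat
rank equals the rank of the electrode's mean LAT; the confusion matrix
counts electrodes by rank, so each beat contributes one permutation and
rows and columns both sum to the number of beats. This exact-rank metric
is one reasonable formalisation of ordering consistency; others (e.g.
rank correlation) would be monotone-related but numerically different.

**Waveform metrics.** Amplitude is peak-to-peak voltage within beat
windows; beat rate is 60 / mean interbeat interval of the channel's
LATs; FPD is the time from LAT to the *dominant* |x| extremum in a
search interval starting 50 ms after the LAT (blanking the
depolarisation complex) and ending 50 ms before the next beat. Taking
the dominant rather than the first local extremum is deliberate: noise
creates spurious early local extrema, while the repolarisation peak is
the prominent one. SNR is amplitude divided by the standard deviation of
all samples outside the beat windows; the windows passed to
`compute_snr()` should span depolarisation *and* repolarisation,
otherwise repolarisation energy inflates the noise estimate.

## Spherical isochrone and conduction-velocity mapping

Electrode LATs are interpolated onto a latitude–longitude grid (default
64 × 128, nodes offset half a step so none sits on a pole) with
normalised inverse-quadratic radial basis functions of the haversine
geodesic distance:

$$\widehat{T}(p) = \frac{\sum_i w_i T_i}{\sum_i w_i},\qquad
  w_i = \frac{1}{1 + (d(p, p_i)/\epsilon)^2}.$$

This is a smoother, not an exact interpolant: every value is a convex
combination of the 16 node LATs (asserted as an invariant), weights
never underflow, and the result is rotation-equivariant. The shape
parameter ε defaults to the mean nearest-neighbour electrode spacing
(≈ 0.02 cm for the standard layout) — small enough that each electrode
dominates its neighbourhood, large enough that the surface stays smooth;
it is the main tuning knob and is deliberately explicit everywhere.

Conduction velocity comes from finite differences of the gridded LAT
field: ∇x = (T_east − T_west)/(2·Δd_east) with Δd_east = r·cos φ·Δλ
(the cos φ metric factor corrects east–west arc lengths away from the
equator; `metric_correction = FALSE` disables it for comparison with
implementations that do not correct), ∇y likewise with Δd_north = r·Δφ;
longitude wraps periodically and the top/bottom rows use one-sided
differences. The gradient direction is the unit CV vector; the *speed*
is taken as the inverse gradient magnitude — the normalisation defines
only the direction, so the magnitude rule is a package decision,
consistent with reporting CV in cm/s. Nodes with gradient magnitude
below (1 ms)/(πr) per cm are masked (a front that crosses the whole
hemisphere in under a millisecond is indistinguishable from a flat
field at these noise levels); a constant map masks everything, with a
warning rather than an error.

**A bias worth knowing about.** On a dense LAT field the
finite-difference speed estimate is essentially exact (the tests recover
5 cm/s to 0.02% with direction errors of hundredths of a degree). On the
*16-electrode interpolated* map, however, normalised-RBF smoothing
shrinks the LAT range (≈ 3× at the default ε), so gradients are
underestimated and speeds overestimated — the worked example reads
≈ 11.6 cm/s median for a true 5 cm/s wave. This is inherent to
smoothing-based interpolation at 16 samples, is worst near the
activation origin and antipode (hence the convention of excluding nodes
within 20° of both when summarising speeds), and shrinks as ε decreases
or electrode count grows. Speed summaries quoted from 16-electrode maps
should therefore be treated as upper bounds and compared across
conditions at fixed ε, not read as absolute conduction velocities.

Maps and CV fields export as legacy ASCII VTK polydata (quad sphere
mesh, point scalars `LAT`, point vectors `CV` as 3D Cartesian tangent
vectors), round-trippable with the bundled minimal reader.

## Calcium-imaging pipeline

Movies (default 60 Hz) are masked by per-pixel temporal dynamic range
(threshold: fraction of the movie's maximum range, default 0.5) minus
any known occlusion geometry (electrode footprints). Each kept pixel's
trace is the 3 × 3 local spatial mean; baseline is the trace's 10th
percentile (the half-maximum rule needs a baseline, and a low percentile
is robust to both noise and long plateaus); the pixel LAT is the first
crossing of baseline + 0.5·(max − baseline), linearly interpolated
between frames — sub-frame accuracy for any smooth upstroke, and
invariant to gain and offset by construction. The LAT image is then
downsampled by non-overlapping 5 × 5 *max* pooling (windows with no
valid pixel stay invalid). Max pooling biases each window toward its
latest activation; mean pooling is available behind `fun = "mean"` for
sensitivity analysis, with max as the default downsampling rule.

Each pooled pixel is smoothed by a local least-squares quadratic
T(x, y) = a + bx + cy + dx² + exy + fy² over a window of 600 µm
(converted to pooled pixels; at least 6 valid neighbours or the pixel is
dropped), the smoothed value being the constant term a (the fitted
surface at the window centre). Planar CV uses central differences of the
smoothed map divided by the pooled pixel pitch, direction-normalised,
speed = inverse gradient magnitude in cm/s. A quadratic input is
reproduced with zero residual (least-squares exactness on the model
class), a planar wave's speed is recovered to well within the pooling
and frame-rate resolution, and doubling the assumed pixel size exactly
doubles the speed.

## Cross-modality comparison

A fluorescence microscope sees one hemisphere, so the 3D map is reduced
to the matching view: the LATs are re-interpolated using only the 12
electrodes of that hemisphere (8 equatorial + 4 polar-ring) and
orthographically projected along the polar axis onto a pixel grid. The
projection is analytic — each pixel centre maps to its point on the
sphere and the interpolant is evaluated there — rather than recovered
from rendered screenshots; this removes any renderer/colormap round
trip while producing the same map content. Maps are compared over
co-valid pixels by Pearson correlation (offset-invariant) and by mean
absolute error expressed as a percentage of the *reference* map's LAT
range; the normalisation basis matters (MAE % is asymmetric in its
arguments) and is stated explicitly in every report.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Wavefront**: a single focal origin with constant-speed geodesic
  expansion (default 5 cm/s on r = 250 µm, so the origin-to-antipode
  transit is πr/v ≈ 15.7 ms), repeating every 1.25 s (48 bpm). The
  default origin, (−0.5734, 3.2322) rad, is a generic point chosen so
  the 16 electrode latencies are well separated (minimum gap ≈ 0.58 ms)
  — a symmetric origin would create exactly tied latencies and make
  "activation order" ill-defined. Optional per-beat origin jitter
  (`origin_jitter`, radians) emulates beat-to-beat wavefront
  variability; it changes both the true per-beat LATs and, through the
  activated fraction, the waveform morphology.
* **Waveforms**: the depolarisation complex is an amplitude-weighted
  mixture of a positive Gaussian lobe centred at −σ and a negative lobe
  at +σ (σ = width/4; default width 3 ms, a typical cardiac
  field-potential spike), mixed by the activated surface fraction
  f = (1 − cos(d/r))/2. The construction has a provable property that
  makes it a fair test bed: the steepest negative slope sits exactly at
  the true activation time for *every* f, while the amplitude extremum
  shifts by ≈ ±σ with morphology. Slope detection is therefore unbiased
  across the electrode population and amplitude detection is not —
  which is the physiological argument for slope-based LAT, reproduced
  in one parameter. Repolarisation is a low, wide Gaussian (25 µV,
  σ = 30 ms) centred `fpd_true` (default 300 ms) after each activation,
  giving FPD detection a well-defined target.
* **Noise**: white Gaussian noise plus a 60 Hz sinusoid, all randomness
  derived from one seed with per-channel sub-streams (identical seeds
  give bit-identical recordings). Noise levels are quoted as the
  *nominal recording SNR* — mean depolarisation peak-to-peak amplitude
  divided by the injected noise sd, i.e. a property of the raw 30 kHz
  recording before any filtering. The preprocessed SNR measured by
  `compute_snr()` is higher, since the filters remove most broadband
  noise power.
* **Calcium movies**: the visible hemisphere is orthographically
  projected; each in-organoid pixel's fluorescence rises logistically
  (crossing half-maximum exactly at the projected true activation time,
  rise time 40 ms), then decays exponentially (400 ms); occluded and
  background pixels stay at baseline. An exactly planar wave generator
  provides a linear ground-truth LAT image for CV validation.
* **Drug effects**: multiplicative factors on beat rate, amplitude, FPD
  and conduction speed (e.g. an isoproterenol-like positive
  chronotrope/inotrope as rate ×1.84, amplitude ×1.81, FPD ×0.80).

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: electrode-to-tissue coupling
variability and drift, far-field components and fractionated
electrograms, motion artefacts and photobleaching in the optical
channel, non-spherical organoid geometry, multiple or reentrant
wavefronts, and beat-rate variability beyond origin wobble. Results on
real recordings will degrade in proportion to how far those effects
dominate.

## Validation conditions and problem sizes

The test suite validates, among others: LAT recovery on one-minute
60 s/30 kHz recordings (mean error ≈ 0.1 ms at nominal SNR 10, well
under the 0.5 ms requirement; exact activation ordering at nominal SNR
20), slope-vs-amplitude ordering accuracy paired over 20 seeds with
origin jitter 0.1 rad, the interpolation oracle on 1000 random query
points at 10⁻¹² s, CV recovery within 10% with median direction error
far below 10° (excluding 20° caps at origin/antipode), the calcium
pipeline at 60 Hz (per-pixel LAT error a small fraction of a frame,
planar CV within 15%, exact quadratic-fit recovery), cross-modality
Pearson r ≈ 0.99 for matched simulations, and metric/drug-factor
recovery within 2%/2 ms/5%. Grids of 64 × 128, 128-pixel movies and
8–47-beat recordings keep each of these runs in seconds to a couple of
minutes on a single CPU; all sizes are parameters, and scaling them up
changes run time, not code paths.

## Known limitations

* Speeds from 16-electrode interpolated maps carry the smoothing bias
  discussed above; the package reports them, but dense-field routes are
  the ground for absolute numbers.
* The FPD search assumes one dominant repolarisation deflection between
  beats; heavily fractionated or biphasic repolarisation would need the
  search window tightened per recording.
* The 60 Hz notch slightly perturbs the repolarisation plateau (its
  ripple can move the detected FPD peak by ~1 ms on noiseless data);
  disable the notch when line interference is absent.
* Max pooling of activation times is faithful to the stated
  downsampling rule but biases pooled LATs late by up to one window's
  internal spread; use mean pooling to bound the effect.
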