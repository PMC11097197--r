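---
title: "Synthetic femoral-flow phantoms and vector-flow analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic femoral-flow phantoms and vector-flow analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoveloc)
```

## Scope and intent

`hemoveloc` implements a benchmarking pipeline for two-dimensional vector
flow imaging of the femoral bifurcation: synthetic pulsatile phantoms with
known ground truth, multi-pass cross-correlation particle image velocimetry
(PIV) in optical-style and echo-style (ultrasound contrast agent) variants,
singular-value-decomposition (SVD) clutter suppression, vector-derived
hemodynamic parameters, and Bland–Altman agreement statistics between
modalities. Experimental recordings of this kind are rarely shareable, so
the synthetic generator is a first-class module: it defines the study
conditions under which every claim in the test suite is evaluated.

Units are fixed at the interfaces throughout: lengths in mm, time in s,
velocity in cm/s, volumetric flow in mL/s, wall shear stress in Pa.

## The triphasic inflow waveform

Peripheral arteries show a triphasic flow pattern: a strong systolic forward
lobe, an early-diastolic backflow phase, and a weak late-diastolic forward
phase. The generator represents each lobe as a raised cosine, which makes
the waveform C1-smooth and strictly periodic with only a handful of
parameters. The calibration targets are volumes, not shapes: the positive
part of the cycle integrates to the forward volume (default 9.6 mL at 1 Hz)
and the negative part to the backflow volume (default 2.3 mL). Amplitudes
are first set from the closed-form lobe integral and then rescaled once
against the trapezoidal integral on the actual sample grid, so the volume
calibration is exact to machine precision on the grid the user receives.

The lobe fractions are free parameters. The defaults (systole 30% of the
cycle, backflow 20%, late-diastolic share 15% of forward volume) were chosen
once so that the systolic peak lands near 54 mL/s, the peak systolic flow
rate of the in vitro condition the phantom emulates. The true experimental
waveform shape is not recoverable from published material; this generator is
a calibrated surrogate, not a replica, and conclusions that depend on fine
waveform morphology (e.g. exact phase timing of flow reversal) should not be
drawn from it.

The bifurcation outflow split is proportional and time-invariant by default
(44% superficial femoral share of the mean), which reproduces the mean split
exactly while ignoring the compliance-driven phase differences a physical
Windkessel circuit would add; a measured branch waveform can be supplied
instead.

## Womersley and Poiseuille profiles

Fully developed pulsatile pipe flow is reconstructed per Fourier harmonic of
the flow waveform. Harmonic k at angular frequency omega_k has Womersley
number `alpha_k = R sqrt(omega_k / nu)` and velocity profile proportional to
`1 - J0(Lambda xi) / J0(Lambda)` with `Lambda = i^(3/2) alpha_k` and
`xi = r/R`; the amplitude is set so the cross-sectional integral of the
profile equals that harmonic of the flow. The steady term is the Poiseuille
paraboloid with centerline velocity `2 Q / (pi R^2)`. The same per-harmonic
factors, inverted, convert a centerline velocity series into a flow
waveform, which is how the package emulates the Doppler-ultrasound route to
volumetric flow; a multiplicative bias knob (default 1, never silently
applied) lets users emulate the documented 10–50% peak-velocity
overestimation of clinical Doppler.

`J0` and `J1` at complex argument are evaluated with the integral
representation `J_n(z) = (1/pi) int_0^pi cos(n t - z sin t) dt` using a
200-node Gauss–Legendre rule. At the argument magnitudes reached by 20
harmonics of a femoral-scale flow (|z| up to about 26) this is accurate to
near machine precision and avoids the cancellation that the power series
suffers from; no installed R routine evaluates Bessel functions at complex
argument. Twenty harmonics reproduce the default waveform's flow to about
0.2% RMS through the forward/inverse round trip; no-slip is enforced exactly
at the wall nodes.

## The stenotic-jet phantom field

The stenosed configuration needs a ground-truth field with the qualitative
features of post-stenotic flow: a contraction, a jet whose mean velocity
follows continuity (`inlet / (1 - area reduction)`; a factor 4 at the
default 75% area reduction), and recirculation beside the jet. The field is
an analytic surrogate built from a streamfunction on a 2D slice: the lumen
half-width narrows as a Gaussian at the stenosis, and the cross-stream shape
of the axial velocity blends from a parabola into a jet profile with
negative side lobes downstream of the throat, decaying over a configurable
jet length. Velocities are obtained by central differences of the
streamfunction, so the discrete divergence vanishes identically and the
cross-sectional flux is conserved along the vessel to well under 1% at the
default 0.2 mm grid.

Two deliberate simplifications: the slice is planar rather than
axisymmetric, with the volumetric rate mapped to a 2D flux such that the
straight-section centerline velocity matches the axisymmetric Poiseuille
value (`flux = (8/3) Q / (pi R)`); and the jet is steady in shape (its
strength follows the waveform) rather than transitional. The field is meant
to exercise the measurement chain — rendering, PIV, vector complexity — with
known truth, not to model jet breakdown physics, which only a flow solver
can provide.

## Particle rendering and clutter

Tracer particles are seeded uniformly over the lumen at 0.05 particles per
pixel squared (the common synthetic-PIV operating point; about 13 particles
in a 16 px window) and rendered as Gaussian blobs of 3 px apparent diameter
(`sigma = d/2.355`). Between frames, positions are advected with a midpoint
(second-order Runge–Kutta) step of the locally interpolated velocity over
one frame interval; for uniform flow this is exact. Particles leaving the
domain or lumen are re-seeded at the upstream edge so density is stationary.
All randomness in a call sits behind one integer seed, and repeated calls
are bitwise identical.

The clutter generator emulates the tissue signal that dominates raw
contrast-enhanced ultrasound data. It injects a band-limited speckle pattern
modulated by a common echogenicity envelope, with lateral motion represented
by the Taylor expansion of translation (pattern, first, second spatial
derivative) so the injected Casorati matrix has numerical rank at most the
requested bound by construction. Static clutter is exactly rank 1.
Amplitudes should be chosen 20–40 dB above the tracer signal to mimic the
tissue-to-blood ratio of real acquisitions; the filtering benchmarks in the
test suite use roughly +40 dB. The injected component is returned alongside
the frames, so filters can be scored against exact truth.

## PIV design

The correlator is zero-mean normalized cross-correlation evaluated by FFT
with zero padding to twice the window and per-lag overlap normalization.
The padding matters: plain circular correlation of linearly shifted window
contents carries a triangular envelope over the lag plane that biases the
subpixel peak toward zero displacement by several hundredths of a pixel per
pixel of displacement; dividing by the per-lag overlap removes it. Subpixel
position comes from the standard three-point Gaussian fit per axis, with a
parabolic fallback when a neighbor is non-positive. The peak search is
restricted to a quarter window, the usual displacement budget per pass.

Multi-pass refinement follows the community default: each pass interpolates
the previous displacement field to the finer grid and applies it as an
integer symmetric window shift (half to each frame). Window deformation is
deliberately omitted — an accuracy-affecting simplification in strong
gradients, noted here because near-wall and jet-edge errors inherit it.
Between passes, outliers are flagged by the normalized median test
(threshold 2, regularization 0.1 px) and replaced by the median of valid
neighbors. Edge windows extending past the image or below 50% lumen
coverage are flagged invalid rather than zero-padded.

Two pairing conventions are fixed by the output rates they must reproduce:
the optical pipeline pairs frames non-overlappingly (8000 fps giving 4000
raw fields/s, then 400 fields/s after the 10-ensemble average), and the echo
pipeline pairs sliding frames with correlation averaging over blocks of 10
planes (9000 fps compounded over 3 angles to 3000 fps, giving 300 fields/s).
The echo postprocessing order — 3x3 Gaussian spatial filter, then temporal
moving average — is a convention choice; the filters nearly commute on
smooth fields. The final vector spacing follows the grid law
`last window x (1 - overlap) x pixel size` exactly (0.42 mm for the optical
preset at 0.0525 mm pixels).

## SVD clutter filtering

Frames are reshaped into the Casorati matrix (pixels x frames) and
decomposed by thin SVD, one contiguous acquisition block at a time.
Filtering retains components in `(low, high]`. Because the basis is
data-dependent, the filter is only linear for a fixed decomposition; the
function therefore accepts a precomputed decomposition, in which case it is
the exact projector onto the retained subspace (and exactly additive across
sequences sharing it).

Threshold selection is the semi-automatic step. The spatial similarity
matrix holds absolute correlations between the magnitudes of spatial
singular vectors: tissue components concentrate energy in the same region
and are mutually similar, so they form a leading high-similarity block. The
lower threshold is set to the end of the uninterrupted leading run of
components whose similarity to the first component stays at or above 0.3. A
running-mean variant of this rule was tried first and discarded: anchored by
the perfect self-similarity of component 1, its average stays above any
reasonable threshold for several components after the clutter block ends and
systematically overshoots the known rank of injected clutter. If the
singular spectrum is flat (no dominant subspace at all), the detector warns
and returns the identity thresholds; on injected rank-3 clutter it lands
within one of the true rank across seeds. The criterion remains a stand-in
for the published semi-automatic procedure, whose details live outside this
package; both thresholds can always be set manually and are logged in the
run manifest.

## Hemodynamic parameters

Flow rate from a diameter profile follows
`Q = pi int_{-R}^{R} u(r) |r| dr` (trapezoidal, native grid), which is
precisely the average of the two half-diameter axisymmetric estimates.
Profiles that stop short of the wall are linearly extrapolated to zero with
a warning.

Vector complexity (VC) is one minus the resultant length of the unit vectors
of flow direction: 0 for unidirectional flow, approaching 1 for isotropic
direction spread. Vectors below 1e-6 cm/s are excluded because the angle of
a null vector is undefined; if a region contains only such vectors VC is
reported missing. VC is invariant under uniform magnitude scaling and under
global rotation, both verified as properties in the suite. The two-argument
arctangent convention (y first) is fixed and immaterial to VC, which is
invariant to an axis swap.

Wall shear stress samples the wall-parallel velocity at 8 points over 2 mm
along the inward normal (bilinear interpolation), fits a weighted cubic
polynomial constrained through zero at the wall, and takes
`WSS = mu du/dn` at the wall; TAWSS is the time average of |WSS|. Weights
grow linearly with wall distance, down-weighting the least reliable
nearest-wall sample. A cubic smoothing spline was considered and rejected:
with 8 samples the two coincide in practice and the polynomial is stable.
The sign convention (average of magnitudes) and the weighting are stand-in
choices where the field's practice varies; on steady Poiseuille at grid
spacing R/10 the estimate is within 10% of `2 mu u_max / R` (about 0.1% at
the default settings, the 10% bound covering coarse grids).

Reynolds number (`v rho L / mu`) and the Kolmogorov length
(`l_c Re^(-3/4)`) are unit-agnostic one-liners; the worked femoral-jet
example (mean velocity 1550 mm/s, diameter 8.9 mm, density 1.14e-6 kg/mm^3,
viscosity 4.16e-6 kg/mm/s) gives Re = 3780 and a Kolmogorov length of
0.0185 mm.

## Agreement statistics

Cycles are aligned at peak systole, located as the maximum of spatial-mean
speed with a 0.6-period minimum peak separation and earliest-sample
tie-break; each cycle is cropped to one period around its peak, resampled to
100 normalized time points, and averaged per node, with the across-cycle SD
stored. Only cycles whose full window lies inside the record are used.
Ensembles are compared after bilinear spatial and linear temporal resampling
onto the reference grid; nodes outside either lumen are excluded pairwise
and counts are always reported. Differences are taken between velocity
magnitudes (not components), pooled over nodes and time points (or the
peak-systole sample alone), and summarized as mean, SD, and limits of
agreement `mean +/- 1.96 SD`, with per-node mean and SD maps alongside.
Because differences are of magnitudes, near-zero speeds fold noise into a
positive bias; the noise-recovery property in the test suite therefore uses
a high-signal construction where folding is negligible, and users comparing
low-speed regions should expect the same effect in real data.

## What the synthetic conditions do and do not show

Passing tests demonstrate that the measurement chain — rendering, clutter
filtering, correlation, validation, derived parameters, agreement — is
internally correct against analytic truth under ideal imaging: linear
intensity, no point-spread blur, no attenuation, no speckle decorrelation,
rigid walls, steady jet shape. They do not certify accuracy on real optical
or ultrasound recordings, where point-spread smoothing, compliance-driven
timing offsets, and transitional jet dynamics dominate the error budget.
The directional claim that post-stenotic recirculation elevates VC relative
to a straight-tube control is exercised end-to-end (field, rendering, PIV,
VC) and is robust; the numeric VC and TAWSS levels of any real experiment
are data-bound and outside what synthetic conditions can reproduce.

## Problem sizes and runtime

The test suite and the demonstration configuration run at desk scale by
design: images of roughly 120–200 px per side, 4–24 frames, grids of
0.2–0.5 mm, 100–2000 waveform samples. These sizes keep the full suite
under a minute while leaving every algorithmic path — multi-pass refinement,
correlation averaging, SVD filtering, ensemble statistics — identical to
what larger runs would execute; all sizes are parameters, and nothing in the
implementation assumes them.
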