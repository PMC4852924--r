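---
title: "Simulating low-field MRI acquisitions from high-field k-space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating low-field MRI acquisitions from high-field k-space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowfieldsim)
```

## The model

MRI signal amplitude grows with the square of the main field strength
(polarisation and induction each contribute one factor of B0), while under
body-noise dominance the thermal noise standard deviation grows linearly with
B0 and with the square root of the readout bandwidth. Writing
`a = B0_low / B0_high` and `b = BW_low / BW_high`, an acquisition
`y = s + n` measured at the high field can be converted into a statistically
correct acquisition at a lower field:

* the pure signal becomes `a^2 * f * s`, where `f` is a relaxation-correction
  factor accounting for the different steady-state weighting at the two
  fields (below);
* the per-component channel noise covariance must become `a^2 b * Sigma`,
  where `Sigma` is the covariance of the real (equivalently imaginary) part
  of the channel noise at the high field.

Because the source noise `n` is inseparable from `s`, the simulator scales
the whole measurement and *adds* fresh correlated noise:

```
y_low = a^2 f y + n_add,   Var(n_add) = (a^2 b - a^4 f^2) Sigma   (per component)
```

so the total simulated noise covariance is exactly `a^2 b Sigma`. The added
variance must be non-negative: `a^2 b >= a^4 f^2` is a hard feasibility
precondition, checked by `derive_scaling()` / `field_scaling()`, whose error
reports the minimum feasible bandwidth ratio `b = a^2 f^2`. Noise is added
only on acquired (masked) k-space positions; lines that were never acquired
stay exactly zero, as they would in a real partial-Fourier acquisition.

The model rests on assumptions the package states but cannot check from the
data alone: body-noise dominance (questionable below ~0.1 T and for small
coils), unchanged transmit and receive fields and noise covariance across
fields, unchanged B0 homogeneity in ppm, a single dominant species or
proton-density weighting, and steady-state acquisition.

## The relaxation correction factor

`correction_factor()` computes `f` as the ratio of low- to high-field
steady-state signal (excluding the B0^2 amplitude prefactor, which the
simulator applies as `a^2`), per echo:

* **Spin echo**: saturation term `(1-E1) sin(theta) / (1-E1 cos(theta))`
  with `E1 = exp(-TR/T1)`, times `exp(-(TE_l/T2_l - TE_h/T2_h))`. T2 is
  treated as field-independent by default (it varies little over 0.1-3 T),
  but each side carries its own `tissue_params` and may override it.
* **Spoiled gradient echo**: the same with T2* in place of T2. T2* is built
  from a single identifiable rate, `1/T2* = 1/T2 + r2prime_per_tesla * B0`.
  When T2* is unknown, `gre_t2_fallback = TRUE` substitutes T2; this
  *underestimates* the low-field signal whenever `B0_l TE_l <= B0_h TE_h`
  (the susceptibility-dephasing exponent only shrinks), so the simulated SNR
  is a conservative lower bound, and the function refuses the fallback when
  the ordering is violated.
* **Balanced SSFP**: ratio of `sin(theta) / (1 + cos(theta) +
  (1-cos(theta)) T1/T2)`. With equal flip angles the `sin` factor is
  cancelled symbolically, so `theta = 180` degrees yields `f = T1_h/T1_l`
  rather than 0/0. The expression is the on-resonance pass-band
  approximation, valid for TE, TR much below T1 and T2; a warning fires when
  `TR > T2/4`. No flip-angle validity limit is enforced.
* **Inversion recovery** (90-degree excitation):
  `(1 - 2 exp(-TI/T1) + exp(-TR/T1))` ratio times the TE decay; when the
  high-field species is nulled (denominator within 1e-9 of zero) the
  correction is undefined and an error is raised.

In the proton-density-weighted limit (TE << T2 and either TR >> T1 or a
small flip angle), SE/GRE reduce to `f = sin(theta_l)/sin(theta_h)`
regardless of the species — the reason a single global correction remains
valid for multi-species PDw imaging. For the real-time airway protocol
(5-degree flip, TE 2.6 ms, TR 4.6 ms, equal parameters at both fields)
this gives `f = 1` to better than 1e-3.

T1 lengthens with field. The simulation requires T1 to be *supplied* at both
fields; `t1_dispersion()` offers the common power law
`T1(B0) = T1_ref (B0/B0_ref)^beta` as a convenience, but it is never applied
implicitly because the exponent is tissue-specific.

### The Bloch-iteration oracle

`bloch_steady_state()` validates the closed forms independently: it
propagates the magnetization TR by TR (rotation, relaxation, ideal spoiling
or refocusing per family; alternating-sign pulses for bSSFP) and reads the
transverse magnitude at TE. The per-TR update is affine in the magnetization,
so the implementation squares the affine map — equivalent to 2^k explicit TR
iterations and exact to machine precision — and monitors the contraction of
the homogeneous part. Over a 1000-point random parameter grid the spoiled and
inversion-recovery closed forms agree with the oracle to better than 1e-6
relative; the bSSFP approximation agrees to 1% in its validity regime.

## Noise model

`estimate_covariance()` implements the RF-off measurement: the sample
covariances of the real and imaginary components are averaged (they share
`Sigma` under body-noise dominance) with `1/(N-1)` normalisation. A
consistency warning fires when the two component covariances differ by more
than 20% in Frobenius norm — quadrature imbalance the shared-covariance model
cannot represent. `sample_noise()` draws correlated complex Gaussian noise by
Cholesky factorisation, falling back to an eigendecomposition with
eigenvalues below `-1e-10 * lambda_max` treated as errors and small negative
ones clipped to zero (floating-point tolerance, not a repair of genuinely
invalid covariances). The default noise-only fixture uses 4096 samples per
channel; at that size a 6x6 covariance is recovered to roughly 2-3%
Frobenius, and to well under 1% at 1e5 samples.

All randomness is seeded explicitly; seeds are recorded in the provenance
block of every simulated dataset, and `simulate_batch()` derives per-repeat
seeds from one master seed so batches are reproducible and their first
element equals a single call.

## Conventions

* Arrays are `(channel, echo, phase-encode, readout)`; the DC sample sits at
  index `floor(N/2)+1` along each image dimension.
* All transforms are centred and *unitary* (`1/sqrt(N)` both ways): Parseval
  holds exactly and white noise keeps its variance across domains, which is
  what makes the k-space noise contract carry directly into image-domain SNR.
  Consequently the DC sample of a noiseless acquisition equals the voxel-sum
  divided by `sqrt(N_pixels)`.
* Partial Fourier with fraction `q` acquires phase-encode lines `1..ceil(qN)`
  — one full half plus `q - 0.5` of the other. The direction is a package
  convention (the phase-encode axis); internal units are SI throughout, with
  ms/degrees/kHz accepted at the CLI boundary.
* `Sigma` is the covariance of one noise component; the total complex
  variance per channel is `2 Sigma_ii`.

## Synthetic phantoms

`make_resolution_phantom()` renders a disk with bar groups of widths 1-4 px;
`make_airway_phantom()` renders a bright tissue disk with a dark lumen whose
radius follows a breathing cycle (`airway_radius_series()`, default 100
frames over 3 cycles). Both are rendered at 4x resolution and box-downsampled
so edges are anti-aliased — this keeps Gibbs ringing out of the corner
background regions used for noise estimation. Coil sensitivities are smooth
Gaussian-magnitude, polynomial-phase maps, identical across simulated fields,
normalised to unit mean magnitude over the object.

`forward_acquire()` multiplies the per-voxel steady-state signal by
`(B0 / 1 T)^2` before the Fourier transform. The quadratic prefactor is
applied *in the generator*, not the simulator, so the central consistency
property is a genuine test: acquiring at 3 T and simulating down to 1.5 T
must be statistically indistinguishable from acquiring directly at 1.5 T
with covariance `a^2 b Sigma`. The acceptance suite verifies this with
image-SNR and noise-moment comparisons over 20 repeats at 95% confidence,
and verifies the end-to-end SNR-ratio law `SNR_low/SNR_high = a f / sqrt(b)`
for three scalings, including the fat-water convention where bandwidth is
scaled with the field (`b = a`) to permit proportionally longer echo times.

### Study conditions

Defaults were fixed once, as representative values, and are not derived from
measured phantom data:

* resolution phantom: doped-water-like background T1 600 ms, T2 100 ms
  (the physical phantom's values were measured but not published); bar
  inserts T1 300 ms, T2 50 ms, PD 0.4;
* airway: muscle-like tissue T1 1.4 s, T2 30 ms, lumen PD 0; 6 receive
  channels; channel noise sd 0.02 at 3 T, giving image SNR near 40 —
  representative of real-time low-resolution imaging, where each frame is
  reconstructed from very few readouts;
* region growing: 4-connected (configurable), acceptance band
  `kappa * sigma_background` with `kappa = 3`;
* SNR: Rayleigh correction `sigma = sd(background) / sqrt(2 - pi/2)` is on by
  default; for multi-channel sum-of-squares images the background is central
  chi rather than Rayleigh, so the correction is approximate — ratios between
  fields, which is what the decision methodology uses, are unaffected because
  the same bias enters numerator and denominator.

## Reconstruction and the decision surface

`homodyne_recon()` implements the canonical partial-Fourier recovery: the
conjugate-symmetric centre band (width `2(q-0.5)N`, Hamming-apodised)
provides a low-resolution phase estimate; acquired lines are ramp-weighted so
each symmetric pair sums to weight 2; the phase-demodulated real part is
taken. At `q = 1` it reduces exactly to the magnitude reconstruction. On a
real-valued 64x64 phantom at the 62.5% fraction the magnitude RMSE against
the full-data reconstruction is about 0.2% of peak (2% is the acceptance
bound); smooth phase raises it but it stays below 3% for gentle ramps.

`airway_dice_sweep()` is the decision surface: for each candidate field, 50
independent simulations are reconstructed, the lumen segmented by region
growing, and Dice overlap against the reference (the source-field
segmentation by default, or ground truth) summarised with 95% confidence
intervals. On the synthetic airway at the conditions above the curve is
monotone non-increasing in decreasing B0, stays above 0.9 down to 0.5 T, and
collapses sharply below — with the variance spike at the failure field that
signals segmentation breakdown. A Dice threshold (0.9 is a reasonable
acceptability cut for airway tracking) then reads off the minimum usable
field strength. The collapse point is a property of this phantom, its SNR
calibration, and the segmentation parameters, not a clinical prediction.

## Problem sizes

The shipped tests and the acceptance script use 64x64 grids, 20 repeats for
SNR statistics, 50 repeats per field for the Dice curve over
{3, 1.5, 0.5, 0.3, 0.2, 0.1} T, 1e5-1e6 noise draws for moment checks, and a
1000-point parameter grid for the oracle comparison; the full acceptance run
completes in well under a minute on one core. Larger grids and frame counts
only change runtime, not any convention.

## What the synthetic results do and do not show

Passing tests establish that the simulator realises its own statistical
contract exactly (signal scaling, noise covariance, SNR law, reconstruction
fidelity) on data that satisfy the model's assumptions by construction. They
say nothing about effects the model deliberately excludes: receive-chain
differences between real scanners at different fields (which produced
severalfold SNR discrepancies against a differently-built low-field system
in practice), field-dependent B0/B1 inhomogeneity, physiological noise,
sequence re-optimisation at low field, or non-Cartesian sampling and
constrained reconstruction. Simulated outputs therefore carry a provenance
block so they can never masquerade as acquired data.
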