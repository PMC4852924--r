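# lowfieldsim

Simulate low-field MRI acquisitions from high-field multi-channel k-space
data, and use the simulations to estimate the minimum main-field strength
(B0) at which an imaging technique still works.

New MRI methods are almost always developed on 1.5 T / 3 T scanners, yet
low-field systems (0.1–0.5 T) can be far cheaper — if the method survives the
SNR loss. `lowfieldsim` answers that question retrospectively, for
proton-density-weighted (PDw) acquisitions: given raw k-space data `y = s + n`
acquired at a high field with channel noise covariance Σ (covariance of the
real part; the imaginary part is i.i.d. with the same Σ, measurable with an
RF-off scan), it produces a statistically correct acquisition at a lower
field:

```
y_low = a² f y + n_add,          a = B0_low / B0_high,  b = BW_low / BW_high
Re{n_add}, Im{n_add} ~ N(0, (a²b − a⁴f²) Σ)     per k-space sample
```

Signal amplitude scales as B0² and body-dominated thermal noise standard
deviation as B0·√BW, so the total simulated noise covariance is exactly
`a²b Σ`. The factor `f` corrects the steady-state relaxation weighting
between fields and is computed per sequence family (spoiled GRE, spin echo,
balanced SSFP, inversion recovery) from TR/TE/TI, flip angle, and T1/T2(*)
at both fields; for PDw protocols with equal flip angles `f ≈ 1`. Feasibility
requires `a²b ≥ a⁴f²` — the noise inherited from the source acquisition
cannot be removed.

Around this core the package provides digital phantoms with a physically
scaled forward model (`forward_acquire`, with the B0² prefactor applied in
the generator so the a² law is emergent, not inserted), noise-covariance
estimation, zero-filled and partial-Fourier homodyne reconstruction,
sum-of-squares coil combination, Rayleigh-corrected magnitude SNR,
region-growing segmentation with Dice overlap, and field-strength sweep
utilities that turn all of this into minimum-field-strength decision curves.

## Worked example

Simulate a real-time upper-airway acquisition (5° flip, TE/TR 2.6/4.6 ms,
BW 62.5 kHz, 6-channel coil) from 3 T down to lower fields and locate the
field below which lumen segmentation fails:

```r
library(lowfieldsim)
aw <- make_airway_phantom(c(64, 64), lumen_radius_series = 8, n_channels = 6)
meta_h <- acq_meta(b0 = 3, tr = 4.6e-3, te = 2.6e-3, flip_angle = 5 * pi / 180,
                   bandwidth = 62.5e3, sequence_family = "SPGR")
Sigma <- noise_covariance(diag(0.02^2, 6))

y_h       <- forward_acquire(aw$frames[[1]], meta_h, Sigma, seed = 1)
Sigma_hat <- estimate_covariance(sample_noise(Sigma, 4096, seed = 2))  # RF-off scan

meta_l <- meta_h; meta_l$b0 <- 1.5
tissue <- tissue_params(pd = 1, t1 = 1.4, t2 = 0.03)
f <- correction_factor(correction_inputs(meta_h, tissue, meta_l, tissue),
                       gre_t2_fallback = TRUE)   # T2* unknown: conservative
scal <- derive_scaling(meta_h, meta_l, f = f)
print(scal)
#> field_scaling: a = 0.5, b = 1, f = 1; additive variance scale 0.1875

sroi <- disk_roi(c(64, 64), 20) & !disk_roi(c(64, 64), 12)
nroi <- corner_roi(c(64, 64), 10)
snr_field_sweep(aw$frames[[1]], meta_h, Sigma_hat, fields = c(1.5, 0.5),
                signal_roi = sroi, noise_roi = nroi, n_repeats = 20, seed = 1)
#>   field mean_snr    sd ci_halfwidth  n snr_ratio predicted_ratio
#> 1   1.5    19.82 0.944        0.442 20     0.518           0.500
#> 2   0.5     7.17 0.312        0.146 20     0.187           0.167

airway_dice_sweep(aw, meta_h, Sigma_hat, fields = c(3, 1.5, 0.5, 0.3, 0.2),
                  n_repeats = 50, seed = 1)
#>   field mean_dice       sd ci_halfwidth  n
#> 1   3.0    1.0000 0.000000     0.000000 50
#> 2   1.5    0.9681 0.003194     0.000908 50
#> 3   0.5    0.9239 0.004608     0.001310 50
#> 4   0.3    0.1057 0.100596     0.028589 50
#> 5   0.2    0.0847 0.000512     0.000145 50
```

Reading the output: the PDw airway protocol gives `f = 1`, so simulating
3 T → 1.5 T at equal bandwidth adds noise with per-component variance
`a²b − a⁴f² = 0.1875 Σ`. Measured image SNR follows the `a·f/√b` law (0.52
observed vs 0.50 predicted at 1.5 T); at very low SNR the measured ratio sits
slightly above the thermal prediction because the multi-channel magnitude
noise floor inflates the signal-ROI mean — a real property of magnitude
imaging, not a simulator error. The Dice curve against the 3 T reference
segmentation stays above 0.9 down to 0.5 T and collapses below, with the
variance spike at the failure field that marks segmentation breakdown: under
these study conditions the minimum usable field for this task is 0.5 T.

The methods vignette (`vignettes/low-field-simulation.Rmd`) documents the
model assumptions, the per-sequence correction factors, all conventions
(array order, centred unitary FFTs, partial-Fourier layout), and what the
synthetic experiments do and do not demonstrate about real scanners.

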