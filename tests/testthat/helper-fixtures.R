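# Shared fixtures: the two acquisition protocols exercised throughout, and
# small phantoms built in code.

# 2D FSPGR resolution-phantom protocol: FA 10 deg, TE/TR 3.1/10 ms,
# BW 31.25 kHz, 62.5% partial k-space.
phantom_protocol <- function(b0 = 3, pf = 1.0) {
  acq_meta(b0 = b0, tr = 10e-3, te = 3.1e-3, flip_angle = 10 * pi / 180,
           bandwidth = 31.25e3, sequence_family = "SPGR",
           partial_fourier_fraction = pf)
}

# Real-time upper-airway protocol: FA 5 deg, TE/TR 2.6/4.6 ms, BW 62.5 kHz.
airway_protocol <- function(b0 = 3) {
  acq_meta(b0 = b0, tr = 4.6e-3, te = 2.6e-3, flip_angle = 5 * pi / 180,
           bandwidth = 62.5e3, sequence_family = "SPGR")
}

# Representative doped-water tissue (T1 600 ms, T2 100 ms).
water_tissue <- function() tissue_params(pd = 1, t1 = 0.6, t2 = 0.1)

small_phantom <- function(n_channels = 1, flat_coils = TRUE) {
  make_resolution_phantom(c(64, 64), n_channels = n_channels,
                          flat_coils = flat_coils)
}

# Metadata copy at a different field / bandwidth.
retarget <- function(meta, b0 = meta$b0, bw = meta$bandwidth) {
  meta$b0 <- b0
  meta$bandwidth <- bw
  meta
}

# Uniform all-acquired k-space of given value, for moment tests.
constant_kspace <- function(value, n_channels, n = 64, meta = phantom_protocol()) {
  samples <- array(complex(real = value, imaginary = 0), c(n_channels, 1, n, n))
  kspace_data(samples, matrix(TRUE, n, n), meta)
}
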