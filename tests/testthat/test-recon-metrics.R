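test_that("ifft reconstruction is unitary: round trips, Parseval, zero maps to zero", {
  ph <- small_phantom()
  meta <- phantom_protocol()
  k0 <- forward_acquire(ph, meta, cov = NULL)
  sig <- lowfieldsim:::phantom_signal_map(ph, meta, meta$te)
  expect_lt(max(abs(abs(matrix(ifft_recon(k0)[1, 1, , ], 64, 64)) - sig)),
            1e-9 * max(sig))

  # pure noise keeps its variance across the transform
  n <- sample_noise(matrix(1, 1, 1), 64 * 64, 1, seed = 4)
  samp <- array(complex(real = 0), c(1, 1, 64, 64))
  samp[1, 1, , ] <- matrix(n, 64, 64)
  kn <- kspace_data(samp, matrix(TRUE, 64, 64), meta)
  img <- matrix(ifft_recon(kn)[1, 1, , ], 64, 64)
  # unitary: total noise energy preserved exactly, per-component variance in law
  expect_equal(sum(abs(img)^2), sum(abs(samp)^2), tolerance = 1e-12)
  expect_equal(stats::var(as.vector(Re(img))), 1, tolerance = 0.1)

  kz <- constant_kspace(0, 1, n = 32)
  expect_true(all(ifft_recon(kz) == 0))
})

test_that("homodyne equals plain magnitude recon at fraction 1 and recovers partial data", {
  ph <- small_phantom()
  kf <- forward_acquire(ph, phantom_protocol(pf = 1), cov = NULL)
  expect_lt(max(abs(homodyne_recon(kf) - abs(ifft_recon(kf)))), 1e-9)

  # real-valued phantom at the 62.5% fraction: RMSE < 2% of peak
  kp <- forward_acquire(ph, phantom_protocol(pf = 0.625), cov = NULL)
  full <- abs(matrix(ifft_recon(kf)[1, 1, , ], 64, 64))
  hom <- abs(matrix(homodyne_recon(kp)[1, 1, , ], 64, 64))
  expect_lt(sqrt(mean((hom - full)^2)) / max(full), 0.02)

  # smooth linear phase ramp: RMSE < 3% of peak
  ph2 <- ph
  yy <- matrix(seq_len(64), 64, 64)
  ph2$coil_sensitivities[, , 1] <- exp(1i * 2 * pi * (0.004 * t(yy) + 0.0024 * yy))
  kf2 <- forward_acquire(ph2, phantom_protocol(pf = 1), cov = NULL)
  kp2 <- forward_acquire(ph2, phantom_protocol(pf = 0.625), cov = NULL)
  full2 <- abs(matrix(ifft_recon(kf2)[1, 1, , ], 64, 64))
  hom2 <- abs(matrix(homodyne_recon(kp2)[1, 1, , ], 64, 64))
  expect_lt(sqrt(mean((hom2 - full2)^2)) / max(full2), 0.03)

  kp$meta$partial_fourier_fraction <- 0.5
  expect_error(homodyne_recon(kp), class = "lfs_domain_error")
})

test_that("sum-of-squares combination is the pixelwise root-sum-of-squares", {
  img <- matrix(complex(real = 1:6, imaginary = 0), 2, 3)
  arr <- array(0i, c(1, 1, 2, 3)); arr[1, 1, , ] <- img
  expect_equal(sos_combine(arr), abs(img))
  arr2 <- array(0i, c(2, 1, 2, 3)); arr2[1, 1, , ] <- img; arr2[2, 1, , ] <- img
  expect_equal(sos_combine(arr2), sqrt(2) * abs(img))
  arr34 <- array(0i, c(2, 1, 1, 1)); arr34[1, 1, 1, 1] <- 3; arr34[2, 1, 1, 1] <- 4i
  expect_equal(as.vector(sos_combine(arr34)), 5)
})

test_that("Rayleigh-corrected SNR recovers the underlying Gaussian noise level", {
  set.seed(9)
  n_bg <- 1e4
  img <- matrix(0, 200, 100)
  img[, 1:50] <- 100
  bg <- sqrt(stats::rnorm(n_bg, sd = 10)^2 + stats::rnorm(n_bg, sd = 10)^2)
  img[, 51:100] <- bg
  sroi <- col(img) <= 50
  nroi <- col(img) > 50
  expect_equal(measure_snr(img, sroi, nroi), 10, tolerance = 0.03)
  # scale invariance
  expect_equal(measure_snr(2 * img, sroi, nroi), measure_snr(img, sroi, nroi))
  # asymptotic unbiasedness at 1e4 background pixels (< 1%)
  expect_lt(abs(measure_snr(img, sroi, nroi) / 10 - 1), 0.01)

  expect_warning(s <- measure_snr(matrix(1, 4, 4), c(1, 2), c(15, 16)), "infinite")
  expect_identical(s, Inf)
  expect_error(measure_snr(img, sroi, sroi), "disjoint", class = "lfs_validation_error")
  expect_error(measure_snr(img, matrix(FALSE, 200, 100), nroi),
               class = "lfs_validation_error")
})

test_that("snr_statistics summarises repeats and handles n = 1", {
  imgs <- list(matrix(c(rep(10, 8), 1, 2, 1, 2, 1, 2, 1, 2), 4, 4))
  s1 <- snr_statistics(imgs, col(imgs[[1]]) <= 2, col(imgs[[1]]) > 2)
  expect_equal(s1$n, 1)
  expect_true(is.na(s1$sd))
  s2 <- snr_statistics(rep(imgs, 3), col(imgs[[1]]) <= 2, col(imgs[[1]]) > 2)
  expect_equal(s2$sd, 0)
})

test_that("region growing segments a uniform disk exactly and respects the band", {
  img <- matrix(1, 64, 64)
  d <- disk_roi(c(64, 64), 10)
  img[d] <- 0
  expect_identical(region_grow(img, c(32, 32), 0.5), d)
  # zero band: only pixels equal to the seed value (the connected disk)
  expect_identical(region_grow(img, c(32, 32), 0), d)
  expect_error(region_grow(img, c(0, 5), 0.1), class = "lfs_validation_error")

  # noisy lumen at SNR 20: overlap with truth above 0.95
  aw <- make_airway_phantom(c(64, 64), lumen_radius_series = 10,
                            n_channels = 1, flat_coils = TRUE)
  cov <- noise_covariance(matrix((0.33 / 20)^2, 1, 1))  # tissue level ~0.33
  k <- forward_acquire(aw$frames[[1]], airway_protocol(), cov, seed = 12)
  img_n <- recon_magnitude(k)
  thr <- 3 * stats::sd(img_n[corner_roi(c(64, 64))])
  seg <- region_grow(img_n, c(32, 32), thr)
  expect_gt(dice(seg, aw$truth_masks[[1]]), 0.95)
})

test_that("Dice coefficient follows its definition and symmetry", {
  a <- matrix(FALSE, 10, 20); b <- a
  a[1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b[11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  b2 <- a; b2[1:5] <- FALSE; b2[11:15] <- TRUE   # |A|=|B|=10, overlap 5
  expect_equal(dice(a, b2), 0.5)
  expect_equal(dice(a, b2), dice(b2, a))
  expect_warning(d0 <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
  expect_identical(d0, 1)
})
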