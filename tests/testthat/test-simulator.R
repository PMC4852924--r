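test_that("derive_scaling computes a, b and enforces feasibility", {
  mh <- phantom_protocol(3)
  s_id <- derive_scaling(mh, mh, f = 1)
  expect_equal(c(s_id$a, s_id$b), c(1, 1))

  s <- derive_scaling(mh, retarget(mh, b0 = 1.5), f = 1)
  expect_equal(s$a, 0.5)
  expect_equal(s$add_var_scale, 0.1875)

  # fat-water convention: bandwidth scaled with the field
  s2 <- derive_scaling(mh, retarget(mh, b0 = 0.3, bw = mh$bandwidth * 0.1), f = 1)
  expect_equal(c(s2$a, s2$b), c(0.1, 0.1))

  expect_error(derive_scaling(retarget(mh, b0 = 1.5), mh),
               class = "lfs_feasibility_error")
  expect_error(derive_scaling(mh, retarget(mh, b0 = 1.5), f = 3),
               "minimum feasible bandwidth", class = "lfs_feasibility_error")
})

test_that("identity scaling returns the input bit-exactly", {
  ph <- small_phantom(n_channels = 2, flat_coils = FALSE)
  cov <- noise_covariance(diag(2) * 1e-4)
  kh <- forward_acquire(ph, phantom_protocol(), cov, seed = 3)
  y <- simulate_low_field(kh, cov, field_scaling(1, 1, 1), seed = 99)
  expect_identical(y$samples, kh$samples)
})

test_that("additive noise follows (a^2 b - a^4 f^2) Sigma and totals a^2 b Sigma", {
  n <- 320
  ksp <- constant_kspace(1, n_channels = 2, n = n)
  scal <- field_scaling(0.5, 1, 1)
  y <- simulate_low_field(ksp, noise_covariance(diag(2)), scal, seed = 7)
  d <- y$samples - 0.25 * ksp$samples
  expect_equal(stats::var(as.vector(Re(d[1, 1, , ]))), 0.1875, tolerance = 0.02)
  expect_equal(stats::var(as.vector(Im(d[2, 1, , ]))), 0.1875, tolerance = 0.02)

  # pure-noise input: output covariance = a^2 b Sigma (total-variance identity)
  sig <- matrix(c(1, 0.5, 0.5, 2), 2)
  n0 <- sample_noise(noise_covariance(sig), n * n, 1, seed = 3)
  samp <- array(complex(real = 0), c(2, 1, n, n))
  samp[1, 1, , ] <- matrix(n0[1, ], n, n)
  samp[2, 1, , ] <- matrix(n0[2, ], n, n)
  k0 <- kspace_data(samp, matrix(TRUE, n, n), phantom_protocol())
  y0 <- simulate_low_field(k0, noise_covariance(sig), scal, seed = 11)
  m <- matrix(y0$samples[, 1, , , drop = FALSE], 2, n * n)
  emp <- (stats::cov(t(Re(m))) + stats::cov(t(Im(m)))) / 2
  expect_lt(norm(emp - 0.25 * sig, "F") / norm(0.25 * sig, "F"), 0.02)
})

test_that("noise is only added on acquired positions; zero-filled region stays zero", {
  ph <- small_phantom()
  cov <- noise_covariance(matrix(1e-4, 1, 1))
  kh <- forward_acquire(ph, phantom_protocol(pf = 0.625), cov, seed = 5)
  y <- simulate_low_field(kh, cov, field_scaling(0.5, 1, 1), seed = 6)
  unacq <- which(!y$mask)
  m <- matrix(y$samples[1, 1, , ], 64, 64)
  expect_true(all(m[unacq] == 0))
  expect_gt(stats::sd(Re(m[y$mask])), 0)
})

test_that("signal component is linear: simulate(alpha y) - alpha a^2 f y is pure noise", {
  n <- 256
  scal <- field_scaling(0.5, 2, 1.5)        # uneven split, still feasible
  cov <- noise_covariance(matrix(2, 1, 1))
  for (alpha in c(1, 3)) {
    ksp <- constant_kspace(alpha, n_channels = 1, n = n)
    y <- simulate_low_field(ksp, cov, scal, seed = 13)
    d <- y$samples - scal$a^2 * scal$f * ksp$samples
    expect_equal(mean(Re(d)), 0, tolerance = 0.01 * sqrt(2))
    expect_equal(stats::var(as.vector(Re(d))), scal$add_var_scale * 2, tolerance = 0.03)
  }
})

test_that("batches are reproducible and their first element matches a single call", {
  ksp <- constant_kspace(1, n_channels = 1, n = 32)
  cov <- noise_covariance(matrix(1, 1, 1))
  scal <- field_scaling(0.5, 1, 1)
  batch <- simulate_batch(ksp, cov, scal, n_repeats = 3, seed = 17)
  expect_length(batch, 3)
  single <- simulate_low_field(ksp, cov, scal, seed = 17)
  expect_identical(batch[[1]]$samples, single$samples)
  expect_false(identical(batch[[1]]$samples, batch[[2]]$samples))

  again <- simulate_batch(ksp, cov, scal, n_repeats = 3, seed = 17)
  expect_identical(batch[[2]]$samples, again[[2]]$samples)

  # different seeds share the identical signal component
  ksp64 <- constant_kspace(1, n_channels = 1, n = 64)
  b1 <- simulate_low_field(ksp64, cov, scal, seed = 19)
  b2 <- simulate_low_field(ksp64, cov, scal, seed = 23)
  d <- b1$samples - b2$samples
  expect_equal(mean(Re(d)), 0, tolerance = 0.03)
  expect_equal(stats::var(as.vector(Re(d))), 2 * 0.1875, tolerance = 0.1)
})

test_that("provenance records the seed and scaling of a simulation", {
  ksp <- constant_kspace(1, n_channels = 1, n = 32)
  y <- simulate_low_field(ksp, noise_covariance(matrix(1, 1, 1)),
                          field_scaling(0.5, 1, 1), seed = 77)
  expect_equal(y$provenance$simulated$seed, 77)
  expect_equal(y$provenance$simulated$a, 0.5)
  expect_equal(y$meta$b0, 1.5)
})
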