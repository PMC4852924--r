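test_that("closed-form signals behave at their analytic limits", {
  # saturation-free limit: 90 deg, TR >> T1, TE -> 0
  expect_equal(spgr_signal(pi / 2, tr = 60, t1 = 0.6, te = 1e-9, t2_effective = 0.1),
               1.0, tolerance = 1e-7)
  expect_warning(s0 <- spgr_signal(0, 0.01, 0.6, 0.003, 0.1), "no excitation")
  expect_identical(s0, 0)

  # SE at 90 deg, TR >> T1 reduces to pure T2 decay
  expect_equal(se_signal(pi / 2, tr = 60, t1 = 0.6, te = 0.05, t2 = 0.1),
               exp(-0.05 / 0.1), tolerance = 1e-10)

  # bSSFP at 180 deg: denominator reduces to 2 T1/T2
  expect_equal(bssfp_signal(pi, t1 = 1, t2 = 0.1) * 2 * (1 / 0.1), sin(pi),
               tolerance = 1e-12)

  # IR nulls at TI = T1 ln 2 when TR >> T1
  expect_equal(ir_signal(ti = 0.6 * log(2), tr = 60, t1 = 0.6, te = 1e-4, t2 = 0.1),
               0, tolerance = 1e-8)

  expect_error(spgr_signal(0.2, 0.01, -1, 0.003, 0.1), class = "lfs_domain_error")
})

test_that("T2* combines T2 and the per-tesla dephasing rate", {
  expect_identical(t2_effective(0.1, 0, 3), 0.1)
  expect_equal(t2_effective(0.1, 5, 3), 0.04)   # 1/(10 + 15) s
  expect_equal(t2_effective(0.1, 5, 0), 0.1)    # B0 -> 0 limit
})

test_that("equal parameters on both sides give f = 1 for every family", {
  ts <- tissue_params(1, 0.8, 0.08, r2prime_per_tesla = 2)
  for (fam in c("SE", "SPGR", "bSSFP", "IR")) {
    ti <- if (fam == "IR") 0.005 else NULL
    m <- acq_meta(3, 0.01, 0.003, 0.3, 1e5, fam, ti = ti)
    expect_identical(correction_factor(correction_inputs(m, ts, m, ts)), 1)
  }
})

test_that("PDw limit gives f = sin(theta_l)/sin(theta_h) regardless of species", {
  for (tis in list(water_tissue(), tissue_params(2, 1.2, 0.04))) {
    mh <- acq_meta(3, tr = 100 * tis$t1, te = tis$t2 / 1e4,
                   flip_angle = 70 * pi / 180, bandwidth = 1e5, "SE")
    ml <- acq_meta(0.5, tr = 100 * tis$t1, te = tis$t2 / 1e4,
                   flip_angle = 40 * pi / 180, bandwidth = 1e5, "SE")
    f <- correction_factor(correction_inputs(mh, tis, ml, tis))
    expect_equal(f, sin(40 * pi / 180) / sin(70 * pi / 180), tolerance = 1e-3)
  }
})

test_that("airway protocol (PDw, equal flip angles) gives f within 1e-3 of 1", {
  tis <- tissue_params(1, 1.4, 0.03)
  f <- suppressWarnings(correction_factor(
    correction_inputs(airway_protocol(3), tis, airway_protocol(0.3), tis),
    gre_t2_fallback = TRUE))
  expect_equal(f, 1, tolerance = 1e-3)
})

test_that("bSSFP correction follows the T1/T2 denominator ratio", {
  mk <- function(b0, th) acq_meta(b0, 0.005, 0.002, th, 1e5, "bSSFP")
  hi <- tissue_params(1, 1.0, 0.1); lo <- tissue_params(1, 0.7, 0.1)
  f <- correction_factor(correction_inputs(mk(3, pi / 3), hi, mk(1, pi / 3), lo))
  expect_equal(f, 6.5 / 5.0, tolerance = 1e-12)   # hand evaluation
  f180 <- correction_factor(correction_inputs(mk(3, pi), hi, mk(1, pi), lo))
  expect_equal(f180, 1.0 / 0.7, tolerance = 1e-14) # sin cancels symbolically
})

test_that("fat-water convention (B0*TE constant, 3 deg) reduces f to TE decay with liver T2", {
  te_h <- c(1.4, 2.3, 3.2) / 1e3
  mh <- acq_meta(3, 0.009, te_h, 3 * pi / 180, 62.5e3, "SPGR")
  ml <- acq_meta(1.5, 0.009, 2 * te_h, 3 * pi / 180, 31.25e3, "SPGR")
  liver <- tissue_params(1, 0.8, 0.042)
  f <- suppressWarnings(correction_factor(correction_inputs(mh, liver, ml, liver),
                                          gre_t2_fallback = TRUE))
  expect_equal(f, exp(-(2 * te_h - te_h) / 0.042), tolerance = 1e-12)
})

test_that("T2 fallback is conservative and refuses B0_l TE_l > B0_h TE_h", {
  liver <- tissue_params(1, 0.8, 0.042)
  mh <- acq_meta(3, 0.009, c(1.4, 2.3, 3.2) / 1e3, 3 * pi / 180, 62.5e3, "SPGR")
  bad_l <- acq_meta(2.9, 0.009, c(1.5, 2.4, 3.3) / 1e3, 3 * pi / 180, 62.5e3, "SPGR")
  expect_error(correction_factor(correction_inputs(mh, liver, bad_l, liver),
                                 gre_t2_fallback = TRUE),
               "underestimat", class = "lfs_domain_error")

  # conservativeness: fallback f never exceeds f computed with any T2* <= T2
  set.seed(41)
  for (i in 1:25) {
    t1 <- runif(1, 0.3, 2); t2 <- runif(1, 0.02, 0.2)
    r2p <- runif(1, 0.5, 10)
    te_h <- runif(1, 1e-3, 8e-3)
    a <- runif(1, 0.05, 0.9)
    te_l <- te_h * runif(1, 0.3, 1 / a)   # keeps B0_l TE_l <= B0_h TE_h
    th <- runif(1, 0.05, 0.5)
    mh_i <- acq_meta(3, 0.2, te_h, th, 1e5, "SPGR")
    ml_i <- acq_meta(3 * a, 0.2, te_l, th, 1e5, "SPGR")
    no_r2p <- tissue_params(1, t1, t2)
    with_r2p <- tissue_params(1, t1, t2, r2prime_per_tesla = r2p)
    f_fb <- suppressWarnings(correction_factor(
      correction_inputs(mh_i, no_r2p, ml_i, no_r2p), gre_t2_fallback = TRUE))
    f_t2s <- correction_factor(correction_inputs(mh_i, with_r2p, ml_i, with_r2p))
    expect_lte(f_fb, f_t2s + 1e-12)
  }
})

test_that("IR correction errors when the high-field species is nulled", {
  tis <- tissue_params(1, 0.8, 0.08)
  m <- acq_meta(3, tr = 48, te = 0.003, flip_angle = pi / 2, bandwidth = 1e5,
                sequence_family = "IR", ti = 0.8 * log(2))
  expect_error(correction_factor(correction_inputs(m, tis, m, tis)),
               "nulled", class = "lfs_domain_error")
})

test_that("f is invariant to proton-density rescaling (depends on relaxation only)", {
  mh <- phantom_protocol(3); ml <- phantom_protocol(1.5)
  t_a <- tissue_params(1, 0.6, 0.1, r2prime_per_tesla = 3)
  t_b <- tissue_params(5, 0.6, 0.1, r2prime_per_tesla = 3)  # PD x5
  f_a <- correction_factor(correction_inputs(mh, t_a, ml, t_a))
  f_b <- correction_factor(correction_inputs(mh, t_b, ml, t_b))
  expect_identical(f_a, f_b)
})

test_that("Bloch propagation reproduces the closed forms", {
  set.seed(5)
  # spoiled families: 200 random parameter draws, 1e-6 relative
  for (i in 1:100) {
    tr <- 10^runif(1, -3, 0); t1 <- tr * 10^runif(1, 0, 2)
    t2 <- t1 * runif(1, 0.05, 1); te <- tr * runif(1, 0.05, 0.9)
    th <- runif(1, 0.02, pi)
    m <- list(tr = tr, te = te, flip_angle = th)
    tis <- suppressWarnings(tissue_params(1, t1, t2))
    expect_equal(bloch_steady_state("SPGR", m, tis),
                 spgr_signal(th, tr, t1, te, t2), tolerance = 1e-6)
  }
  for (i in 1:50) {
    tr <- 10^runif(1, -2, 1); t1 <- tr * 10^runif(1, -1, 1)
    ti <- tr * runif(1, 0.1, 0.9); t2 <- t1 * runif(1, 0.05, 1)
    te <- tr * runif(1, 0.01, 0.09)
    got <- bloch_steady_state("IR", list(tr = tr, te = te, flip_angle = pi / 2, ti = ti),
                              suppressWarnings(tissue_params(1, t1, t2)))
    want <- abs(ir_signal(ti, tr, t1, te, t2))
    expect_equal(got, want, tolerance = 1e-6 + 1e-9 / max(want, 1e-9))
  }
  # bSSFP approximation holds to 1% in its TR << T1, T2 regime
  for (i in 1:20) {
    t1 <- runif(1, 0.5, 2); t2 <- t1 * runif(1, 0.05, 0.5)
    tr <- t1 / 1000; th <- runif(1, 0.1, pi - 0.1)
    got <- bloch_steady_state("bSSFP", list(tr = tr, te = tr / 2, flip_angle = th),
                              tissue_params(1, t1, t2))
    expect_equal(got, bssfp_signal(th, t1, t2), tolerance = 0.01)
  }
})

test_that("single-shot limit: 90 deg with TR >> T1 gives M0 exp(-TE/T2)", {
  got <- bloch_steady_state("SE", list(tr = 100 * 0.6, te = 0.03, flip_angle = pi / 2),
                            water_tissue())
  expect_equal(got, exp(-0.03 / 0.1), tolerance = 1e-9)
})

test_that("Bloch bSSFP matches the exact alternating-RF steady state", {
  # independent literature cross-check: M = M0 sin(th)(1-E1)/(1-(E1-E2)cos(th)-E1E2)
  th <- 1.1; t1 <- 0.9; t2 <- 0.09; tr <- 0.004
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  exact <- sin(th) * (1 - e1) / (1 - (e1 - e2) * cos(th) - e1 * e2) * exp(-(tr / 2) / t2)
  got <- bloch_steady_state("bSSFP", list(tr = tr, te = tr / 2, flip_angle = th),
                            tissue_params(1, t1, t2))
  expect_equal(got, exact, tolerance = 1e-9)
})
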