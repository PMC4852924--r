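# The core transform: scale acquired high-field k-space by a^2 * f and add
# correlated noise with per-component covariance (a^2 b - a^4 f^2) * Sigma so
# that the simulated data carry exactly the thermal-noise statistics of the
# lower field (variance proportional to B0^2 * bandwidth under body-noise
# dominance).

#' Derive field scaling from two acquisition protocols
#'
#' Computes `a = B0_low/B0_high` and `b = BW_low/BW_high` and checks
#' feasibility `a^2 b >= a^4 f^2` per echo (the additive-noise variance must
#' be non-negative; the inherited noise term `a^2 f n_high` cannot be removed).
#'
#' @param meta_h,meta_l [acq_meta()] of the acquired and target protocols.
#' @param f Relaxation correction factor(s), one per echo (see
#'   [correction_factor()]).
#' @return A [field_scaling()] object.
#' @export
derive_scaling <- function(meta_h, meta_l, f = 1) {
  stopifnot(inherits(meta_h, "acq_meta"), inherits(meta_l, "acq_meta"))
  if (meta_l$b0 > meta_h$b0) {
    lfs_feasibility_error(sprintf(
      "target B0 (%.3g T) exceeds source B0 (%.3g T): not a lower field",
      meta_l$b0, meta_h$b0))
  }
  field_scaling(a = meta_l$b0 / meta_h$b0,
                b = meta_l$bandwidth / meta_h$bandwidth,
                f = f)
}

#' Simulate a low-field acquisition from high-field k-space
#'
#' Returns `y_low = a^2 * f * y_high + n_add` on acquired positions, where
#' `n_add` has independent real/imaginary parts, each multivariate normal
#' across channels with covariance `(a^2 b - a^4 f^2) * Sigma`, independent
#' across k-space positions. Unacquired (masked-out) positions stay exactly
#' zero, as they would in a real acquisition with the same sampling. Total
#' simulated noise covariance is `a^2 b * Sigma` regardless of how variance is
#' split between the inherited and added components.
#'
#' @param kspace_h High-field [kspace_data()].
#' @param cov [noise_covariance()] of the high-field acquisition (per real
#'   component); channel count must match.
#' @param scaling A [field_scaling()] object; `f` scalar or one per echo.
#' @param seed Integer seed for the additive noise (recorded in provenance).
#' @param meta_l Optional [acq_meta()] describing the simulated protocol
#'   (TEs and bandwidth may legitimately differ, as when echo times are
#'   rescaled to preserve fat-water phase shifts). By default the source
#'   metadata is copied with `b0` and `bandwidth` scaled by `a` and `b`.
#' @return A [kspace_data()] at the lower field, with provenance recording
#'   the seed and scaling.
#' @export
simulate_low_field <- function(kspace_h, cov, scaling, seed = NULL, meta_l = NULL) {
  viol <- validate_kspace(kspace_h, cov)
  if (length(viol)) {
    lfs_validation_error(paste0("invalid input:\n  - ", paste(viol, collapse = "\n  - ")))
  }
  stopifnot(inherits(scaling, "field_scaling"))
  d <- dim(kspace_h$samples)
  ne <- d[2]
  f <- scaling$f
  if (length(f) == 1L) f <- rep(f, ne)
  if (length(f) != ne) {
    lfs_validation_error(sprintf("scaling has %d f value(s) but data have %d echo(es)",
                                 length(f), ne))
  }
  add_var <- scaling$a^2 * scaling$b - scaling$a^4 * f^2
  if (any(add_var < 0)) {
    lfs_feasibility_error(sprintf(
      "infeasible: a^2*b < a^4*f^2; minimum feasible bandwidth ratio b = %.6g",
      max(scaling$a^2 * f^2)))
  }

  idx <- which(kspace_h$mask)
  out <- kspace_h$samples
  seeds <- if (is.null(seed)) vector("list", ne) else as.list(seed + seq_len(ne) - 1L)
  for (ec in seq_len(ne)) {
    m <- matrix(out[, ec, , , drop = FALSE], d[1], d[3] * d[4])
    sc <- scaling$a^2 * f[ec]
    if (sc != 1 || add_var[ec] != 0) {
      m[, idx] <- sc * m[, idx] +
        sample_noise(cov, length(idx), add_var[ec], seed = seeds[[ec]])
      out[, ec, , ] <- array(m, c(d[1], d[3], d[4]))
    }
  }

  if (is.null(meta_l)) {
    meta_l <- kspace_h$meta
    meta_l$b0 <- meta_l$b0 * scaling$a
    meta_l$bandwidth <- meta_l$bandwidth * scaling$b
  }
  kspace_data(out, kspace_h$mask, meta_l,
              provenance = c(kspace_h$provenance,
                             list(simulated = list(
                               seed = seed, a = scaling$a, b = scaling$b, f = f,
                               add_var_scale = add_var,
                               source_b0 = kspace_h$meta$b0))))
}

#' Batch of independent low-field simulations
#'
#' Runs [simulate_low_field()] `n_repeats` times with per-repeat seeds
#' `seed + 0:(n_repeats-1)`, so the batch is reproducible and its first
#' element equals a single call with the same seed. Used for SNR and
#' segmentation statistics over repeated simulations.
#'
#' @inheritParams simulate_low_field
#' @param n_repeats Number of independent simulations (>= 1).
#' @return List of [kspace_data()] objects.
#' @export
simulate_batch <- function(kspace_h, cov, scaling, n_repeats, seed = 1L,
                           meta_l = NULL) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) lfs_domain_error("n_repeats must be >= 1")
  lapply(seq_len(n_repeats) - 1L, function(k) {
    simulate_low_field(kspace_h, cov, scaling, seed = seed + k * 1000L,
                       meta_l = meta_l)
  })
}
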