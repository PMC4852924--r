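# Steady-state signal equations for the supported sequence families and the
# relaxation-correction factor f = s_low / (a^2 * s_high) used by the
# simulator. All signals are dimensionless: they exclude the constant A
# proportional to B0^2, which the simulator applies as a^2.

#' Spoiled gradient-echo steady-state signal
#'
#' `(1 - E1) sin(theta) / (1 - E1 cos(theta)) * exp(-TE/T2eff)` with
#' `E1 = exp(-TR/T1)`; ideal spoiling assumed (transverse magnetization
#' destroyed every TR). With `t2_effective = T2` this is also the spin-echo
#' steady-state signal.
#'
#' @param theta Flip angle in radians, in `[0, pi]`.
#' @param tr Repetition time (s).
#' @param t1 Longitudinal relaxation time (s).
#' @param te Echo time (s), vectorised.
#' @param t2_effective Decay constant applied at TE: T2* for gradient echo,
#'   T2 for spin echo (s).
#' @return Signal per unit proton density (vector if `te` is a vector).
#' @export
spgr_signal <- function(theta, tr, t1, te, t2_effective) {
  if (t1 <= 0 || t2_effective <= 0) lfs_domain_error("relaxation times must be > 0")
  if (tr <= 0 || any(te < 0)) lfs_domain_error("tr must be > 0 and te >= 0")
  if (theta < 0 || theta > pi) lfs_domain_error("theta must be in [0, pi]")
  if (theta == 0) {
    warning("flip angle 0: no excitation, signal is 0", call. = FALSE)
    return(rep(0, length(te)))
  }
  e1 <- exp(-tr / t1)
  (1 - e1) * sin(theta) / (1 - e1 * cos(theta)) * exp(-te / t2_effective)
}

#' Spin-echo steady-state signal
#'
#' Same longitudinal steady state as [spgr_signal()], with transverse decay
#' governed by T2 (static dephasing refocused by the 180-degree pulse).
#'
#' @inheritParams spgr_signal
#' @param t2 Transverse relaxation time (s).
#' @export
se_signal <- function(theta, tr, t1, te, t2) {
  spgr_signal(theta, tr, t1, te, t2)
}

#' Balanced SSFP steady-state signal
#'
#' On-resonance pass-band expression valid for TE, TR much smaller than T1 and
#' T2: `sin(theta) / (1 + cos(theta) + (1 - cos(theta)) * T1/T2)`. A warning is
#' issued when `tr > t2/4`, outside the regime where this approximation holds.
#'
#' @inheritParams se_signal
#' @param tr Repetition time (s), used only for the validity warning; may be
#'   `NULL` to skip the check.
#' @export
bssfp_signal <- function(theta, t1, t2, tr = NULL) {
  if (t1 <= 0 || t2 <= 0) lfs_domain_error("relaxation times must be > 0")
  if (theta < 0 || theta > pi) lfs_domain_error("theta must be in [0, pi]")
  if (!is.null(tr) && tr > t2 / 4) {
    warning("bSSFP approximation assumes TE, TR << T1, T2; TR > T2/4 here", call. = FALSE)
  }
  sin(theta) / (1 + cos(theta) + (1 - cos(theta)) * (t1 / t2))
}

#' Inversion-recovery steady-state signal
#'
#' 90-degree excitation after a 180-degree inversion and delay TI:
#' `(1 - 2 exp(-TI/T1) + exp(-TR/T1)) * exp(-TE/T2)`. Negative values (before
#' the null point) are returned signed; callers needing magnitude take `abs()`.
#'
#' @inheritParams se_signal
#' @param ti Inversion time (s).
#' @export
ir_signal <- function(ti, tr, t1, te, t2) {
  if (t1 <= 0 || t2 <= 0) lfs_domain_error("relaxation times must be > 0")
  if (ti <= 0 || tr <= 0 || any(te < 0)) lfs_domain_error("ti, tr must be > 0 and te >= 0")
  (1 - 2 * exp(-ti / t1) + exp(-tr / t1)) * exp(-te / t2)
}

#' Effective transverse relaxation time T2*
#'
#' `1/T2* = 1/T2 + r2prime_per_tesla * B0`. The rate per tesla lumps the
#' gyromagnetic ratio, geometry constant, and ppm field inhomogeneity into one
#' identifiable parameter.
#'
#' @param t2 Transverse relaxation time (s).
#' @param r2prime_per_tesla Susceptibility dephasing rate per tesla (1/(s*T)).
#' @param b0 Field strength (T).
#' @return T2* in seconds.
#' @export
t2_effective <- function(t2, r2prime_per_tesla, b0) {
  if (t2 <= 0) lfs_domain_error("t2 must be > 0")
  if (r2prime_per_tesla < 0) lfs_domain_error("r2prime_per_tesla must be >= 0")
  if (b0 < 0) lfs_domain_error("b0 must be >= 0")
  1 / (1 / t2 + r2prime_per_tesla * b0)
}

#' Convenience T1 field-dispersion model
#'
#' `T1(B0) = T1_ref * (B0/B0_ref)^beta`. Longitudinal relaxation shortens at
#' lower field; the exponent is tissue-specific and must be chosen by the
#' user — the package never applies this model implicitly, because the
#' simulation assumes T1 is known at both fields.
#'
#' @param t1_ref T1 at the reference field (s).
#' @param b0 Target field (T).
#' @param b0_ref Reference field (T).
#' @param beta Dispersion exponent (typically 0.3-0.4 for soft tissue).
#' @return T1 at `b0` in seconds.
#' @export
t1_dispersion <- function(t1_ref, b0, b0_ref, beta) {
  if (t1_ref <= 0 || b0 <= 0 || b0_ref <= 0) lfs_domain_error("t1_ref, b0, b0_ref must be > 0")
  t1_ref * (b0 / b0_ref)^beta
}

#' Paired high/low-field correction inputs
#'
#' @param meta_h,meta_l [acq_meta()] at the high and low field; same sequence
#'   family and echo count on both sides.
#' @param tissue_h,tissue_l [tissue_params()] of the dominant species at each
#'   field.
#' @return An object of class `correction_inputs`.
#' @export
correction_inputs <- function(meta_h, tissue_h, meta_l, tissue_l) {
  stopifnot(inherits(meta_h, "acq_meta"), inherits(meta_l, "acq_meta"),
            inherits(tissue_h, "tissue_params"), inherits(tissue_l, "tissue_params"))
  if (meta_h$sequence_family != meta_l$sequence_family) {
    lfs_validation_error("high and low side must use the same sequence_family")
  }
  if (length(meta_h$te) != length(meta_l$te)) {
    lfs_validation_error("high and low side must have the same number of echoes")
  }
  structure(list(meta_h = meta_h, tissue_h = tissue_h,
                 meta_l = meta_l, tissue_l = tissue_l),
            class = "correction_inputs")
}

#' Relaxation correction factor f
#'
#' The scalar (per echo) by which the relaxation-weighted signal changes
#' between fields: `f = s_low / s_high` with both signals evaluated from the
#' steady-state equation of the sequence family, excluding the B0^2 amplitude
#' prefactor (which the simulator applies separately as a^2).
#'
#' Family specifics:
#' * **SE**: saturation-ratio times `exp(-(TE_l/T2_l - TE_h/T2_h))`; with a
#'   shared T2 this is the textbook form.
#' * **SPGR/GRE**: as SE but decaying with T2* at each field. T2* is computed
#'   from `r2prime_per_tesla` when present in both tissues. When it is absent
#'   and `gre_t2_fallback = TRUE`, T2 replaces T2*: this underestimates the
#'   low-field signal (conservative) provided `B0_l*TE_l <= B0_h*TE_h`, and the
#'   function refuses to use the fallback when that ordering is violated.
#' * **bSSFP**: ratio of the pass-band steady-state expressions; when the flip
#'   angles are equal, `sin(theta)` is cancelled symbolically so that
#'   `theta = 180` degrees yields `f = T1_h/T1_l` exactly.
#' * **IR**: ratio of the inversion-recovery expressions; an error is raised
#'   when the high-field species is nulled (denominator within 1e-9 of zero).
#'
#' In the proton-density-weighted limit (TE << T2 and either TR >> T1 or small
#' flip angle) SE/GRE reduce to `f = sin(theta_l)/sin(theta_h)` regardless of
#' the species, which is what makes a single global correction valid for
#' multi-species PDw imaging.
#'
#' @param inputs A [correction_inputs()] object.
#' @param gre_t2_fallback Use T2 in place of an unknown T2* for SPGR/GRE.
#' @return Numeric vector of f, one value per echo.
#' @export
correction_factor <- function(inputs, gre_t2_fallback = FALSE) {
  stopifnot(inherits(inputs, "correction_inputs"))
  mh <- inputs$meta_h; ml <- inputs$meta_l
  th <- inputs$tissue_h; tl <- inputs$tissue_l
  fam <- mh$sequence_family

  sat <- function(theta, tr, t1) {
    e1 <- exp(-tr / t1)
    (1 - e1) * sin(theta) / (1 - e1 * cos(theta))
  }

  f <- switch(fam,
    SE = {
      sat(ml$flip_angle, ml$tr, tl$t1) / sat(mh$flip_angle, mh$tr, th$t1) *
        exp(-(ml$te / tl$t2 - mh$te / th$t2))
    },
    SPGR = {
      if (!is.null(th$r2prime_per_tesla) && !is.null(tl$r2prime_per_tesla)) {
        t2s_h <- t2_effective(th$t2, th$r2prime_per_tesla, mh$b0)
        t2s_l <- t2_effective(tl$t2, tl$r2prime_per_tesla, ml$b0)
      } else if (gre_t2_fallback) {
        if (any(ml$b0 * ml$te > mh$b0 * mh$te + 1e-15)) {
          lfs_domain_error(paste0(
            "T2 fallback refused: B0_l*TE_l > B0_h*TE_h, so substituting T2 for T2* ",
            "would overestimate the low-field signal instead of underestimating it"))
        }
        warning(paste0("T2 used in place of unknown T2*: conservative estimate ",
                       "(simulated signal at best equals the true low-field signal)"),
                call. = FALSE)
        t2s_h <- th$t2
        t2s_l <- tl$t2
      } else {
        lfs_domain_error(paste0(
          "T2* unknown for SPGR/GRE: supply r2prime_per_tesla in both tissues ",
          "or set gre_t2_fallback = TRUE"))
      }
      sat(ml$flip_angle, ml$tr, tl$t1) / sat(mh$flip_angle, mh$tr, th$t1) *
        exp(-(ml$te / t2s_l - mh$te / t2s_h))
    },
    bSSFP = {
      den <- function(theta, t1, t2) 1 + cos(theta) + (1 - cos(theta)) * (t1 / t2)
      ratio <- den(mh$flip_angle, th$t1, th$t2) / den(ml$flip_angle, tl$t1, tl$t2)
      if (isTRUE(all.equal(mh$flip_angle, ml$flip_angle))) {
        rep(ratio, length(ml$te))
      } else {
        rep(sin(ml$flip_angle) / sin(mh$flip_angle) * ratio, length(ml$te))
      }
    },
    IR = {
      num <- 1 - 2 * exp(-ml$ti / tl$t1) + exp(-ml$tr / tl$t1)
      den <- 1 - 2 * exp(-mh$ti / th$t1) + exp(-mh$tr / th$t1)
      if (abs(den) < 1e-9) {
        lfs_domain_error(paste0(
          "correction factor undefined: high-field IR signal is nulled ",
          "(1 - 2*exp(-TI/T1) + exp(-TR/T1) within 1e-9 of zero)"))
      }
      num / den * exp(-(ml$te / tl$t2 - mh$te / th$t2))
    },
    lfs_validation_error(sprintf("unsupported sequence family '%s'", fam))
  )
  if (any(!is.finite(f)) || any(f <= 0)) {
    lfs_domain_error(sprintf("correction factor is not finite and positive: %s",
                             paste(signif(f, 4), collapse = ", ")))
  }
  f
}

# Steady-state signal for a voxel, dispatched on the metadata's family.
# Excludes the B0^2 amplitude prefactor. Vectorised over te.
sequence_signal <- function(meta, tissue, te = meta$te) {
  switch(meta$sequence_family,
    SPGR = {
      t2e <- if (is.null(tissue$r2prime_per_tesla)) tissue$t2
             else t2_effective(tissue$t2, tissue$r2prime_per_tesla, meta$b0)
      spgr_signal(meta$flip_angle, meta$tr, tissue$t1, te, t2e)
    },
    SE = se_signal(meta$flip_angle, meta$tr, tissue$t1, te, tissue$t2),
    bSSFP = rep(bssfp_signal(meta$flip_angle, tissue$t1, tissue$t2, tr = NULL),
                length(te)),
    IR = ir_signal(meta$ti, meta$tr, tissue$t1, te, tissue$t2),
    lfs_validation_error(sprintf("unsupported sequence family '%s'", meta$sequence_family))
  )
}
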