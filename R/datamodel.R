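#' Acquisition metadata
#'
#' Bundles the sequence parameters that determine both the steady-state signal
#' and the noise statistics of an acquisition. All quantities are SI: seconds,
#' tesla, hertz, radians. The command-line interface accepts the units the
#' protocols are usually quoted in (ms, degrees, kHz) and converts on entry.
#'
#' @param b0 Main field strength in tesla (> 0).
#' @param tr Repetition time in seconds (> 0).
#' @param te Echo time(s) in seconds, one per echo; each must lie in (0, tr).
#' @param flip_angle Excitation flip angle in radians, in (0, pi].
#' @param bandwidth Total readout bandwidth in hertz (> 0).
#' @param sequence_family One of `"SPGR"` (spoiled gradient echo; also covers
#'   GRE/FLASH), `"SE"` (spin echo), `"bSSFP"` (balanced SSFP), `"IR"`
#'   (inversion recovery).
#' @param ti Inversion time in seconds (IR only), or `NULL`.
#' @param partial_fourier_fraction Fraction q in (0.5, 1] of phase-encode lines
#'   acquired: lines 1..ceil(q*N) of an N-line grid whose DC line is N/2+1.
#' @return An object of class `acq_meta`.
#' @export
acq_meta <- function(b0, tr, te, flip_angle, bandwidth,
                     sequence_family = c("SPGR", "SE", "bSSFP", "IR"),
                     ti = NULL, partial_fourier_fraction = 1.0) {
  sequence_family <- match.arg(sequence_family)
  for (nm in c("b0", "tr", "flip_angle", "bandwidth", "partial_fourier_fraction")) {
    v <- get(nm)
    if (!is_scalar_num(v)) lfs_validation_error(sprintf("%s must be a single finite number", nm))
  }
  if (!is.numeric(te) || length(te) < 1L || !all_finite(te)) {
    lfs_validation_error("te must be a finite numeric vector (one echo time per echo)")
  }
  if (b0 <= 0) lfs_validation_error("b0 must be > 0 tesla")
  if (tr <= 0) lfs_validation_error("tr must be > 0 s")
  if (any(te <= 0) || any(te >= tr)) lfs_validation_error("each te must lie in (0, tr)")
  if (flip_angle <= 0 || flip_angle > pi) lfs_validation_error("flip_angle must be in (0, pi] radians")
  if (bandwidth <= 0) lfs_validation_error("bandwidth must be > 0 Hz")
  if (partial_fourier_fraction <= 0.5 || partial_fourier_fraction > 1) {
    lfs_validation_error("partial_fourier_fraction must be in (0.5, 1]")
  }
  if (!is.null(ti)) {
    if (!is_scalar_num(ti) || ti <= 0) lfs_validation_error("ti must be a single positive number or NULL")
  }
  if (sequence_family == "IR" && is.null(ti)) {
    lfs_validation_error("sequence_family 'IR' requires an inversion time ti")
  }
  structure(
    list(b0 = b0, tr = tr, te = as.numeric(te), ti = ti,
         flip_angle = flip_angle, bandwidth = bandwidth,
         partial_fourier_fraction = partial_fourier_fraction,
         sequence_family = sequence_family),
    class = "acq_meta"
  )
}

#' Tissue relaxation parameters
#'
#' Proton density and relaxation times of the dominant species at a stated
#' field. The optional `r2prime_per_tesla` encodes the susceptibility-driven
#' contribution to effective transverse relaxation as a single rate per tesla,
#' so that 1/T2* = 1/T2 + r2prime_per_tesla * B0 (the product of gyromagnetic
#' ratio, geometry constant and ppm inhomogeneity is not separately
#' identifiable and is never exposed).
#'
#' @param pd Proton density, dimensionless, >= 0.
#' @param t1,t2 Longitudinal and transverse relaxation times in seconds (> 0).
#' @param r2prime_per_tesla Optional additional transverse relaxation rate per
#'   tesla (1/(s*T), >= 0); `NULL` means T2* is unknown.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(pd, t1, t2, r2prime_per_tesla = NULL) {
  if (!is_scalar_num(pd) || pd < 0) lfs_validation_error("pd must be a single number >= 0")
  if (!is_scalar_num(t1) || t1 <= 0) lfs_domain_error("t1 must be a single number > 0 s")
  if (!is_scalar_num(t2) || t2 <= 0) lfs_domain_error("t2 must be a single number > 0 s")
  if (!is.null(r2prime_per_tesla)) {
    if (!is_scalar_num(r2prime_per_tesla) || r2prime_per_tesla < 0) {
      lfs_domain_error("r2prime_per_tesla must be >= 0 or NULL")
    }
  }
  if (t1 < t2) warning("t1 < t2 is unphysical for most tissues; proceeding anyway", call. = FALSE)
  structure(list(pd = pd, t1 = t1, t2 = t2, r2prime_per_tesla = r2prime_per_tesla),
            class = "tissue_params")
}

#' Channel noise covariance
#'
#' Covariance of the REAL part of the channel thermal noise (the imaginary
#' part is modelled as independent with the same covariance, the body-noise
#' convention), so the total complex variance of channel i is `2 * sigma[i,i]`.
#'
#' @param sigma k x k symmetric positive semi-definite matrix in squared
#'   sample units.
#' @return An object of class `noise_covariance`.
#' @export
noise_covariance <- function(sigma) {
  if (!is.matrix(sigma) || !is.numeric(sigma) || nrow(sigma) != ncol(sigma)) {
    lfs_validation_error("sigma must be a square numeric matrix")
  }
  if (!all_finite(sigma)) lfs_validation_error("sigma contains non-finite values")
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    lfs_validation_error("sigma must be symmetric")
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), .Machine$double.eps)) {
    lfs_validation_error(sprintf(
      "sigma is not positive semi-definite (eigenvalue %.6g)", min(ev)))
  }
  structure(list(sigma = sigma), class = "noise_covariance")
}

#' @export
dim.noise_covariance <- function(x) dim(x$sigma)

#' Multi-channel k-space container
#'
#' Complex k-space samples indexed `(channel, echo, phase-encode, readout)`
#' together with the sampling mask over `(phase-encode, readout)` and the
#' acquisition metadata. Unacquired positions must be exactly zero. The DC
#' sample sits at the array centre (`floor(N/2)+1` along each image dimension)
#' and all transforms in the package are centred and unitary.
#'
#' @param samples Complex 4-D array `(channel, echo, phase-encode, readout)`.
#' @param mask Logical matrix `(phase-encode, readout)`; `TRUE` = acquired.
#'   `NULL` derives the mask from `meta$partial_fourier_fraction`.
#' @param meta An [acq_meta()] object; `length(meta$te)` must equal the echo
#'   dimension.
#' @param provenance Optional list recording how the data were produced
#'   (seed, scaling, source); carried through I/O round trips.
#' @return An object of class `kspace_data`.
#' @export
kspace_data <- function(samples, mask = NULL, meta, provenance = list()) {
  if (!is.array(samples) || length(dim(samples)) != 4L) {
    lfs_validation_error("samples must be a 4-D array (channel, echo, phase-encode, readout)")
  }
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  if (!all_finite(samples)) lfs_validation_error("samples contain NaN or Inf")
  if (!inherits(meta, "acq_meta")) lfs_validation_error("meta must be an acq_meta object")
  d <- dim(samples)
  if (d[1] < 1L) lfs_validation_error("channel count must be >= 1")
  if (d[2] < 1L) lfs_validation_error("echo count must be >= 1")
  if (length(meta$te) != d[2]) {
    lfs_validation_error(sprintf("meta records %d echo time(s) but samples have %d echo(es)",
                                 length(meta$te), d[2]))
  }
  if (is.null(mask)) mask <- partial_fourier_mask(d[3], d[4], meta$partial_fourier_fraction)
  if (!is.matrix(mask) || !is.logical(mask) || any(dim(mask) != d[3:4])) {
    lfs_validation_error("mask must be a logical (phase-encode, readout) matrix matching samples")
  }
  obj <- structure(list(samples = samples, mask = mask, meta = meta,
                        provenance = provenance),
                   class = "kspace_data")
  unacq <- which(!mask)
  if (length(unacq)) {
    for (ch in seq_len(d[1])) for (ec in seq_len(d[2])) {
      m <- matrix(samples[ch, ec, , ], d[3], d[4])
      if (any(m[unacq] != 0)) {
        lfs_validation_error("unacquired (mask = FALSE) positions must be exactly zero")
      }
    }
  }
  obj
}

#' Partial-Fourier phase-encode sampling mask
#'
#' Fraction `q` in (0.5, 1] means: one full half of phase-encode space plus a
#' fraction `q - 0.5` of the other half, i.e. lines `1..ceil(q*N)` of an
#' N-line grid whose DC line is `floor(N/2)+1`.
#'
#' @param n_pe,n_ro Grid size along phase-encode and readout.
#' @param fraction Partial-Fourier fraction q in (0.5, 1].
#' @return Logical `(n_pe, n_ro)` matrix.
#' @export
partial_fourier_mask <- function(n_pe, n_ro, fraction) {
  if (fraction <= 0.5 || fraction > 1) lfs_validation_error("fraction must be in (0.5, 1]")
  m <- matrix(FALSE, n_pe, n_ro)
  m[seq_len(ceiling(fraction * n_pe)), ] <- TRUE
  m
}

#' Field-strength scaling parameters
#'
#' The dimensionless triplet governing the simulation: `a = B0_low/B0_high`,
#' `b = BW_low/BW_high`, and the relaxation-correction factor `f` (one value
#' per echo). Feasibility requires `a^2*b >= a^4*f^2` for every echo; the
#' deficit `a^2*b - a^4*f^2` is the per-component variance scale of the noise
#' that must be added.
#'
#' @param a Field ratio in (0, 1].
#' @param b Bandwidth ratio (> 0).
#' @param f Relaxation correction factor(s), > 0, scalar or per echo.
#' @return An object of class `field_scaling` with element `add_var_scale`.
#' @export
field_scaling <- function(a, b, f = 1) {
  if (!is_scalar_num(a) || a <= 0) lfs_validation_error("a must be a single number in (0, 1]")
  if (a > 1) lfs_feasibility_error("a = B0_low/B0_high > 1: not a lower field")
  if (!is_scalar_num(b) || b <= 0) lfs_validation_error("b must be a single number > 0")
  if (!is.numeric(f) || !all_finite(f) || any(f <= 0)) {
    lfs_validation_error("f must be finite and > 0 (scalar or one value per echo)")
  }
  add_var <- a^2 * b - a^4 * f^2
  if (any(add_var < -1e-12 * a^2 * b)) {
    bad <- which.min(add_var)
    lfs_feasibility_error(sprintf(
      paste0("infeasible scaling at echo %d: a^2*b < a^4*f^2 ",
             "(a=%.4g, b=%.4g, f=%.4g); minimum feasible bandwidth ratio b = a^2*f^2 = %.6g"),
      bad, a, b, f[bad], max(a^2 * f^2)))
  }
  structure(list(a = a, b = b, f = as.numeric(f),
                 add_var_scale = pmax(add_var, 0)),
            class = "field_scaling")
}

#' Validate a k-space / covariance pair
#'
#' Reporting-only check of the container invariants and their mutual
#' consistency. Never throws for invariant violations and never mutates its
#' inputs: it returns a character vector of human-readable violations, empty
#' when everything holds.
#'
#' @param kspace A [kspace_data()] object (or candidate list with the same
#'   fields).
#' @param cov Optional [noise_covariance()] (or plain matrix) to check against
#'   the channel dimension.
#' @return Character vector of violations; `character(0)` if none.
#' @export
validate_kspace <- function(kspace, cov = NULL) {
  v <- character(0)
  d <- dim(kspace$samples)
  if (is.null(d) || length(d) != 4L) {
    return("samples is not a 4-D (channel, echo, phase-encode, readout) array")
  }
  if (!all_finite(kspace$samples)) v <- c(v, "samples contain non-finite values")
  if (d[1] < 1L) v <- c(v, "channel count < 1")
  if (d[2] < 1L) v <- c(v, "echo count < 1")
  if (!is.null(kspace$meta) && length(kspace$meta$te) != d[2]) {
    v <- c(v, sprintf("echo count mismatch: %d echoes vs %d echo times in metadata",
                      d[2], length(kspace$meta$te)))
  }
  msk <- kspace$mask
  if (is.null(msk) || !is.logical(msk) || any(dim(msk) != d[3:4])) {
    v <- c(v, "mask missing or not a logical (phase-encode, readout) matrix matching samples")
  } else if (any(!msk)) {
    unacq <- which(!msk)
    for (ch in seq_len(d[1])) for (ec in seq_len(d[2])) {
      m <- matrix(kspace$samples[ch, ec, , ], d[3], d[4])
      if (any(m[unacq] != 0)) {
        v <- c(v, "unacquired positions are not exactly zero")
        break
      }
    }
  }
  if (!is.null(cov)) {
    s <- if (inherits(cov, "noise_covariance")) cov$sigma else cov
    if (!is.matrix(s) || nrow(s) != ncol(s)) {
      v <- c(v, "covariance is not a square matrix")
    } else {
      if (nrow(s) != d[1]) {
        v <- c(v, sprintf("channel-count mismatch: %d k-space channels vs %d x %d covariance",
                          d[1], nrow(s), ncol(s)))
      }
      if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) {
        v <- c(v, "covariance is not symmetric")
      } else {
        ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-10 * max(abs(ev), .Machine$double.eps)) {
          v <- c(v, sprintf("covariance is not positive semi-definite (eigenvalue %.6g)", min(ev)))
        }
      }
    }
  }
  v
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("kspace_data: %d channel(s), %d echo(es), %d x %d (PE x RO)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  B0 %.3g T | TR %.3g ms | TE %s ms | flip %.3g deg | BW %.3g kHz | PF %.3g\n",
              x$meta$b0, 1e3 * x$meta$tr,
              paste(signif(1e3 * x$meta$te, 3), collapse = "/"),
              180 / pi * x$meta$flip_angle, x$meta$bandwidth / 1e3,
              x$meta$partial_fourier_fraction))
  cat(sprintf("  %s | %.1f%% of k-space acquired\n",
              x$meta$sequence_family, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.field_scaling <- function(x, ...) {
  cat(sprintf("field_scaling: a = %.4g, b = %.4g, f = %s; additive variance scale %s\n",
              x$a, x$b, paste(signif(x$f, 4), collapse = ", "),
              paste(signif(x$add_var_scale, 4), collapse = ", ")))
  invisible(x)
}
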