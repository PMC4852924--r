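# Cartesian reconstruction (zero-filled iFFT and partial-Fourier homodyne),
# sum-of-squares coil combination, magnitude SNR with Rayleigh correction,
# region-growing segmentation, and Dice overlap.

#' Zero-filled inverse FFT reconstruction
#'
#' Centred unitary inverse transform of each channel/echo plane; the same
#' normalisation as the forward acquisition, so noiseless round trips are
#' exact and noise variance is preserved between domains.
#'
#' @param kspace A [kspace_data()] object.
#' @return Complex array `(channel, echo, phase-encode, readout)`.
#' @export
ifft_recon <- function(kspace) {
  d <- dim(kspace$samples)
  out <- array(complex(real = 0, imaginary = 0), d)
  for (ch in seq_len(d[1])) for (ec in seq_len(d[2])) {
    out[ch, ec, , ] <- ifft2c(matrix(kspace$samples[ch, ec, , ], d[3], d[4]))
  }
  out
}

# Homodyne ramp weights and symmetric-band bounds along phase-encode.
homodyne_weights <- function(n_pe, fraction) {
  m <- ceiling(fraction * n_pe)
  ctr <- n_pe %/% 2L + 1L
  s <- 2L * ctr - m                 # first row of the conjugate-symmetric band
  w <- numeric(n_pe)
  w[seq_len(max(s - 1L, 0L))] <- 2
  band <- s:m
  w[band] <- 1 - (band - ctr) / (m - ctr + 1)
  list(w = w, band = band, m = m)
}

#' Homodyne partial-Fourier reconstruction
#'
#' Standard homodyne recovery: the conjugate-symmetric centre band (width
#' `2*(q - 0.5)*N` phase-encode lines) provides a low-resolution phase
#' estimate (Hamming-apodised); acquired lines are ramp-weighted so that each
#' symmetric pair sums to weight 2; the image is phase-demodulated and its
#' real part taken. With full sampling (`q = 1`) the result equals the
#' magnitude of the zero-filled reconstruction exactly.
#'
#' @param kspace A [kspace_data()] with `partial_fourier_fraction` in (0.5, 1].
#' @return Real array `(channel, echo, phase-encode, readout)`.
#' @export
homodyne_recon <- function(kspace) {
  q <- kspace$meta$partial_fourier_fraction
  if (q <= 0.5) lfs_domain_error("homodyne needs partial_fourier_fraction > 0.5")
  d <- dim(kspace$samples)
  out <- array(0, d)
  if (q >= 1) {
    img <- ifft_recon(kspace)
    return(abs(img))
  }
  hw <- homodyne_weights(d[3], q)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_along(hw$band) - 1) / (length(hw$band) - 1))
  for (ch in seq_len(d[1])) for (ec in seq_len(d[2])) {
    k <- matrix(kspace$samples[ch, ec, , ], d[3], d[4])
    kw <- k * hw$w
    kc <- matrix(complex(real = 0, imaginary = 0), d[3], d[4])
    kc[hw$band, ] <- k[hw$band, ] * ham
    phase <- Arg(ifft2c(kc))
    out[ch, ec, , ] <- Re(ifft2c(kw) * exp(-1i * phase))
  }
  out
}

#' Sum-of-squares coil combination
#'
#' Pixelwise root-sum-of-squares of per-channel magnitudes.
#'
#' @param images Complex or real array `(channel, echo, phase-encode,
#'   readout)` as returned by [ifft_recon()] / [homodyne_recon()], or a matrix
#'   (single channel/echo).
#' @return Magnitude array `(echo, phase-encode, readout)`, dropped to a
#'   matrix when there is a single echo.
#' @export
sos_combine <- function(images) {
  if (is.matrix(images)) return(abs(images))
  d <- dim(images)
  if (length(d) != 4L) lfs_validation_error("images must be a (channel, echo, pe, ro) array")
  out <- array(0, d[2:4])
  for (ec in seq_len(d[2])) {
    acc <- matrix(0, d[3], d[4])
    for (ch in seq_len(d[1])) acc <- acc + abs(matrix(images[ch, ec, , ], d[3], d[4]))^2
    out[ec, , ] <- sqrt(acc)
  }
  if (d[2] == 1L) matrix(out[1, , ], d[3], d[4]) else out
}

#' Magnitude-image SNR
#'
#' `SNR = mean(signal ROI) / sigma_hat` where `sigma_hat` estimates the
#' underlying per-component Gaussian noise level. On a magnitude image the
#' signal-free background is Rayleigh distributed with
#' `sd = sigma * sqrt(2 - pi/2)`; with `rayleigh_correct = TRUE` (default) the
#' background standard deviation is divided by that factor to recover
#' `sigma`. For multi-channel sum-of-squares images the background is central
#' chi rather than Rayleigh and the correction is approximate (a warning can
#' be silenced by passing `rayleigh_correct = FALSE` and supplying calibrated
#' noise externally).
#'
#' @param image Numeric (magnitude) matrix.
#' @param signal_roi,noise_roi Logical masks (same dimensions as `image`) or
#'   index vectors; must be disjoint and non-empty, with `noise_roi` outside
#'   the object.
#' @param rayleigh_correct Divide background sd by `sqrt(2 - pi/2)`.
#' @return SNR (dimensionless); `Inf` with a warning when the background has
#'   zero spread.
#' @export
measure_snr <- function(image, signal_roi, noise_roi, rayleigh_correct = TRUE) {
  as_idx <- function(roi) {
    if (is.logical(roi)) {
      if (!all(dim(roi) == dim(image))) lfs_validation_error("ROI mask dimensions must match image")
      which(roi)
    } else as.integer(roi)
  }
  si <- as_idx(signal_roi); ni <- as_idx(noise_roi)
  if (!length(si) || !length(ni)) lfs_validation_error("ROIs must be non-empty")
  if (length(intersect(si, ni))) lfs_validation_error("signal and noise ROIs must be disjoint")
  s <- mean(image[si])
  sdev <- stats::sd(image[ni])
  if (sdev == 0) {
    warning("noise ROI has zero spread: SNR is infinite", call. = FALSE)
    return(Inf)
  }
  sigma <- if (rayleigh_correct) sdev / sqrt(2 - pi / 2) else sdev
  s / sigma
}

#' SNR statistics over repeated reconstructions
#'
#' Per-repeat SNR followed by sample mean/sd and a 95% confidence interval of
#' the mean.
#'
#' @param images List of magnitude matrices (one per repeat).
#' @inheritParams measure_snr
#' @return List with `mean`, `sd` (`NA` for a single repeat), `ci_halfwidth`,
#'   `n`, and the per-repeat `values`.
#' @export
snr_statistics <- function(images, signal_roi, noise_roi, rayleigh_correct = TRUE) {
  vals <- vapply(images, measure_snr, numeric(1),
                 signal_roi = signal_roi, noise_roi = noise_roi,
                 rayleigh_correct = rayleigh_correct)
  n <- length(vals)
  list(mean = mean(vals),
       sd = if (n > 1) stats::sd(vals) else NA_real_,
       ci_halfwidth = if (n > 1) ci_halfwidth(vals) else NA_real_,
       n = n, values = vals)
}

#' Region-growing segmentation
#'
#' Deterministic 4-connected (optionally 8-connected) flood fill from a seed
#' pixel: a neighbouring pixel joins the region when its value lies within an
#' absolute band `threshold` of the running mean of the pixels accepted so
#' far. Neighbours are visited in a fixed order (up, down, left, right) from a
#' FIFO queue, so results are reproducible.
#'
#' @param image Numeric matrix.
#' @param seed_point `c(row, col)` inside the image.
#' @param threshold Absolute acceptance band around the running region mean.
#' @param connectivity 4 or 8.
#' @return Logical mask of the grown region.
#' @export
region_grow <- function(image, seed_point, threshold, connectivity = 4) {
  ny <- nrow(image); nx <- ncol(image)
  r0 <- as.integer(seed_point[1]); c0 <- as.integer(seed_point[2])
  if (r0 < 1 || r0 > ny || c0 < 1 || c0 > nx) lfs_validation_error("seed point out of bounds")
  if (threshold < 0) lfs_domain_error("threshold must be >= 0")
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1), dc = c(0, 0, -1, 1, -1, 1, -1, 1))
  } else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  inreg <- matrix(FALSE, ny, nx)
  queued <- matrix(FALSE, ny, nx)
  queue <- integer(ny * nx); qh <- 1L; qt <- 1L
  lin <- function(r, c) (c - 1L) * ny + r
  queue[qt] <- lin(r0, c0); qt <- qt + 1L; queued[r0, c0] <- TRUE
  total <- 0; count <- 0L
  while (qh < qt) {
    p <- queue[qh]; qh <- qh + 1L
    r <- ((p - 1L) %% ny) + 1L
    cc <- ((p - 1L) %/% ny) + 1L
    v <- image[r, cc]
    if (count > 0L && abs(v - total / count) > threshold) next
    inreg[r, cc] <- TRUE
    total <- total + v; count <- count + 1L
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1L]; cn <- cc + offs[k, 2L]
      if (rr >= 1L && rr <= ny && cn >= 1L && cn <= nx && !queued[rr, cn]) {
        queued[rr, cn] <- TRUE
        queue[qt] <- lin(rr, cn); qt <- qt + 1L
      }
    }
  }
  inreg
}

#' Dice overlap coefficient
#'
#' `2|A∩B| / (|A| + |B|)`. Two empty masks agree on absence and return 1 with
#' a warning.
#'
#' @param mask_a,mask_b Logical masks of identical dimensions.
#' @return Overlap in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) lfs_validation_error("mask dimensions differ")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) {
    warning("both masks empty: Dice defined as 1 (agreement on absence)", call. = FALSE)
    return(1)
  }
  2 * sum(mask_a & mask_b) / (na + nb)
}
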