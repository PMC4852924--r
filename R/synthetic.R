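# Digital phantoms and forward acquisition: everything needed to exercise the
# simulator without scanner data. Phantoms are rendered at 4x resolution and
# box-downsampled so region edges are anti-aliased (reduces Gibbs ringing that
# would otherwise contaminate SNR regions of interest).

new_phantom <- function(grid, frac, labels, tissues, sens) {
  structure(list(grid = grid, frac = frac, labels = labels,
                 tissues = tissues, coil_sensitivities = sens),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital_phantom: %d x %d grid, %d region(s) [%s], %d channel(s)\n",
              x$grid[1], x$grid[2], length(x$tissues),
              paste(names(x$tissues), collapse = ", "),
              dim(x$coil_sensitivities)[3]))
  invisible(x)
}

# Box-downsample an (os*ny, os*nx) matrix to (ny, nx) by block means.
box_downsample <- function(m, os) {
  ny <- nrow(m) / os; nx <- ncol(m) / os
  a <- array(m, c(os, ny, os, nx))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Smooth complex coil sensitivity maps: Gaussian magnitude lobes centred on a
# ring around the object plus a gentle low-order polynomial phase; identical
# across simulated fields (the receive chain is assumed unchanged). Normalised
# to unit mean magnitude over the object support.
make_coil_sensitivities <- function(grid, n_channels, object_mask, flat = FALSE) {
  ny <- grid[1]; nx <- grid[2]
  sens <- array(complex(real = 1, imaginary = 0), c(ny, nx, n_channels))
  if (!flat) {
    yy <- matrix(seq_len(ny) - (ny + 1) / 2, ny, nx)
    xx <- matrix(seq_len(nx) - (nx + 1) / 2, ny, nx, byrow = TRUE)
    r0 <- 0.6 * min(ny, nx)
    w <- 0.9 * min(ny, nx)
    for (ch in seq_len(n_channels)) {
      phi <- 2 * pi * (ch - 1) / n_channels
      cy <- r0 * sin(phi); cx <- r0 * cos(phi)
      mag <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * w^2))
      ph <- 2 * pi * (0.1 * sin(phi) * xx / nx + 0.1 * cos(phi) * yy / ny +
                        0.05 * xx * yy / (nx * ny) * cos(2 * phi))
      sens[, , ch] <- mag * exp(1i * ph)
    }
  }
  for (ch in seq_len(n_channels)) {
    s <- sens[, , ch]
    mbar <- mean(abs(s[object_mask]))
    sens[, , ch] <- s / mbar
  }
  sens
}

render_regions <- function(grid, painter, tissues, n_channels, flat_coils,
                           oversample = 4L) {
  ny <- grid[1]; nx <- grid[2]; os <- oversample
  yy <- matrix((seq_len(os * ny) - 0.5) / os, os * ny, os * nx)
  xx <- matrix((seq_len(os * nx) - 0.5) / os, os * ny, os * nx, byrow = TRUE)
  lab_hi <- painter(yy, xx)                      # integer region ids on fine grid
  nreg <- length(tissues)
  frac <- array(0, c(ny, nx, nreg))
  for (r in seq_len(nreg)) frac[, , r] <- box_downsample((lab_hi == r) + 0, os)
  labels <- apply(frac, c(1, 2), which.max)
  pd <- vapply(tissues, function(t) t$pd, numeric(1))
  object <- matrix(FALSE, ny, nx)
  for (r in seq_len(nreg)) if (pd[r] > 0) object <- object | (frac[, , r] > 0.5)
  sens <- make_coil_sensitivities(grid, n_channels, object, flat = flat_coils)
  new_phantom(grid, frac, labels, tissues, sens)
}

#' Resolution phantom
#'
#' Deterministic digital phantom emulating a doped-water resolution phantom: a
#' uniform disk background containing groups of resolution bars of widths 1-4
#' pixels, surrounded by signal-free air. Tissue parameters of the two classes
#' are user-settable; defaults are representative doped-water values (T1
#' 600 ms, T2 100 ms), not measured phantom values.
#'
#' @param grid `c(n_pe, n_ro)`, each >= 32.
#' @param background,bars [tissue_params()] of the disk and the bar inserts.
#' @param n_channels Number of receive channels.
#' @param flat_coils Use unit sensitivities (single-channel-style, real).
#' @return A `digital_phantom`.
#' @export
make_resolution_phantom <- function(grid = c(256, 160),
                                    background = tissue_params(pd = 1, t1 = 0.6, t2 = 0.1),
                                    bars = tissue_params(pd = 0.4, t1 = 0.3, t2 = 0.05),
                                    n_channels = 1L, flat_coils = FALSE) {
  if (any(grid < 32)) lfs_validation_error("grid must be at least 32 x 32")
  ny <- grid[1]; nx <- grid[2]
  cy <- ny / 2; cx <- nx / 2
  rad <- 0.42 * min(ny, nx)
  widths <- c(1, 2, 3, 4)
  painter <- function(yy, xx) {
    lab <- matrix(1L, nrow(yy), ncol(xx))          # air
    disk <- (yy - cy)^2 + (xx - cx)^2 <= rad^2
    lab[disk] <- 2L                                 # background
    # four bar groups, stacked vertically, centred horizontally
    y0 <- cy - 0.3 * min(ny, nx)
    for (g in seq_along(widths)) {
      w <- widths[g]
      gy <- y0 + (g - 1) * 0.2 * min(ny, nx)
      for (k in 0:2) {                              # 3 bars per group
        x0 <- cx - 3 * w + k * 2 * w
        bar <- disk & yy >= gy & yy < gy + 0.08 * min(ny, nx) &
          xx >= x0 & xx < x0 + w
        lab[bar] <- 3L
      }
    }
    lab
  }
  render_regions(grid, painter,
                 tissues = list(air = tissue_params(0, 1, 0.5),
                                background = background, bars = bars),
                 n_channels = n_channels, flat_coils = flat_coils)
}

#' Airway phantom sequence
#'
#' Frames of a bright tissue disk containing a dark (PD = 0) airway lumen of
#' time-varying radius, emulating axial upper-airway imaging over breathing
#' cycles. Ground-truth lumen masks (pixels with majority lumen occupancy)
#' are returned alongside each frame.
#'
#' @param grid `c(n_pe, n_ro)`, each >= 32.
#' @param lumen_radius_series Lumen radius in pixels per frame (>= 0).
#' @param tissue [tissue_params()] of the surrounding tissue; default is
#'   muscle-like (T1 1.4 s, T2 30 ms).
#' @param n_channels Number of receive channels (the in-vivo protocol used 6).
#' @param flat_coils Use unit sensitivities.
#' @return List with `frames` (list of `digital_phantom`) and `truth_masks`
#'   (list of logical matrices marking the lumen).
#' @export
make_airway_phantom <- function(grid = c(64, 64),
                                lumen_radius_series = airway_radius_series(),
                                tissue = tissue_params(pd = 1, t1 = 1.4, t2 = 0.03),
                                n_channels = 6L, flat_coils = FALSE) {
  if (any(grid < 32)) lfs_validation_error("grid must be at least 32 x 32")
  if (any(lumen_radius_series < 0)) lfs_domain_error("lumen radii must be >= 0")
  ny <- grid[1]; nx <- grid[2]
  cy <- ny / 2; cx <- nx / 2
  rad <- 0.42 * min(ny, nx)
  tissues <- list(air = tissue_params(0, 1, 0.5), tissue = tissue,
                  lumen = tissue_params(0, 1, 0.5))
  frames <- vector("list", length(lumen_radius_series))
  truth <- vector("list", length(lumen_radius_series))
  for (i in seq_along(lumen_radius_series)) {
    r <- lumen_radius_series[i]
    painter <- function(yy, xx) {
      lab <- matrix(1L, nrow(yy), ncol(xx))
      disk <- (yy - cy)^2 + (xx - cx)^2 <= rad^2
      lab[disk] <- 2L
      if (r > 0) lab[disk & ((yy - cy)^2 + (xx - cx)^2 <= r^2)] <- 3L
      lab
    }
    ph <- render_regions(grid, painter, tissues, n_channels, flat_coils)
    frames[[i]] <- ph
    truth[[i]] <- ph$frac[, , 3] >= 0.5
  }
  list(frames = frames, truth_masks = truth)
}

#' Breathing-cycle lumen radius series
#'
#' Sinusoidal open/collapse pattern: `n_frames` frames spanning `n_breaths`
#' cycles between `r_open` and `r_collapsed` pixels.
#'
#' @param n_frames,n_breaths Temporal sampling (defaults emulate 100 frames
#'   over 3 breaths).
#' @param r_open,r_collapsed Radii in pixels at full opening / collapse.
#' @return Numeric vector of radii.
#' @export
airway_radius_series <- function(n_frames = 100, n_breaths = 3,
                                 r_open = 8, r_collapsed = 2) {
  mid <- (r_open + r_collapsed) / 2
  amp <- (r_open - r_collapsed) / 2
  t <- seq_len(n_frames) - 1
  mid + amp * sin(2 * pi * n_breaths * t / n_frames)
}

# Complex per-voxel transverse signal map for one echo, including the B0^2
# amplitude prefactor (reference 1 T) and coil sensitivity.
phantom_signal_map <- function(phantom, meta, te) {
  ny <- phantom$grid[1]; nx <- phantom$grid[2]
  sig <- matrix(0, ny, nx)
  for (r in seq_along(phantom$tissues)) {
    ts <- phantom$tissues[[r]]
    if (ts$pd <= 0) next
    s <- sequence_signal(meta, ts, te = te)
    sig <- sig + phantom$frac[, , r] * ts$pd * s
  }
  sig * (meta$b0 / 1.0)^2
}

#' Forward acquisition of a digital phantom
#'
#' Per-voxel steady-state signal (sequence equation of `meta$sequence_family`,
#' scaled by the `B0^2` amplitude prefactor relative to 1 T) times the complex
#' coil sensitivity, transformed to k-space with the centred unitary FFT,
#' masked to the partial-Fourier pattern, and corrupted with correlated channel
#' noise of per-component covariance `cov` on acquired positions.
#'
#' Because the `B0^2` prefactor is applied here, acquiring at a high field and
#' simulating down should be statistically indistinguishable from acquiring
#' directly at the low field with covariance `a^2 b * Sigma` — the package's
#' central consistency property.
#'
#' @param phantom A `digital_phantom`.
#' @param meta An [acq_meta()]; channel count of `cov` must match the phantom.
#' @param cov [noise_covariance()] per real component, or `NULL` for noiseless.
#' @param seed Integer seed for the noise draw.
#' @return A [kspace_data()].
#' @export
forward_acquire <- function(phantom, meta, cov = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"), inherits(meta, "acq_meta"))
  ny <- phantom$grid[1]; nx <- phantom$grid[2]
  nc <- dim(phantom$coil_sensitivities)[3]
  if (!is.null(cov)) {
    sig <- if (inherits(cov, "noise_covariance")) cov$sigma else cov
    if (nrow(sig) != nc) {
      lfs_validation_error(sprintf(
        "phantom has %d channel(s) but covariance is %d x %d", nc, nrow(sig), ncol(sig)))
    }
  }
  ne <- length(meta$te)
  samples <- array(complex(real = 0, imaginary = 0), c(nc, ne, ny, nx))
  msk <- partial_fourier_mask(ny, nx, meta$partial_fourier_fraction)
  idx <- which(msk)
  for (ec in seq_len(ne)) {
    base <- phantom_signal_map(phantom, meta, meta$te[ec])
    for (ch in seq_len(nc)) {
      k <- fft2c(base * phantom$coil_sensitivities[, , ch])
      k[!msk] <- 0
      samples[ch, ec, , ] <- k
    }
    if (!is.null(cov)) {
      n <- sample_noise(cov, length(idx), 1,
                        seed = if (is.null(seed)) NULL else seed + (ec - 1L))
      m <- matrix(samples[, ec, , , drop = FALSE], nc, ny * nx)
      m[, idx] <- m[, idx] + n
      samples[, ec, , ] <- array(m, c(nc, ny, nx))
    }
  }
  kspace_data(samples, msk, meta,
              provenance = list(acquired = list(synthetic = TRUE, seed = seed,
                                                b0 = meta$b0)))
}
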