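# Channel noise: covariance estimation from RF-off data and correlated
# complex Gaussian sampling. Convention throughout: the stored covariance is
# that of the REAL component; the imaginary component is i.i.d. with the same
# covariance.

#' Estimate channel noise covariance from noise-only data
#'
#' Pools the sample covariances of the real and imaginary components,
#' `0.5 * (cov(Re) + cov(Im))` with 1/(N-1) normalisation, as measured from an
#' acquisition with RF turned off. A warning is raised when the two component
#' covariances differ by more than 20% in Frobenius norm, which indicates
#' quadrature imbalance the shared-covariance model cannot represent.
#'
#' @param noise_samples Complex matrix `(channel, sample)`.
#' @return A [noise_covariance()] object.
#' @export
estimate_covariance <- function(noise_samples) {
  if (is.vector(noise_samples)) noise_samples <- matrix(noise_samples, nrow = 1L)
  if (!is.matrix(noise_samples)) {
    lfs_validation_error("noise_samples must be a (channel, sample) matrix")
  }
  if (!all_finite(noise_samples)) lfs_validation_error("noise_samples contain NaN or Inf")
  if (ncol(noise_samples) < 2L) {
    lfs_domain_error("need at least 2 noise samples per channel to estimate a covariance")
  }
  re <- t(Re(noise_samples))
  im <- t(Im(noise_samples))
  c_re <- stats::cov(re)
  c_im <- stats::cov(im)
  fro <- function(m) sqrt(sum(m^2))
  denom <- max(fro(c_re), fro(c_im), .Machine$double.eps)
  if (fro(c_re - c_im) > 0.2 * denom) {
    warning(sprintf(paste0(
      "real and imaginary component covariances differ by %.1f%% (Frobenius); ",
      "quadrature imbalance is not representable by a shared covariance"),
      100 * fro(c_re - c_im) / denom), call. = FALSE)
  }
  noise_covariance((c_re + c_im) / 2)
}

# Factorize a PSD matrix: Cholesky when possible, otherwise eigendecomposition
# with small negative eigenvalues (>= -1e-10 * lambda_max) clipped to zero.
psd_factor <- function(sigma) {
  L <- tryCatch(t(chol(sigma)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  eg <- eigen(sigma, symmetric = TRUE)
  lmax <- max(abs(eg$values), .Machine$double.eps)
  if (min(eg$values) < -1e-10 * lmax) {
    lfs_domain_error(sprintf(
      "covariance is not positive semi-definite: eigenvalue %.6g (most negative)",
      min(eg$values)))
  }
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow = length(eg$values))
}

#' Draw correlated complex Gaussian channel noise
#'
#' Real and imaginary parts are independent, each multivariate normal across
#' channels with covariance `variance_scale * cov`, independent across k-space
#' positions. Deterministic given `seed`.
#'
#' @param cov A [noise_covariance()] object (or plain PSD matrix).
#' @param n_positions Number of independent k-space positions to draw.
#' @param variance_scale Non-negative multiplier of the covariance.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Complex `(channel, n_positions)` matrix.
#' @export
sample_noise <- function(cov, n_positions, variance_scale = 1, seed = NULL) {
  sigma <- if (inherits(cov, "noise_covariance")) cov$sigma else cov
  if (!is.matrix(sigma)) lfs_validation_error("cov must be a matrix or noise_covariance")
  if (!is_scalar_num(variance_scale) || variance_scale < 0) {
    lfs_domain_error("variance_scale must be a single number >= 0")
  }
  k <- nrow(sigma)
  n_positions <- as.integer(n_positions)
  if (variance_scale == 0) {
    return(matrix(complex(real = 0, imaginary = 0), k, n_positions))
  }
  L <- psd_factor(sigma) * sqrt(variance_scale)
  with_seed(seed, {
    zr <- matrix(stats::rnorm(k * n_positions), k, n_positions)
    zi <- matrix(stats::rnorm(k * n_positions), k, n_positions)
    matrix(complex(real = L %*% zr, imaginary = L %*% zi), k, n_positions)
  })
}
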