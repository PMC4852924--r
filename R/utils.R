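# Internal helpers: classed conditions, seeded RNG scoping, centered FFTs.

lfs_error <- function(msg, class) {
  stop(structure(
    class = c(class, "lfs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

lfs_validation_error  <- function(msg) lfs_error(msg, "lfs_validation_error")
lfs_feasibility_error <- function(msg) lfs_error(msg, "lfs_feasibility_error")
lfs_io_error          <- function(msg) lfs_error(msg, "lfs_io_error")
lfs_domain_error      <- function(msg) lfs_error(msg, "lfs_domain_error")
lfs_convergence_error <- function(msg) lfs_error(msg, "lfs_convergence_error")

# Evaluate expr with the global RNG state set from `seed`, restoring the
# caller's RNG state afterwards. seed = NULL runs expr with the ambient state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    lfs_domain_error("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

all_finite <- function(x) {
  if (is.complex(x)) all(is.finite(Re(x))) && all(is.finite(Im(x)))
  else all(is.finite(x))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# --- centered unitary 2-D FFT -------------------------------------------------
# Convention: DC at matrix index (floor(ny/2)+1, floor(nx/2)+1); forward and
# inverse are both scaled by 1/sqrt(N) so the pair is unitary (Parseval holds
# exactly and white noise keeps its variance across the transform).

roll_idx <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

fftshift2 <- function(x) {
  x[roll_idx(nrow(x), nrow(x) %/% 2L), roll_idx(ncol(x), ncol(x) %/% 2L), drop = FALSE]
}

ifftshift2 <- function(x) {
  x[roll_idx(nrow(x), -(nrow(x) %/% 2L)), roll_idx(ncol(x), -(ncol(x) %/% 2L)), drop = FALSE]
}

fft2c <- function(img) {
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

ifft2c <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

# 95% normal-approximation confidence half-width of a sample mean.
ci_halfwidth <- function(x) {
  n <- sum(is.finite(x))
  if (n < 2) return(NA_real_)
  stats::qt(0.975, df = n - 1) * stats::sd(x[is.finite(x)]) / sqrt(n)
}
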