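#' Brute-force Bloch steady state
#'
#' Independent numerical check of the closed-form steady-state signal
#' equations. The magnetization is propagated TR by TR through discrete
#' excitation-rotation, relaxation, and spoiling/refocusing steps appropriate
#' to the sequence family, until the state stops changing; the transverse
#' magnitude at TE (per unit proton density) is returned.
#'
#' Family propagation rules:
#' * **SPGR/SE**: rotate Mz by theta, record transverse, relax Mz over TR,
#'   destroy transverse at end of TR (ideal spoiling; for SE the 180-degree
#'   refocusing removes static dephasing so decay at TE uses T2, for SPGR T2*).
#' * **bSSFP**: full 3-vector propagation with alternating +/-theta pulses
#'   about x, on-resonance relaxation over TR, echo at TE after a +theta pulse.
#' * **IR**: 180-degree inversion, relax TI, 90-degree excitation (transverse
#'   recorded, decayed by exp(-TE/T2)), relax the remaining TR - TI.
#'
#' The per-TR update is affine in the magnetization, so steady state is reached
#' by repeated squaring of the affine map (equivalent to 2^k explicit TR
#' iterations, exact to machine precision); convergence is declared when the
#' homogeneous part has contracted below `tol` and an error is raised if that
#' takes more than `n_iterations` equivalent TRs.
#'
#' @param sequence_family `"SPGR"`, `"SE"`, `"bSSFP"`, or `"IR"`.
#' @param params An [acq_meta()] object or list with `tr`, `te`, `flip_angle`,
#'   and `ti` (IR only), in seconds/radians.
#' @param tissue A [tissue_params()] object; `r2prime_per_tesla` (with
#'   `params$b0`) switches SPGR decay from T2 to T2*.
#' @param n_iterations Maximum equivalent TR count before a convergence error.
#' @param tol Contraction threshold on the homogeneous part of the propagation.
#' @return Transverse signal magnitude at each TE, per unit proton density.
#' @export
bloch_steady_state <- function(sequence_family, params, tissue,
                               n_iterations = 1e7, tol = 1e-13) {
  fam <- match.arg(sequence_family, c("SPGR", "SE", "bSSFP", "IR"))
  tr <- params$tr; te <- params$te; theta <- params$flip_angle
  t1 <- tissue$t1; t2 <- tissue$t2
  if (tr <= 0 || t1 <= 0 || t2 <= 0) lfs_domain_error("tr, t1, t2 must be > 0")

  if (fam %in% c("SPGR", "SE")) {
    t2dec <- if (fam == "SPGR" && !is.null(tissue$r2prime_per_tesla) &&
                 !is.null(params$b0)) {
      t2_effective(t2, tissue$r2prime_per_tesla, params$b0)
    } else t2
    e1 <- exp(-tr / t1)
    # one TR: Mz -> e1*cos(theta)*Mz + (1 - e1)   (M0 = 1)
    g <- e1 * cos(theta); c0 <- 1 - e1
    m <- 1; steps <- 1
    repeat {
      if (abs(g) < tol) break
      if (steps > n_iterations) {
        lfs_convergence_error(sprintf(
          "Bloch iteration did not converge within %g TRs (residual %.3g)",
          n_iterations, abs(g)))
      }
      c0 <- g * c0 + c0; g <- g * g; steps <- steps * 2
    }
    mz_ss <- g * m + c0
    return(abs(mz_ss * sin(theta)) * exp(-te / t2dec))
  }

  if (fam == "IR") {
    ti <- params$ti
    if (is.null(ti) || ti <= 0 || ti >= tr) lfs_domain_error("IR requires 0 < ti < tr")
    eti <- exp(-ti / t1); erem <- exp(-(tr - ti) / t1)
    # Over one TR (start = Mz just before inversion):
    #   invert, relax TI:          mz_ti = (1 - eti) - eti * Mz
    #   90-degree pulse:           transverse = mz_ti, Mz -> 0
    #   relax TR - TI:             Mz_end = 1 - erem
    g <- 0; c0 <- 1 - erem           # converges after one TR; keep generic form
    m <- 1; steps <- 1
    while (abs(g) >= tol) {
      if (steps > n_iterations) lfs_convergence_error("IR propagation failed to contract")
      c0 <- g * c0 + c0; g <- g * g; steps <- steps * 2
    }
    mz_pre <- g * m + c0
    mz_ti <- (1 - eti) - eti * mz_pre
    return(abs(mz_ti) * exp(-te / t2))
  }

  # bSSFP: 3-vector affine propagation over a 2-TR (+theta, -theta) cycle.
  rot_x <- function(th) matrix(c(1, 0, 0,
                                 0, cos(th), -sin(th),
                                 0, sin(th),  cos(th)), 3, 3, byrow = TRUE)
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  relax_A <- diag(c(e2, e2, e1))
  relax_c <- c(0, 0, 1 - e1)
  one_tr <- function(th) {
    A <- relax_A %*% rot_x(th)
    list(A = A, c = relax_c)
  }
  p <- one_tr(theta); m_ <- one_tr(-theta)
  # two-TR cycle starting just before a +theta pulse
  A <- m_$A %*% p$A
  cc <- m_$A %*% p$c + m_$c
  steps <- 2
  repeat {
    contraction <- max(abs(A))
    if (contraction < tol) break
    if (steps > n_iterations) {
      lfs_convergence_error(sprintf(
        "bSSFP propagation did not converge within %g TRs (residual %.3g)",
        n_iterations, contraction))
    }
    cc <- A %*% cc + cc; A <- A %*% A; steps <- steps * 2
  }
  m_pre <- as.vector(A %*% c(0, 0, 1) + cc)   # state just before a +theta pulse
  m_plus <- rot_x(theta) %*% m_pre
  mxy <- sqrt(m_plus[1]^2 + m_plus[2]^2)
  mxy * exp(-te / t2)
}
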