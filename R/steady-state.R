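rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Steady-state pc-bSSFP signal of a single compartment
#'
#' Computes the transverse magnetization at TE of the periodic steady state of
#' a balanced SSFP sequence whose RF phase advances by `phase_increment` every
#' TR. The per-TR evolution (instantaneous RF rotation, then relaxation and
#' free precession) is an affine map of the magnetization vector; in the frame
#' demodulated by the current RF phase the map is time-invariant and its fixed
#' point is obtained by a 3x3 linear solve (`method = "closed"`) or, as a
#' cross-check, by iterating the recursion to convergence
#' (`method = "iterate"`, relative change < 1e-12).
#'
#' The RF phase advances by `+phase_increment` per TR and the receiver is
#' demodulated by the phase of the exciting pulse, so a phase increment `phi`
#' is equivalent to an off-resonance shift of `-phi / (2*pi*TR)`.
#'
#' @param seq A [seq_params()] object.
#' @param tissue A one-row tissue table ([tissue_table()]).
#' @param phase_increment RF phase increment in radians.
#' @param b1_scale Transmit field scale: actual/nominal flip-angle ratio (> 0).
#' @param method `"closed"` (default) or `"iterate"`.
#' @return A complex scalar: `Mx + i My` at TE, in units of the compartment's
#'   proton density.
#' @export
#' @examples
#' s <- steady_state_signal(seq_params(), tissue_table(T1 = 1, T2 = 0.06), pi)
#' Mod(s)
steady_state_signal <- function(seq, tissue, phase_increment, b1_scale = 1,
                                method = c("closed", "iterate")) {
  method <- match.arg(method)
  validate_tissues(tissue)
  if (b1_scale <= 0) abort("`b1_scale` must be positive.")
  alpha <- b1_scale * seq$flip_nominal * pi / 180
  ss_signal_one(seq$TR, seq$TE, tissue$T1[1], tissue$T2[1], alpha,
                tissue$freq_offset[1], phase_increment, tissue$pd[1], method)
}

ss_signal_one <- function(TR, TE, T1, T2, alpha, f, phi, M0 = 1,
                          method = "closed") {
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  # net z-rotation per TR in the RF-demodulated frame
  A <- rot_z(2 * pi * f * TR - phi) %*% diag(c(E2, E2, E1)) %*% rot_x(alpha)
  b <- c(0, 0, M0 * (1 - E1))
  if (method == "closed") {
    M <- solve(diag(3) - A, b)
  } else {
    M <- c(0, 0, M0)
    for (i in seq_len(100000L)) {
      Mn <- drop(A %*% M) + b
      if (sum(abs(Mn - M)) < 1e-12 * (sum(abs(Mn)) + 1e-300)) { M <- Mn; break }
      M <- Mn
      if (i == 100000L) abort("steady-state iteration did not converge; check T1/T2.")
    }
  }
  E1t <- exp(-TE / T1); E2t <- exp(-TE / T2)
  Mte <- drop(rot_z(2 * pi * f * TE) %*% diag(c(E2t, E2t, E1t)) %*%
                rot_x(alpha) %*% M) + c(0, 0, M0 * (1 - E1t))
  complex(real = Mte[1], imaginary = Mte[2])
}

#' Simulate a phase-cycle profile
#'
#' Evaluates the proton-density-weighted sum of per-compartment steady-state
#' signals at every RF phase increment of the sequence, producing the complex
#' pc-bSSFP profile of one voxel. The exact periodic steady state is used
#' (dummy pulses are irrelevant here; the Monte Carlo engine honours them).
#'
#' @param tissues Tissue table, one row per compartment.
#' @param seq A [seq_params()] object.
#' @param b1_scale Actual/nominal flip-angle ratio.
#' @return A `bssfp_profile` tibble with columns `phase_increment` (radians)
#'   and `signal` (complex), carrying the sequence as attribute `seq`.
#' @export
#' @examples
#' prof <- simulate_profile(wm_compartments("3T"), seq_params())
#' configuration_modes(prof)
simulate_profile <- function(tissues, seq = seq_params(), b1_scale = 1) {
  validate_tissues(tissues)
  if (b1_scale <= 0) abort("`b1_scale` must be positive.")
  alpha <- b1_scale * seq$flip_nominal * pi / 180
  sig <- vapply(seq$phase_inc, function(phi) {
    s <- 0 + 0i
    for (k in seq_len(nrow(tissues))) {
      s <- s + ss_signal_one(seq$TR, seq$TE, tissues$T1[k], tissues$T2[k],
                             alpha, tissues$freq_offset[k], phi, tissues$pd[k])
    }
    s
  }, complex(1))
  new_bssfp_profile(seq$phase_inc, sig, seq)
}

new_bssfp_profile <- function(phase_inc, signal, seq) {
  out <- tibble(phase_increment = phase_inc, signal = signal)
  attr(out, "seq") <- seq
  class(out) <- c("bssfp_profile", class(out))
  out
}

profile_seq <- function(profile) {
  s <- attr(profile, "seq")
  if (is.null(s)) abort("profile is missing its `seq` attribute.")
  s
}
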