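#' Default RF phase-increment scheme
#'
#' The standard 12-point phase-cycling scheme uses RF phase increments
#' `phi_j = pi/12 * (2j - 1)`, `j = 1, ..., 12`, uniformly spaced over
#' (0, 2*pi). The generalization to `n` cycles keeps the half-step offset so
#' the increments stay strictly inside (0, 2*pi).
#'
#' @param n Number of phase cycles (default 12).
#' @return Numeric vector of `n` phase increments in radians.
#' @export
#' @examples
#' phase_increments(12)
phase_increments <- function(n = 12) {
  stopifnot(n >= 1)
  pi / n * (2 * seq_len(n) - 1)
}

#' pc-bSSFP sequence parameters
#'
#' Bundles the timing and excitation parameters of a phase-cycled balanced
#' SSFP protocol. Defaults follow the 3T protocol used throughout the package
#' (TR/TE = 4.8/2.4 ms, 15 degree nominal flip, 12 phase cycles, 256 dummy
#' pulses, B0 = 2.89 T).
#'
#' @param TR Repetition time in seconds.
#' @param TE Echo time in seconds; must satisfy `TE < TR`.
#' @param flip_nominal Nominal flip angle in degrees.
#' @param phase_inc RF phase increments in radians, strictly increasing in
#'   (0, 2*pi). Default [phase_increments()].
#' @param n_dummy Number of dummy pulses preceding the readout in transient
#'   (Monte Carlo) simulations. The analytic signal path uses the exact
#'   periodic steady state, for which `n_dummy` is irrelevant.
#' @param B0 Main field strength in tesla.
#' @return An object of class `seq_params`.
#' @export
#' @examples
#' seq_params()                       # 3T protocol
#' seq_params_preset("9.4T default")  # 9.4T protocol
seq_params <- function(TR = 4.8e-3, TE = 2.4e-3, flip_nominal = 15,
                       phase_inc = phase_increments(12), n_dummy = 256,
                       B0 = 2.89) {
  if (!(TE < TR) || TE <= 0) abort("`TE` must satisfy 0 < TE < TR.")
  if (any(diff(phase_inc) <= 0) || any(phase_inc <= 0) || any(phase_inc >= 2 * pi))
    abort("`phase_inc` must be strictly increasing within (0, 2*pi).")
  if (n_dummy < 1) abort("`n_dummy` must be >= 1.")
  structure(
    list(TR = TR, TE = TE, flip_nominal = flip_nominal,
         phase_inc = phase_inc, n_dummy = as.integer(n_dummy), B0 = B0),
    class = "seq_params"
  )
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "pc-bSSFP sequence: TR/TE = %.3g/%.3g ms, flip = %g deg, %d phase cycles, B0 = %.3g T\n",
    x$TR * 1e3, x$TE * 1e3, x$flip_nominal, length(x$phase_inc), x$B0))
  invisible(x)
}

#' Tissue compartment table
#'
#' Builds a tibble of tissue compartments, the input expected by
#' [simulate_profile()] and the Monte Carlo engine. Each row is one water
#' pool with its relaxation times, relative proton density, frequency offset
#' and diffusivity.
#'
#' @param compartment Character labels.
#' @param T1,T2 Relaxation times in seconds (`T2 <= T1`).
#' @param pd Relative proton density (>= 0).
#' @param freq_offset Resonance frequency offset in Hz.
#' @param D Diffusivity in m^2/s (>= 0).
#' @return A tibble with one row per compartment.
#' @export
#' @examples
#' tissue_table(T1 = 1, T2 = 0.06)
#' wm_compartments("3T")
tissue_table <- function(compartment = "tissue", T1, T2, pd = 1,
                         freq_offset = 0, D = 0) {
  tb <- tibble(compartment = compartment, T1 = T1, T2 = T2, pd = pd,
               freq_offset = freq_offset, D = D)
  validate_tissues(tb)
  tb
}

validate_tissues <- function(tissues) {
  req <- c("T1", "T2", "pd")
  if (!all(req %in% names(tissues)) || nrow(tissues) < 1)
    abort("tissue table needs columns T1, T2, pd and at least one row.")
  with(tissues, {
    if (any(T1 <= 0) || any(T2 <= 0)) abort("T1 and T2 must be positive.")
    if (any(T2 > T1)) abort("each compartment must satisfy T2 <= T1.")
    if (any(pd < 0)) abort("proton densities must be non-negative.")
  })
  invisible(tissues)
}

#' Three-compartment white-matter tissue values
#'
#' Literature relaxation values for the extra-axonal, intra-axonal and myelin
#' water pools used by the default simulation configurations: at 3T
#' T1/T2 = 1000/60, 1000/60, 300/12 ms, at 9.4T T1/T2 = 1500/30, 1500/30,
#' 400/10 ms; diffusivities 1e-9 m^2/s (extra/intra-axonal) and 1e-10 m^2/s
#' (myelin); myelin proton density one half.
#'
#' @param field `"3T"` or `"9.4T"`.
#' @return A tissue tibble (see [tissue_table()]).
#' @export
wm_compartments <- function(field = c("3T", "9.4T")) {
  field <- match.arg(field)
  if (field == "3T") {
    tissue_table(compartment = c("extra-axonal", "intra-axonal", "myelin"),
                 T1 = c(1.0, 1.0, 0.3), T2 = c(0.060, 0.060, 0.012),
                 pd = c(1, 1, 0.5), freq_offset = 0,
                 D = c(1e-9, 1e-9, 1e-10))
  } else {
    tissue_table(compartment = c("extra-axonal", "intra-axonal", "myelin"),
                 T1 = c(1.5, 1.5, 0.4), T2 = c(0.030, 0.030, 0.010),
                 pd = c(1, 1, 0.5), freq_offset = 0,
                 D = c(1e-9, 1e-9, 1e-10))
  }
}

#' Named simulation presets
#'
#' The eleven spin-walk configurations used for the in-silico anisotropy
#' analysis, keyed by name. Each preset carries the sequence parameters,
#' tissue table, susceptibility shift (ppm), substrate dropout fraction and
#' the B0 used for phase evolution (which may differ from the sequence's
#' nominal protocol, as in the `"9.4T B0-only"` hybrid).
#'
#' @param name Preset name; see `names(spinwalk_presets())`.
#' @return `seq_params_preset()` returns a `seq_params` object;
#'   `spinwalk_presets()` returns the full named list of presets;
#'   `spinwalk_preset()` returns one preset (list with elements `seq`,
#'   `tissues`, `delta_chi`, `dropout`, `B0_phase`).
#' @export
spinwalk_presets <- function() {
  seq3 <- seq_params()
  seq94 <- seq_params(TR = 4.0e-3, TE = 2.0e-3, flip_nominal = 9, B0 = 9.39)
  seq3_tr10 <- seq_params(TR = 10e-3, TE = 5e-3, flip_nominal = 15, B0 = 2.89)
  t3 <- wm_compartments("3T")
  t94 <- wm_compartments("9.4T")
  zeroD <- function(tt, which = TRUE) { tt$D[which] <- 0; tt }
  list(
    "3T default"      = list(seq = seq3,  tissues = t3,  delta_chi = -0.1, dropout = 0.25, B0_phase = 2.89),
    "9.4T default"    = list(seq = seq94, tissues = t94, delta_chi = -0.1, dropout = 0.25, B0_phase = 9.39),
    "3T Diff: 0"      = list(seq = seq3,  tissues = zeroD(t3),  delta_chi = -0.1, dropout = 0.25, B0_phase = 2.89),
    "9.4T Diff: 0"    = list(seq = seq94, tissues = zeroD(t94), delta_chi = -0.1, dropout = 0.25, B0_phase = 9.39),
    "3T AM100"        = list(seq = seq3,  tissues = t3,  delta_chi = -0.1, dropout = 0.00, B0_phase = 2.89),
    "3T AM50"         = list(seq = seq3,  tissues = t3,  delta_chi = -0.1, dropout = 0.50, B0_phase = 2.89),
    "3T dchi-2e-7"    = list(seq = seq3,  tissues = t3,  delta_chi = -0.2, dropout = 0.25, B0_phase = 2.89),
    "9.4T dchi-2e-7"  = list(seq = seq94, tissues = t94, delta_chi = -0.2, dropout = 0.25, B0_phase = 9.39),
    "3T TR10"         = list(seq = seq3_tr10, tissues = t3, delta_chi = -0.1, dropout = 0.25, B0_phase = 2.89),
    "3T Diffmyelin: 0" = list(seq = seq3, tissues = zeroD(t3, 3), delta_chi = -0.1, dropout = 0.25, B0_phase = 2.89),
    "9.4T B0-only"    = list(seq = seq3,  tissues = t3,  delta_chi = -0.1, dropout = 0.25, B0_phase = 9.39)
  )
}

#' @rdname spinwalk_presets
#' @export
spinwalk_preset <- function(name) {
  p <- spinwalk_presets()
  if (!name %in% names(p))
    abort(sprintf("unknown preset '%s'; see names(spinwalk_presets())", name))
  p[[name]]
}

#' @rdname spinwalk_presets
#' @export
seq_params_preset <- function(name) spinwalk_preset(name)$seq
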