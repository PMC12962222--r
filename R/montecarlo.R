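#' Monte Carlo walk configuration
#'
#' Scaled-down defaults for desk use: 2,000 spins on a 15-degree angle grid.
#' The full-scale conditions (1e5 spins, 19 angles at 5-degree steps) are
#' obtained by overriding `n_spins` and `thetas`.
#'
#' @param n_spins Number of random walkers (>= 100).
#' @param dt Time step in seconds; must divide both TE and TR.
#' @param thetas Fiber-to-field angles in degrees.
#' @param seed Optional integer seed.
#' @return A `walk_config` list.
#' @export
walk_config <- function(n_spins = 2000, dt = 1e-5,
                        thetas = seq(0, 90, by = 15), seed = NULL) {
  if (n_spins < 100) abort("`n_spins` must be at least 100.")
  structure(list(n_spins = as.integer(n_spins), dt = dt, thetas = thetas,
                 seed = seed), class = "walk_config")
}

#' Random-walk trajectories with phase accumulation
#'
#' Walks `n_spins` spins through the substrate under the pc-bSSFP timing of
#' `seq`: spins start uniformly over the periodic domain, take isotropic
#' Gaussian steps with per-axis standard deviation `sqrt(2 * D * dt)` for the
#' diffusivity of their (fixed, impermeable) compartment, and steps that would
#' cross a compartment boundary are rejected and resampled. Precession phase
#' `2*pi*gamma_bar*dB/B0*dt` is accumulated per TR - split at TE - against
#' every supplied field map simultaneously over a single trajectory pass, and
#' is stored per tesla so the same trajectories can be replayed at any B0.
#'
#' @param substrate An `axon_substrate`.
#' @param seq A [seq_params()] object; phases are recorded for
#'   `n_dummy + 1` TRs.
#' @param field_maps List of `field_map` objects (see [field_map_stack()]), or
#'   a single `field_map`.
#' @param config A [walk_config()].
#' @return A `spin_walk` object holding the per-spin, per-TR phase records
#'   (`phase_te`, `phase_rest`; arrays spins x TRs x angles, radians per
#'   tesla), spin compartments, start positions and unwrapped net
#'   displacements.
#' @export
walk_spins <- function(substrate, seq, field_maps, config = walk_config()) {
  if (inherits(field_maps, "field_map")) field_maps <- list(field_maps)
  thetas <- vapply(field_maps, function(f) f$theta, numeric(1))
  nx <- nrow(substrate$labels)
  stacked <- vapply(field_maps, function(f) {
    stopifnot(nrow(f$offset) == nx)
    f$offset
  }, matrix(0, nx, nx))
  D <- substrate$tissues$D
  n_tr <- seq$n_dummy + 1L
  res <- with_seed(config$seed,
    walk_spins_cpp(as.integer(substrate$labels), nx, nx, substrate$px,
                   as.numeric(stacked), length(field_maps), D,
                   config$dt, seq$TR, seq$TE, n_tr, config$n_spins,
                   GAMMA_BAR))
  structure(
    list(phase_te = res$phase_te, phase_rest = res$phase_rest,
         compartment = res$compartment, x0 = res$x0, y0 = res$y0,
         dx_net = res$dx_net, dy_net = res$dy_net,
         thetas = thetas, seq = seq, substrate_tissues = substrate$tissues,
         config = config),
    class = "spin_walk"
  )
}

#' @export
print.spin_walk <- function(x, ...) {
  cat(sprintf("spin walk: %d spins, %d TRs, %d angles (%s deg)\n",
              length(x$compartment), dim(x$phase_te)[2], length(x$thetas),
              paste(x$thetas, collapse = ", ")))
  invisible(x)
}

#' Replay the pc-bSSFP sequence over recorded trajectories
#'
#' Evolves each spin's magnetization through `n_dummy` dummy TRs plus one
#' readout TR for all RF phase increments of the sequence, reusing the same
#' trajectory for every phase cycle (trajectories are independent of RF
#' phase). Relaxation uses the compartment's T1/T2; precession uses the
#' recorded per-TR phase scaled by `B0`. The transverse magnetization is read
#' at TE and summed over spins with compartment proton-density weights.
#'
#' @param walk A `spin_walk` object.
#' @param seq Sequence to replay; defaults to the walk's sequence (timings
#'   must match the recorded TR/TE).
#' @param B0 Field strength in tesla used to scale the recorded phases.
#' @param tissues Compartment table (rows: extra-axonal, intra-axonal,
#'   myelin); defaults to the substrate's table.
#' @return A tibble of `bssfp_profile` rows: columns `theta`, `compartment`
#'   ("all" plus each compartment), `phase_increment`, `signal`.
#' @export
replay_bssfp <- function(walk, seq = walk$seq, B0 = seq$B0,
                         tissues = walk$substrate_tissues) {
  if (abs(seq$TR - walk$seq$TR) > 1e-12 || abs(seq$TE - walk$seq$TE) > 1e-12)
    abort("sequence TR/TE do not match the recorded trajectories.")
  validate_tissues(tissues)
  alpha <- seq$flip_nominal * pi / 180
  n_tr <- dim(walk$phase_te)[2]
  labs <- c("extra-axonal", "intra-axonal", "myelin")[seq_len(nrow(tissues))]
  out <- purrr::map_dfr(seq_along(walk$thetas), function(ti) {
    cm <- replay_bssfp_cpp(
      matrix(walk$phase_te[, , ti], ncol = n_tr),
      matrix(walk$phase_rest[, , ti], ncol = n_tr),
      walk$compartment, tissues$T1, tissues$T2, tissues$pd,
      seq$phase_inc, seq$TR, seq$TE, alpha, B0, seq$n_dummy)
    per <- purrr::map_dfr(seq_len(ncol(cm)), function(l)
      tibble(theta = walk$thetas[ti], compartment = labs[l],
             phase_increment = seq$phase_inc, signal = cm[, l]))
    all <- tibble(theta = walk$thetas[ti], compartment = "all",
                  phase_increment = seq$phase_inc,
                  signal = rowSums(cm))
    dplyr::bind_rows(all, per)
  })
  attr(out, "seq") <- seq
  out
}

#' Orientation sweep: Monte Carlo pc-bSSFP relaxometry versus angle
#'
#' Runs the full in-silico chain for one simulation configuration: field maps
#' for every requested angle, a single trajectory pass, sequence replay,
#' configuration-mode extraction and MIRACLE relaxometry, for the combined
#' signal and for each compartment separately.
#'
#' @param substrate An `axon_substrate`.
#' @param preset A preset name (see [spinwalk_presets()]) or a preset list.
#' @param config A [walk_config()].
#' @param walk Optionally a pre-computed `spin_walk` (its angles override
#'   `config$thetas`); used to replay several presets over identical
#'   trajectories (e.g., the field-strength-only comparison).
#' @return A tibble with columns `theta`, `compartment`, `R1`, `R2`, `M0`,
#'   `residual`, `converged`.
#' @export
#' @examples
#' \donttest{
#' sub <- pack_axons(n_axons = 40, domain = 18, dropout = 0.25, seed = 2)
#' sweep <- theta_sweep(sub, "3T default",
#'                      walk_config(n_spins = 300, thetas = c(0, 90), seed = 2))
#' }
theta_sweep <- function(substrate, preset = "3T default",
                        config = walk_config(), walk = NULL) {
  if (is.character(preset)) preset <- spinwalk_preset(preset)
  seq <- preset$seq
  substrate$tissues <- preset$tissues
  if (is.null(walk)) {
    fms <- field_map_stack(substrate, config$thetas, preset$B0_phase)
    if (!is.null(preset$delta_chi) &&
        abs(preset$delta_chi - substrate$delta_chi) > 0) {
      fms <- lapply(fms, function(f) {
        f$offset <- f$offset * (preset$delta_chi / substrate$delta_chi)
        f
      })
    }
    walk <- walk_spins(substrate, seq, fms, config)
  }
  profiles <- replay_bssfp(walk, seq, B0 = preset$B0_phase,
                           tissues = preset$tissues)
  relaxometry_from_profiles(profiles, seq)
}

#' @rdname theta_sweep
#' @param profiles Profile tibble from [replay_bssfp()].
#' @param seq Sequence used for the replay.
#' @export
relaxometry_from_profiles <- function(profiles, seq) {
  profiles |>
    dplyr::group_by(.data$theta, .data$compartment) |>
    dplyr::group_modify(function(df, key) {
      md <- configuration_modes(df)
      if (Mod(md$F_0) <= 0) return(tibble(R1 = NA_real_, R2 = NA_real_,
                                          M0 = NA_real_, residual = NA_real_,
                                          converged = FALSE))
      ft <- fit_miracle(md, seq)
      tibble(R1 = ft$R1, R2 = ft$R2, M0 = ft$M0,
             residual = ft$residual, converged = ft$converged)
    }) |>
    dplyr::ungroup()
}
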