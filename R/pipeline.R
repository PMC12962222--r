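#' Synthetic-cohort analysis pipeline
#'
#' Runs the cohort half of the analysis end-to-end: generate the cohort,
#' pool the white-matter voxels, bin the requested parameter, fit the
#' orientation-dependence model(s), and return every intermediate product
#' together with a reproducibility manifest (seeds and content hashes).
#'
#' @param spec A [cohort_spec()].
#' @param value Parameter to analyse (`"R2"`, `"R1"` or `"AI"`).
#' @param strategy Binning strategy (see [bin_parameter()]).
#' @param models Model ids to fit (see [model_eval()]).
#' @param angle `"theta"` or `"epsilon"` binning.
#' @return List with `cohort`, `curve`, `fits` (named list of
#'   `orientation_fit`), `coefficients` (per-subject truth) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_cohort_pipeline(cohort_spec(n_subjects = 3, dims = c(12, 12, 12),
#'                                        wm_voxels = 600))
#' glance(res$fits$susceptibility)
#' }
run_cohort_pipeline <- function(spec, value = "R2", strategy = 2,
                                models = c("susceptibility", "gen_mae"),
                                angle = "theta") {
  cohort <- generate_cohort(spec)
  wm <- dplyr::filter(cohort, .data$wm)
  curve <- bin_parameter(wm, !!rlang::sym(value), strategy = strategy,
                         angle = angle)
  target <- if (value == "AI") "AI" else value
  fits <- setNames(lapply(models, function(m)
    fit_model(curve, m, target = target)), models)
  manifest <- tibble(
    stage = c("cohort", "curve", rep("fit", length(fits))),
    name = c("cohort", "curve", names(fits)),
    hash = c(rlang::hash(cohort), rlang::hash(curve),
             vapply(fits, function(f) rlang::hash(f$params), character(1))),
    seed = spec$seed
  )
  list(cohort = cohort, curve = curve, fits = fits,
       coefficients = attr(cohort, "coefficients"), manifest = manifest)
}

#' Simulation pipeline: field-strength comparison on one substrate
#'
#' Runs the in-silico half end-to-end for two simulation presets sharing one
#' substrate and one trajectory pass where the presets permit it (identical
#' TR/TE and diffusivities, as in the field-strength-only comparison):
#' substrate packing, field maps, Monte Carlo walk, replay, MIRACLE, gen-MAE
#' fits of the R2(theta) curves (with the offset angle fixed at zero, as
#' appropriate for coherent simulated substrates) and the susceptibility
#' partition of the fitted anisotropic components.
#'
#' @param preset_low,preset_high Preset names (see [spinwalk_presets()]).
#' @param substrate An `axon_substrate`, or NULL to pack the default.
#' @param config A [walk_config()].
#' @param seed Seed for packing (when `substrate` is NULL) and the walk.
#' @return List with `sweeps` (tibble with column `preset`), `fits`,
#'   `partition` (one-row tibble incl. the fitted `p_a` ratio) and `manifest`.
#' @export
run_simulation_pipeline <- function(preset_low = "3T default",
                                    preset_high = "9.4T B0-only",
                                    substrate = NULL,
                                    config = walk_config(),
                                    seed = 1L) {
  p_lo <- spinwalk_preset(preset_low)
  p_hi <- spinwalk_preset(preset_high)
  if (is.null(substrate))
    substrate <- pack_axons(dropout = p_lo$dropout, seed = seed)
  config$seed <- config$seed %||% (seed + 1L)

  same_traj <- isTRUE(all.equal(p_lo$seq$TR, p_hi$seq$TR)) &&
    isTRUE(all.equal(p_lo$seq$TE, p_hi$seq$TE)) &&
    identical(p_lo$tissues$D, p_hi$tissues$D) &&
    isTRUE(all.equal(p_lo$delta_chi, p_hi$delta_chi))

  sub_lo <- substrate; sub_lo$tissues <- p_lo$tissues
  fms <- field_map_stack(sub_lo, config$thetas, p_lo$B0_phase)
  walk_lo <- walk_spins(sub_lo, p_lo$seq, fms, config)
  sweep_lo <- theta_sweep(sub_lo, p_lo, config, walk = walk_lo)
  sweep_hi <- theta_sweep(substrate, p_hi, config,
                          walk = if (same_traj) walk_lo else NULL)
  sweeps <- dplyr::bind_rows(
    dplyr::mutate(sweep_lo, preset = preset_low),
    dplyr::mutate(sweep_hi, preset = preset_high))

  fit_one <- function(sw) {
    cv <- sw |>
      dplyr::filter(.data$compartment == "all") |>
      dplyr::transmute(angle_mid = .data$theta, mean = .data$R2, n = 1L)
    fit_model(cv, "gen_mae", target = "R2", fix = list(eps0 = 0))
  }
  fits <- list(low = fit_one(sweep_lo), high = fit_one(sweep_hi))
  part <- susceptibility_partition(
    fits$low$params[["p_a"]], fits$high$params[["p_a"]],
    eta = field_ratio_eta(p_hi$B0_phase, p_lo$B0_phase))
  manifest <- tibble(
    stage = c("substrate", "sweep", "sweep", "partition"),
    name = c("substrate", preset_low, preset_high, "partition"),
    hash = c(rlang::hash(substrate$labels), rlang::hash(sweep_lo),
             rlang::hash(sweep_hi), rlang::hash(part)),
    seed = seed
  )
  list(sweeps = sweeps, fits = fits, partition = part, manifest = manifest)
}
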