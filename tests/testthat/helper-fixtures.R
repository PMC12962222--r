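# Lazily computed shared fixtures (packing and Monte Carlo runs are the
# expensive parts of the suite; each is built once and reused).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small packed substrate for geometry tests
tiny_substrate <- function() fixture("tiny_sub",
  pack_axons(n_axons = 60, domain = 20, dropout = 0.25, px = 0.1, seed = 42))

# full-domain substrate at coarser grid for Monte Carlo ordering tests
wm_substrate <- function() fixture("wm_sub",
  pack_axons(dropout = 0.25, px = 0.1, seed = 42))

# uniform single-compartment substrate (extra-axonal everywhere)
uniform_substrate <- function(n = 60, px = 0.1, tissues = wm_compartments("3T")) {
  substrate_from_labels(matrix(0L, n, n), px = px, tissues = tissues)
}

# scaled 3T-default orientation sweep (walk shared across ordering tests);
# returns list(walk, sweep, sweep_dchi2, seq)
mc_3t <- function() fixture("mc_3t", {
  sub <- wm_substrate()
  cfg <- walk_config(n_spins = 600, thetas = c(0, 45, 90), seed = 7)
  preset <- spinwalk_preset("3T default")
  sub$tissues <- preset$tissues
  fms <- field_map_stack(sub, cfg$thetas, preset$B0_phase)
  walk <- walk_spins(sub, preset$seq, fms, cfg)
  sweep <- theta_sweep(sub, preset, cfg, walk = walk)
  # doubled susceptibility: field maps are linear in delta_chi, trajectories
  # are independent of it, so the same walk replays with scaled phases
  walk2 <- walk
  walk2$phase_te <- walk$phase_te * 2
  walk2$phase_rest <- walk$phase_rest * 2
  sweep2 <- relaxometry_from_profiles(
    replay_bssfp(walk2, preset$seq, B0 = preset$B0_phase,
                 tissues = preset$tissues), preset$seq)
  list(walk = walk, sweep = sweep, sweep_dchi2 = sweep2, preset = preset)
})

# scaled 9.4T-default sweep on the same substrate
mc_94t <- function() fixture("mc_94t", {
  sub <- wm_substrate()
  cfg <- walk_config(n_spins = 600, thetas = c(0, 45, 90), seed = 7)
  theta_sweep(sub, "9.4T default", cfg)
})

rate_aniso <- function(sweep, comp = "all", rate = "R2") {
  v <- sweep[[rate]][sweep$compartment == comp]
  100 * (max(v) - min(v)) / (max(v) + min(v))
}
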