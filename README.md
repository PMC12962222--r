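# pcbssfp

Orientation-dependent relaxometry with phase-cycled balanced SSFP (pc-bSSFP)
in white matter — simulation, estimation and model fitting, end to end, with
no external data.

## The problem

Transverse relaxation in brain white matter depends on the angle θ between a
fiber bundle and the main field B0. Two mechanisms can produce this
anisotropy: residual dipolar couplings of water ordered at the myelin surface
(a magic-angle effect, independent of field strength) and mesoscopic field
perturbations from the magnetic susceptibility of myelin (whose dephasing
grows with B0). pc-bSSFP measures R1, R2 and the profile asymmetry index AI
in one scan, and comparing the fitted anisotropic R2 component across two
field strengths separates the two mechanisms: a purely dipolar component is
field-invariant, while a purely susceptibility-driven component scales with
η = (B0_high/B0_low)².

This package implements the full computational chain for that analysis:

- **Signal physics** — exact periodic steady state of phase-cycled bSSFP
  (per-TR affine recursion solved in closed form), multi-compartment voxel
  profiles, configuration modes F₋₁, F₀, F₁ by DFT across the RF phase
  increments φⱼ = π/12·(2j−1), and the asymmetry index
  AI = (h_p − h_n)/(h_p + h_n) from the B0-centred frequency response.
- **MIRACLE relaxometry** — joint (R1, R2, M0) estimation from the mode
  magnitudes with B1⁺ flip-angle correction, by bounded numerical inversion
  of the exact forward model.
- **Microstructure simulation** — packed hollow-cylinder axon substrates
  (gamma radii, uniform g-ratios, adjustable dropout), FFT dipole-kernel
  susceptibility field maps (kernel 1/3 − k_B²/|k|²), and a Monte Carlo
  spin-walk engine with impermeable compartments that replays the pc-bSSFP
  sequence (256 dummies + readout) over recorded trajectories for every
  phase cycle and fiber-to-field angle.
- **Orientation analysis** — θ = arccos|V1·ẑ|, FA/AD/RD from tensor
  eigenvalues, ε₀ = arctan(RD/AD), three (FA, angle) binning strategies, and
  anisotropy percentages 100·(max−min)/(max+min).
- **Model fitting** — five orientation-dependence models:
  susceptibility `y = a + b sin²θ + c sin⁴θ`; classical dipole
  `y = a + b|3cos²θ − 1|`; extended dipole `y = a + b(3cos²θ − 1)²`; and the
  generalized magic-angle-effect model `y = p_i + p_a f(α, θ − ε₀)` with
  `f(α,ε) = ¼(3cos²α−1)²(3cos²ε−1)² + 9/8(sin⁴α sin⁴ε + sin²2α sin²2ε)`,
  with and without voxelwise ε₀ correction; plus the susceptibility
  partition `100·ΔR2,a/(R2,a·(η−1))`.
- **Synthetic cohorts** — co-registered parameter maps, diffusion tensors
  and WM masks with programmable generating models, so every analysis step
  is testable against known truth.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods for
fitted objects and `autoplot()` for profiles, substrates, field maps, binned
curves and fits.

## Worked example

```r
library(pcbssfp)

# a three-compartment white-matter voxel at 3T
sq   <- seq_params()                      # TR/TE 4.8/2.4 ms, 15 deg, 2.89 T
prof <- simulate_profile(wm_compartments("3T"), sq)
fit_miracle(configuration_modes(prof), sq)
#> MIRACLE fit: R1 = 1.454 1/s, R2 = 26.59 1/s, M0 = 2.502 (residual 6.56e-16)

# the apparent T2 (1/26.59 s = 37.6 ms) sits below the PD-weighted
# compartment mean (50.4 ms): the short-T2 myelin pool biases the
# single-pool inversion towards faster relaxation.

# partition of the anisotropic R2 component between field strengths
susceptibility_partition(5.99, 28.30)
#> # A tibble: 1 x 5
#>     eta delta_R2a pct_low pct_high ratio
#>   <dbl>     <dbl>   <dbl>    <dbl> <dbl>
#> 1  10.6      22.3    39.0     87.1  4.72
```

The partition reads: with anisotropic amplitudes 5.99 s⁻¹ (3T) and
28.30 s⁻¹ (9.4T), susceptibility accounts for 39.0% of the anisotropic R2
at 3T and 87.1% at 9.4T; the amplitude ratio 4.7 lies between the pure
magic-angle limit (1) and the pure susceptibility limit (η = 10.56).

A full in-silico field-strength comparison on one substrate:

```r
res <- run_simulation_pipeline("3T default", "9.4T B0-only", seed = 1,
                               config = walk_config(n_spins = 6000,
                                                    thetas = seq(0, 90, 15)))
res$partition$ratio   # fitted p_a ratio between the two field strengths
#> [1] 10.54           # close to eta, as expected for a susceptibility model
```

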