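---
title: "Models and methods behind pcbssfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pcbssfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pcbssfp)
```

This vignette documents the models the package implements, the assumptions
they rest on, the numerical choices made where the design was genuinely open,
and what the synthetic test bed does and does not establish about real data.

## 1. Phase-cycled bSSFP signal model

A balanced SSFP sequence whose RF phase advances by a fixed increment φ per
TR drives the magnetization into a periodic steady state. One TR maps the
pre-pulse magnetization **M** through an affine transformation: an
instantaneous rotation by the flip angle α about the (phase-advanced) RF
axis, transverse relaxation `E2 = exp(-TR/T2)`, longitudinal recovery with
`E1 = exp(-TR/T1)`, and free precession. In the frame demodulated by the
current RF phase the map is time-invariant,

```
M' -> Rz(2*pi*f*TR - phi) * diag(E2, E2, E1) * Rx(alpha) * M' + (0, 0, M0*(1 - E1)),
```

and its fixed point is a 3×3 linear solve. `steady_state_signal()` solves
this exactly (`method = "closed"`) or iterates it to a relative change below
1e-12 (`method = "iterate"`); the two agree to 1e-9 and the on-resonance
magnitude matches the textbook closed form
`M0 sinα (1−E1)√E2 / (1 − (E1−E2)cosα − E1E2)` to 1e-10 across flip angles
1–80°. The receiver is demodulated by the phase of the exciting pulse, so a
phase increment φ is equivalent to an off-resonance shift −φ/(2πTR); the
frequency response is periodic in 1/TR.

Assumptions: instantaneous RF pulses (no slice profile), no magnetization
transfer or exchange between pools, proton-density-weighted linear
superposition of compartment signals within a voxel.

**RF phase-sign convention.** The DFT kernel `exp(-i n φ_j)` defines the
configuration modes, fixed so a pure `exp(+i φ_j)` profile lands on F₊₁.
Which physical pathway (FID-like or echo-like) maps to which signed mode
depends on the sign of the RF phase advance; the package advances the RF
phase by +φ per TR. All downstream estimation uses mode magnitudes, which
are invariant to this choice, to a global complex phase, and to a global
frequency offset.

**Asymmetry index.** The textbook definition — peak heights either side
of the stopband — does not prescribe how to centre a 12-sample profile. The
package (i) Fourier-interpolates the magnitude profile (trigonometric
interpolation, exact at the samples; default upsampling 64, i.e. 768 grid
points), (ii) shifts the global magnitude minimum to the edge of the
phase-cycle axis (stopband centring — robust and parameter-free), and
(iii) takes the global maximum of each half-axis, breaking ties towards the
smaller |frequency|. A profile whose dynamic range is below 1e-12 of its
maximum is flagged flat and assigned AI = 0 with a warning.

## 2. MIRACLE relaxometry

`fit_miracle()` inverts the single-pool forward model numerically: it seeks
(T1, T2, M0) whose mode magnitudes |F₋₁|, |F₀|, |F₁| (computed by the
package's own signal path) best match the measured ones in least squares.
M0 enters linearly and is profiled out; (log T1, log T2) are initialized on
a 20×20 log grid over T1 ∈ [0.2, 5] s, T2 ∈ [0.005, 1] s (grid ties broken
towards the smaller T2, and T2 ≤ T1 enforced on the grid) and refined by
bounded Levenberg–Marquardt. A closed-form inversion exists in the
literature; the numerical inversion of the exact forward model is used here
because it is self-consistent by construction and testable as a fixed point
— noiseless single-pool input reproduces R1 and R2 to better than 1e-4 with
residuals below 1e-8. B1⁺ enters as `flip_actual = b1_scale * flip_nominal`.

On multi-compartment input the single-pool assumption makes the apparent T2
an underestimate of the PD-weighted compartment mean (the short-T2 myelin
pool dominates the misfit); this bias is part of what the simulation module
quantifies, not an error to be corrected.

## 3. Axon substrates and susceptibility fields

`pack_axons()` builds two-dimensional hollow-cylinder substrates: radii from
a gamma distribution (mean 0.7 µm, variance 0.25 µm², truncated to
0.25–5 µm; shape 1.96, scale 0.357 µm), g-ratios uniform in 0.6–0.7, packed
into a periodic 43 × 43 µm² domain by random sequential insertion at reduced
radii followed by growth under overdamped pairwise repulsion.

**Density budget.** The truncation of the radius distribution lifts the mean
radius to ≈0.81 µm and E[r²] to ≈0.88 µm², so the mean outer-disk area per
axon is ≈6.6 µm². The heavy gamma tail makes the total area of a fixed axon
count fluctuate strongly between seeds (a single 5 µm axon adds ~190 µm²),
so the packer samples axons in surplus (default 220) and removes uniformly
random ones until the outer-disk area fits a fixed budget of 68% of the
domain — the density at which the realized myelin volume fractions match
densely packed white matter (≈39% at zero dropout, ≈30% at 25% dropout,
≈21% at 50%). Uniform removal leaves the per-axon radius distribution
unchanged. Whole-axon dropout (myelin and core revert to extra-axonal
space) generates the sparser packing variants.

Grid resolution defaults to 0.05 µm/pixel (860² over 43 µm); the myelin
fraction changes by under 0.3 percentage points when refined to 0.025 µm.

**Field maps.** The relative offset δB/B0 is computed by Fourier-domain
convolution of the susceptibility map (Δχ on myelin pixels, default
−0.1 ppm) with the dipole kernel `1/3 − k_B²/|k|²`, where k_B is the
in-plane wavevector component along the projection of B0 (the geometry is
invariant along the fiber axis, so the 3-D convolution reduces to 2-D; the
k = 0 term is zeroed, making the map zero-mean over the periodic domain).
This reproduces the analytic infinite-cylinder solution — interior
`Δχ(3cos²θ−1)/6`, exterior `(Δχ/2)sin²θ(a²/r²)cos2φ` — to better than 2%
away from the interface once the removed domain mean is accounted for. A
single scalar Δχ is applied; an anisotropic susceptibility tensor for the
myelin lipids is not modelled, with the expected consequence that simulated
anisotropy strength is a lower bound on what anisotropic susceptibility
would produce.

## 4. Monte Carlo spin walk

Spins start uniformly over the domain; each step is an isotropic Gaussian
displacement with per-axis SD √(2·D·dt) for the diffusivity of the spin's
compartment (defaults 1e-9 m²/s extra-/intra-axonal, 1e-10 m²/s myelin; dt
= 1e-5 s, which divides both TE and TR). Compartments are impermeable:
steps that would cross a boundary are rejected and resampled, and a
dt-halving control keeps R2(90°) within 2%, guarding against
boundary-handling bias. Positions wrap periodically. Phase
`2π·γ̄·δB/B0·dt` is accumulated per TR (split at TE) against all requested
field maps in a single trajectory pass, stored per tesla; the walk is
two-dimensional in the disk plane because the field is invariant along the
fiber axis, so axial displacements accrue no phase.

The sequence replay evolves each spin through `n_dummy` (default 256) dummy
TRs plus one readout TR for every phase increment, reusing the same
trajectory (trajectories are independent of RF phase), with compartment
relaxation applied per half-TR segment and the readout at TE. Per-spin
magnetization sums are PD-weighted (myelin ½) per compartment, so combined
and compartment-resolved profiles come from one pass.

**The 256-dummy transient.** From thermal equilibrium the bSSFP steady
state is approached on a time scale of order T1 (the slow eigenvalue of the
per-TR map is ≈0.994 at 3T, α = 15°), so 256 × 4.8 ms leaves a residual of
a few percent in the profile, and correspondingly in MIRACLE estimates.
This is a property of the simulated protocol, shared by every configuration
the package compares, and largely cancels in orderings and amplitude
ratios. Engine-equivalence controls therefore use longer dummy trains
(≥1024 TRs), where ensemble profiles match the analytic steady state to
better than 1e-3 and MIRACLE recovers the input T2 to better than 2%.

**Field-strength-only comparison.** δB/B0 is independent of B0, and the 3T
default and 9.4T B0-only configurations share TR/TE, flip, relaxation and
diffusivities; the package therefore replays the identical trajectories at
2.89 T and 9.39 T — the two ensembles differ in nothing but the field
strength, which is the cleanest version of this comparison. The fitted
anisotropic-amplitude ratio is computed with the generalized MAE model with
ε₀ fixed at 0 (simulated substrates have coherent fibers, so the principal
and actual fiber directions coincide).

**Problem sizes.** Package defaults are desk-scale: 2000 spins and a
15°-angle grid (the full-scale conditions, 1e5 spins and 19 angles, are a
configuration change). The field-strength comparison reported by the
acceptance script uses 6000 spins: at 2000 the Monte Carlo standard error
of the fitted amplitude ratio is about ±1 (the 3T anisotropic amplitude is
only ≈0.2 s⁻¹), and tripling the ensemble brings that error comfortably
inside the width of the plausible range around η. Tests use 300–600 spins
with 2–3 angles, which resolve every ordering they assert.

## 5. Orientation analysis and model fitting

θ = arccos(|V1·ẑ|) folds antipodal orientations into [0°, 90°];
FA, AD = λ₁ and RD = (λ₂+λ₃)/2 come from the tensor eigenvalues, and
ε₀ = arctan(RD/AD) estimates the offset between principal and apparent
fiber directions. Binning uses half-open `[lo, hi)` cells with the final
bin closed (ties on an interior edge go to the upper bin); ε = θ − ε₀ can
be negative in noisy voxels and is clamped to [0°, 90°] before ε-binning.
Anisotropy percentages exclude empty bins. Masking is the caller's
contract: voxels enter the bins exactly as supplied.

Model fits minimize unweighted least squares of bin means at bin-centre
angles (bin counts are not used as weights — with inter-subject means the
counts reflect anatomy, not precision). The three trigonometric-polynomial
models are linear and fitted exactly. The generalized MAE model uses the
biologically informed bounds p_i ∈ [0,100] s⁻¹, p_a ∈ [0,50] s⁻¹,
α ∈ [0°,90°], ε₀ ∈ [0°,45°] for rate targets (amplitudes unconstrained for
the already-normalized AI), a multi-start over 8 initializations of α with
ties resolved towards the smaller α, and R² = 1 − SSres/SStot.

Two identifiability facts matter when reading fitted parameters. First,
the extended dipole model is the α = 0, ε₀ = 0 slice of the generalized
MAE model (p_a·f(0,ε) = 4p_a·[(3cos²ε−1)/2]²). Second, as a function of
sin²ε the kernel f(α,·) spans quadratics, so with unconstrained amplitudes
(AI fits) the triple (p_i, p_a, α) has an exact two-branch conjugacy — two
parameter sets produce identical curves, and the smaller-α tie-break picks
one branch deterministically. Rate fits do not suffer this: the p_a ≥ 0
bound removes the conjugate branch.

The susceptibility partition uses
`100·ΔR2,a/(R2,a(low)·(η−1))` and `100·η·ΔR2,a/(R2,a(high)·(η−1))` with
η = (B0_high/B0_low)²; this grouping is the one consistent with all the
worked values the package reproduces, and the limits are transparent:
ΔR2,a = 0 gives 0% (pure magic angle), R2,a scaling by η gives 100%.

## 6. Synthetic cohorts: what they do and do not show

`generate_subject()` draws per-subject generating coefficients from normal
inter-subject distributions, assigns voxels to a mixture of coherent tracts
with Watson-type orientation dispersion (default three near-orthogonal
tracts, κ = 12 — chosen to populate all θ bins with realistic coherence),
sets FA ~ N(0.65, 0.12²) truncated to [0.05, 0.95] in white matter, builds
axially symmetric tensors whose radial diffusivity hits the target FA at
AD = 1.7e-3 mm²/s, evaluates the generating model at θ (at θ − ε₀ for the
generalized MAE, using the voxel's own ε₀), and adds Gaussian map noise
(defaults 0.05, 0.5 s⁻¹ and 0.01 for R1, R2, AI). The WM mask is the
`wm_voxels` grid points closest to the grid centre — an exact, deterministic
count. Matched-field cohorts share geometry per subject and differ only in
generating coefficients and noise streams.

Passing the recovery tests shows the chain bin → fit → partition is
unbiased at cohort scale under its own generating assumptions (single
dominant fiber per voxel, Gaussian map noise, axially symmetric tensors).
It does not validate those assumptions for real tissue: crossing fibers,
Rician image noise, registration error, B0 drift and anatomy-correlated
binning are all outside the generator, as are magnetization transfer and
exchange in the simulator. Recovery tolerances for cohort-level checks are
set at twice the inter-subject standard error of the programmed
coefficient (a 95% band, fixed before the tests were first run), plus a
small allowance for within-bin angle aggregation.

## 7. Reproducibility

Every stochastic entry point takes a seed and restores the caller's RNG
state; identical seeds give bit-identical substrates, trajectories and
cohorts. Pipeline drivers return a manifest of content hashes so reruns can
be compared at a glance. The acceptance script re-derives all reported
numbers from package calls at run time; nothing is read from stored
results.
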