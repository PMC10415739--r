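# dropletTMSD

Simulation and analysis of toehold-mediated DNA strand displacement
(TMSD) reactions compartmentalized in water-in-oil emulsion droplets,
with or without a random-sequence oligonucleotide background.

## The problem

TMSD is the workhorse reaction of dynamic DNA nanotechnology: an
invader strand binds a short single-stranded toehold on a
fluorophore-labelled reporter complex and displaces the
quencher-labelled incumbent, producing a fluorescence increase. In
complex reaction environments — synthetic cells, large DNA circuits —
many unrelated nucleic acids transiently bind the invader and slow the
reaction down. Encapsulating the reaction in thousands of picolitre
droplets makes it possible to measure the kinetics of each compartment
separately, and raises a statistical question: how much
droplet-to-droplet variability is produced by the encapsulation process
itself (stoichiometry noise), and how much by each droplet sampling a
different subset of an interfering random-sequence pool?

`dropletTMSD` provides the full in-silico counterpart of such an
experiment, for experimentalists planning droplet assays and for anyone
studying variability in compartmentalized reaction networks:

* **Pool thermodynamics** — for an invader `A` and pool strand `B`,
  the interaction free energy `ΔΔG = ΔG_AB − (ΔG_A + ΔG_B)` from a
  unified nearest-neighbor stack model (or a pluggable external
  engine); Boltzmann binding probabilities
  `p(n) = Q⁻¹ exp(−ΔΔG_n / k_B T)`; exact two-state bound fractions
  `θ(C_j)` from the mass-balance quadratic; and the sequestration
  statistic `μ = M⁻¹ Σ θ(C_j)` over the top decile of binders.
* **Compartments** — droplet volumes `V = (4π/3) r³`, copy numbers
  `N_x = N_A c_x V`, mixing ratios `ξ = V_A/(V_A+V_B)` from sinusoidal
  pressure programs, in-droplet concentrations `[A] = ξ[A]_stock`,
  `[B] = (1−ξ)[B]_stock`, and independent Poisson partitioning of pool
  molecules into droplets.
* **Kinetics** — the one-step bimolecular model
  `d[I]/dt = d[R]/dt = −k[I][R] = −d[F]/dt`, integrated numerically and
  solved in closed form; initial velocities `v₀ = k[A]₀[B]₀`;
  finite-window slopes; the stoichiometry parabola
  `v = kξ(1−ξ)[A]_stock[B]_stock`; analytic time-to-conversion.
* **Synthetic traces** — two-channel (reference + reporter) per-droplet
  fluorescence tables with common-mode and additive noise, plus the
  artifact classes a tracking pipeline has to discard (negative-slope,
  intensity-jump, out-of-focus traces).
* **Analysis** — QC filtering, reference-dye normalization, two-point
  and regression slope estimation, mean-normalization, CV/IQR/MAD
  variability statistics, central-peak Gaussian fits, rate-constant
  fitting, reference-intensity concentration mapping and the parabola
  overlay for stoichiometry maps.

## Worked example

Simulate a 1000-droplet experiment at the standard composition
(500 nM invader stock, 400 nM reporter stock, 5 µM N25 random pool,
radius 15 µm ± 3%), analyse it blind, and recover the kinetics:

```r
library(dropletTMSD)

inv  <- example_invader()                       # synthetic 25-mer
pool <- generate_random_pool(3000, 25, seed = 1)
eq   <- pool_equilibrium(inv, pool, invader_conc = 500e-9, pool_conc = 5e-6)

cfg <- emulsion_config(n_droplets = 1000, radius_mean = 15, radius_cv = 0.03,
                       pool_stock = 5e-6, pool_size = 3000, xi_sd = 0.01)
em  <- generate_emulsion(cfg, pool_interactions = eq$interactions,
                         seed = 1, calibration = 2.7 / 3.2)

traces <- simulate_trace_set(em, rate_parameters(3.2e4),
                             acquisition_config(n_frames = 60),
                             noise_model(1, 0.01), seed = 1)
traces <- inject_artifacts(traces, artifact_spec(0.05, 0.02, 0.02), seed = 1)

qc <- qc_filter(traces)
qc
#> <qc_report: 907 kept, 93 discarded>
#>             intensity_jump             negative_slope
#>                         23                         50
#> out_of_focus_or_low_signal
#>                         20

sl <- estimate_slopes(traces, slope_window(10, 50),
                      normalize = "ref", ids = qc$kept)
variability_stats(sl)
#> <variability_stats n=907: CV=0.04166 IQR=0.05818 MAD=0.03283>
```

The QC filter removed the 93 injected artifact droplets (50
negative-slope, ~2% each of jumps and out-of-focus) and essentially
nothing else. The droplet-to-droplet slope CV of ~4% combines the
programmed 2% stoichiometry noise (ξ jitter of 0.01 around 0.5 enters
the parabola to second order), the trace noise, and the rate-constant
variability induced by each droplet sampling a different pool subset.
Fitting the ensemble mean trace recovers the calibrated effective rate
constant:

```r
tt <- seq(0, 2700, 10)
fm <- rowMeans(vapply(em$rate_factor, function(rf)
  closed_form_conversion(rf * 3.2e4, 250e-9, 200e-9, tt),
  numeric(length(tt))))
fit_rate_constant(tt, to_fluorescence(fm, 200e-9, 0, 200), 250e-9, 200e-9)
#> <rate_fit: k_hat = 2.7e+04 M^-1 s^-1, residual norm 0.000159>
```

i.e. the pool ensemble (population-mean rate factor 2.7/3.2 ≈ 0.844)
fits at 2.7 × 10⁴ M⁻¹ s⁻¹, below the clean-system 3.2 × 10⁴ M⁻¹ s⁻¹.

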