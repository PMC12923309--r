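# lightheat

Layered-tissue photon Monte Carlo and photothermal dosimetry in R.

## The problem

Near-infrared photothermal therapy (PTT) and photoacoustic imaging (PAI)
both live or die by how much optical energy a contrast agent deposits in
a tumor. J-aggregation of indocyanine green (IcG) redshifts its
absorption peak from ~780 nm to ~890 nm, away from the hemoglobin band —
but quantifying the payoff requires modelling light transport through
skin, fat and tumor at the candidate wavelengths, and then converting
heating measurements into efficiency and dose metrics. `lightheat`
implements that chain for researchers designing or analysing such
experiments:

- **Photon transport**: a weighted photon-packet Monte Carlo (hop–drop–
  spin) through a 1-D layered stack, with Henyey–Greenstein scattering,
  Fresnel/Snell boundaries, unbiased Russian roulette, and absorbed
  energy / fluence tallied on an (r, z) grid. The C++ kernel runs 10⁶
  photons through a four-layer skin model in tens of seconds.
- **Beam convolution**: the point-source impulse response convolved with
  a finite Gaussian (or flat) beam by Gauss–Legendre quadrature.
- **Tissue + agent optics**: layered stacks built from a packaged
  (synthetic, literature-style) optical-property table, with
  contrast-agent absorption mixed into the tumor layer from a dose
  assumption (mg/kg dose × uptake fraction ÷ tumor volume →
  Beer–Lambert μₐ).
- **Photothermal conversion efficiency**: η from heating/cooling traces
  via the cooling-time-constant method —
  η = [hS·(T_max − T_surr) − Q_dis] / [I·(1 − 10^(−Abs))] with
  hS = m·C_p/τ_c and τ_c from the ln θ cooling line.
- **Thermal dosimetry**: CEM43 = Σ Δt·R^(43−T) (R = 0.25 below 43 °C,
  0.5 above), contrast-enhancement ratios, and a photoacoustic
  initial-pressure proxy p₀ = Γ·μₐ·Φ.
- **Synthetic data**: seeded generators for absorber spectra
  (monomer/J-aggregate band models), noisy heating traces with known
  ground truth, optical-property tables and PA-vs-depth series — every
  input the pipeline needs, reproducibly.

See the methods vignette
(`vignettes/light-transport-and-thermal-dosimetry.Rmd`) for the model,
its assumptions and the numerical choices.

## Worked example

How much more energy lands at the top of an agent-loaded tumor under
2 mm of fat at the redshifted wavelengths?

```r
library(lightheat)

agent <- list(spectrum = gen_absorbance_spectra("j_aggregate"),
              loading  = agent_loading())   # 5 mg/kg, 1% uptake, 50 mm^3
dose_to_concentration(agent$loading)
#> [1] 2.580645e-05        # ~25.8 uM chromophore in the tumor

peaks <- sapply(c(808, 852, 890), function(wl) {
  st <- build_tumor_stack(2, wavelengths = wl, agent = agent)
  ir <- run_simulation(st, wl, config = mc_config(n_photons = 1e5, seed = wl))
  tumor_interface_peak(st, convolve_beam(ir, beam_profile(1, 4)))
})
round(peaks / peaks[1], 2)
#> [1] 1.00 2.95 5.74
```

The folds say: with the J-aggregate loaded at the dose-derived
concentration, the tumor's upper face absorbs ~3× more energy per joule
of incident beam at 852 nm and ~5.7× more at 890 nm than at 808 nm.
(The fold is smaller than the raw μₐ ratio because a strongly absorbing
tumor depresses its own local fluence — see the vignette.) A PCE
round-trip looks like:

```r
p  <- lumped_thermal_params(tau_c_s = 180, q_dis_mW = 10, I_mW = 2000)
tr <- gen_temperature_trace(p, eta = 0.15, seed = 42)$trace
estimate_pce(tr, I_mW = 2000, abs_lambda = 1, q_dis_mW = 10)
#> photothermal conversion efficiency: 14.9%
#>   tau_c = 182.2 s (R^2 = 0.9949, 523 cooling points), hS = 22.94 mW/degC
```

A thin command-line wrapper over the same functions lives at
`inst/cli/lightheat.R` (`depth-scan`, `pce-fit`, `cem43`, `synth-trace`).

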