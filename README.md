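# drsmethb

Noninvasive estimation of **methemoglobin fraction** and **arterial oxygen
saturation (SaO2)** from skin diffuse reflectance spectra, built as a fully
simulated study: a four-layer skin optical model drives a fiber-probe Monte
Carlo reflectance simulator, spectra are condensed into 12 spectral
descriptors, and a small feed-forward neural network inverts them into the
two blood parameters.

Methemoglobin (MetHb) is the oxidized, non-oxygen-carrying form of
hemoglobin. Its visible absorption bands (notably around 500 and 630 nm)
overlap those of oxy- and deoxyhemoglobin, which makes broadband diffuse
reflectance spectroscopy (DRS) a candidate for continuous, noninvasive
MetHb monitoring — and makes the inversion a genuine regression problem.
The package is aimed at tissue-optics researchers who want a reproducible,
end-to-end sandbox for this estimation chain.

## What is inside

* **Optics** — per-layer absorption as volume-fraction-weighted chromophore
  mixtures (oxy/deoxy/met-hemoglobin, water, melanin, bilirubin,
  beta-carotene, fat; μa = 2.303 (c/64500) ε(λ) for the hemoglobins) and
  Rayleigh+Mie reduced scattering μs′ = a′[f·(λ/500)⁻⁴ + (1−f)(λ/500)^(−b)],
  g = 0.86. Bundled chromophore tables are labelled synthetic
  approximations of the published compilations (see the vignette).
* **Monte Carlo** — layered MCML transport (hop–drop–spin, Fresnel/Snell
  boundaries, roulette at 10⁻⁴/0.1) with one 100 µm source fiber and six
  100 µm collection fibers on a 240 µm hexagonal ring; MRG32k3a RNG with
  per-wavelength substreams; a pure-R naive reference loop reproduces the
  compiled engine bitwise on a shared stream. A "white Monte Carlo"
  shared-trajectory mode evaluates all 66 blood conditions from one
  trajectory set per wavelength, exactly and ~66× faster.
* **Features** — Savitzky–Golay smoothing; most-prominent-peak analysis
  (amplitude, location, widths at half height/prominence, prominence);
  signal power; Teager–Kaiser energy operator ψ[x](n) = x(n)² − x(n−1)x(n+1)
  with six statistics; greedy correlation-based feature selection (CFS).
* **Estimator** — `drs_ann()`, a classed single-hidden-layer network
  (10 hidden units, linear outputs, seeded and deterministic) with
  `predict`, `print`, `summary`, `coef`, `residuals` and `plot` methods,
  evaluated by MAE, MAPE, MSE, RMSE and R² per output.
* **Pipeline** — the 11 MetHb levels × 6 SaO2 levels experiment grid,
  dataset generation with manifest, the four feature-set network variants
  (all 12 / 5 peak / 7 power+KTE / 6 CFS features), and prediction on
  external two-column spectra. A thin CLI lives in `inst/cli/`.

## Worked example

```r
library(drsmethb)
# simulate a mildly methemoglobinemic state over the visible band
blood <- blood_state(sao2 = 0.85, methb_fraction = 0.20)
config <- sim_config(n_photons = 2e4, seed = 7, wavelengths = seq(400, 700, 5))
spec <- simulate_spectrum(default_skin_model(), blood, config = config,
                          engine = "shared")
print(spec)
#> <spectrum_result> 61 wavelengths (400-700 nm), 20000 photons/wavelength, seed 7, engine 'shared'
#>   total reflectance: 0.03116-0.04501

fv <- assemble_features(drs_spectrum(spec$wavelengths, spec$total_reflectance))
round(fv[1:6], 5)
#>        peak_amplitude         peak_location     width_half_height
#>               0.04433             510.00000             300.00000
#>            prominence width_half_prominence          signal_power
#>               0.00522             179.27540               0.00169
```

The spectrum collects 3–4.5 % of launched light in the six fibers, with the
broad visible maximum near 510 nm flanked by the hemoglobin valleys; the
descriptor condenses that shape (amplitude/location/width of the dominant
peak, mean power, energy statistics) into the 12 numbers the network
consumes. The full study then runs, e.g.:

```r
ds    <- generate_dataset(experiment_grid(),
                          config = sim_config(n_photons = 2e4, seed = 1,
                                              wavelengths = seq(400, 1000, 5)))
feats <- featurize_manifest(ds)
rep   <- run_experiment(feats, "all", split_seed = 1, init_seed = 101)
rep$metrics   # test-set MAE/MAPE/MSE/RMSE/R2 for methb_fraction and sao2
```

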