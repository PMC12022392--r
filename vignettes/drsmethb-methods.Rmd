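---
title: "Simulating and inverting skin diffuse reflectance for methemoglobin and oxygen saturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and inverting skin diffuse reflectance for methemoglobin and oxygen saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Methemoglobin (MetHb) is the Fe(III) form of hemoglobin: it cannot bind
oxygen, and elevated fractions (above a few percent of total hemoglobin)
impair oxygen transport. Because MetHb, oxyhemoglobin and deoxyhemoglobin
have overlapping but distinct visible absorption bands, broadband diffuse
reflectance spectroscopy (DRS) of skin carries information about both the
MetHb fraction and the arterial oxygen saturation (SaO2). `drsmethb`
implements the full forward-and-inverse chain: a four-layer skin optical
model, a fiber-probe Monte Carlo reflectance simulator, a 12-feature
spectral descriptor, and a small feed-forward network that regresses
(MetHb fraction, SaO2) from a spectrum.

## The tissue optical model

The skin stack is stratum corneum (20 µm), epidermis (80 µm), dermis
(2000 µm) and subcutaneous fat (6000 µm), with air above and the bottom
medium treated as a transmission sink. Each layer's absorption coefficient
is a volume-fraction-weighted mixture of chromophores:

* stratum corneum: water plus a power-law baseline
  $\mu_{a,\mathrm{base}}(\lambda) = 7.84\times10^{8}\,\lambda^{-3.255}$ cm⁻¹;
* epidermis: water, melanin
  ($\mu_{a,\mathrm{mel}} = 6.6\times10^{11}\,\lambda^{-3.33}$ cm⁻¹) and baseline;
* dermis: blood, water, bilirubin ($2.3\,C_{bi}\,\varepsilon_{bi}$ with
  $C_{bi} = 1.71\times10^{-6}$ mol/L), beta-carotene and baseline;
* subcutaneous fat: blood, water, fat and baseline.

Blood is the sum of an arterial and a venous term,

$$\mu_{a,\mathrm{blood}} = \big[S\mu_{a,\mathrm{oxy}} + (1-S)\mu_{a,\mathrm{deoxy}} + \mu_{a,\mathrm{met}}\big]_{S=S_aO_2} + \big[\cdot\big]_{S=S_vO_2},$$

with $S_vO_2 = \max(S_aO_2 - 0.10,\,0)$ unless supplied. Each hemoglobin
derivative converts molar extinction to absorption via
$\mu_a = 2.303\,(c/64500)\,\varepsilon(\lambda)$, where the MetHb fraction
$f$ splits the 150 g/L total hemoglobin into $c_{met} = 150 f$ and
$c_{oxy,deoxy} = 150(1-f)$. The printed blood model adds the arterial and
venous coefficients at full concentration in both terms; we implement that
sum literally as the default and expose an optional `arterial_fraction`
$f_A$ that combines the terms as $f_A A + (1-f_A) V$ instead, because the
plain sum effectively counts the blood compartment twice and a user may
prefer the convex combination. All results in this package use the
literal sum.

Reduced scattering uses the 500 nm-normalized Rayleigh + Mie law
$\mu_s'(\lambda) = a'[f_{Ray}(\lambda/500)^{-4} +
(1-f_{Ray})(\lambda/500)^{-b_{Mie}}]$ with the tabulated
$(a', f_{Ray}, b_{Mie})$ per layer and $\mu_s = \mu_s'/(1-g)$ at a fixed
anisotropy $g = 0.86$. The stratum corneum, whose scattering parameters
are not separately tabulated, reuses the epidermal values; at 20 µm
thickness its influence is negligible. Refractive indices are 1.55
(stratum corneum), 1.40 (epidermis, dermis; constant by default with a
per-wavelength function hook) and 1.44 (fat). The bottom ambient index
defaults to 1.44, matching the fat layer, so photons reaching the bottom
are scored as transmitted without an arbitrary index step — the bottom
medium's optical properties are not part of the model.

### Chromophore tables

The bundled two-column TSV tables (oxy-, deoxy-, methemoglobin and
bilirubin as molar extinction; water, beta-carotene and fat as absorption
coefficients) are *synthetic approximations*: smooth reconstructions
anchored at the well-known band positions and magnitudes of the published
compilations (Soret bands at 414/430/406 nm, Q bands at 540/576 and
555 nm, the MetHb 500 and 630 nm bands, the water 970 nm and lipid
930 nm bands). They are suitable for method development and testing;
quantitative work against measured spectra should substitute exact
digitizations via `chromophore_tables(dir = ...)`. Queries interpolate
linearly and refuse wavelengths outside 400--1000 nm.

## The Monte Carlo engine

Transport is classic layered MCML: packets launch uniformly over the
100 µm source fiber at normal incidence, lose the specular Fresnel
fraction, then hop (exponential free paths, $s = -\ln\xi/\mu_t$), drop
(deposit $w\,\mu_a/\mu_t$), and spin (Henyey--Greenstein deflection,
uniform azimuth). Interfaces apply unpolarized Fresnel reflection/Snell
refraction with total internal reflection; the step remainder is rescaled
by the ratio of interaction coefficients when a packet crosses into a new
layer. Low-weight packets (below $10^{-4}$) play roulette with survival
chance 0.1 and a $\times 10$ weight boost — the conventional, unbiased
MCML values. Detection assigns a top-surface exit to whichever of the six
100 µm collection fibers (hexagonal ring at 240 µm center-to-center)
contains the exit point; the fibers accept the full hemisphere by default,
with an optional maximum-acceptance-angle knob since a numerical aperture
is not part of the model. The total diffuse reflectance of a spectrum is
the sum over the six fibers. The printed 0.005 cm voxel is kept only as
metadata for optional deposition maps; transport itself is layered and
analytic in the lateral coordinates, which is exact for laterally
homogeneous stacks.

The RNG is MRG32k3a in its double-precision formulation, with one
substream per wavelength derived from `(seed, stream index)` through a
MINSTD scrambler. Every arithmetic step of the generator is exact in IEEE
doubles, so the pure-R reference loop (`mc_reference_wavelength()`) — a
deliberately naive transcription of the transport loop — consumes an
identical stream and reproduces the compiled engine's detected weights to
floating-point precision. That oracle equivalence, energy conservation
(specular + diffuse + transmitted + absorbed = 1 within $10^{-3}$ at
$10^{5}$ packets), hexagonal detector symmetry and the Henyey--Greenstein
first moment are all asserted in the test suite.

### Shared-trajectory evaluation of the condition grid

The study design fixes every optical property except the dermis and
subcutaneous-fat absorption, which vary over the 11 MetHb × 6 SaO2 grid.
`generate_dataset()` exploits this: with the default `"shared"` engine it
samples scattering-only trajectories once per wavelength (free paths from
$\mu_s$ alone) and weights each trajectory analytically by
$\exp(-\sum_\ell \mu_{a,\ell} L_\ell)$ for every condition, where
$L_\ell$ is the path length in layer $\ell$. This is standard
"white Monte Carlo" importance sampling — unbiased for exactly the same
transport problem — and makes the 66-condition grid cost one simulation
per wavelength instead of 66. The per-photon energy ledger then balances
identically to machine precision, and the engine cross-check in the test
suite verifies statistical agreement with the direct hop-drop-spin engine
at matched budgets.

The price is a different *noise structure*: all 66 conditions share one
trajectory set per wavelength, so between-condition differences are exact
while only the common per-wavelength Monte Carlo error remains. Features
computed from these spectra are therefore much cleaner than features from
66 independent simulations at the same photon budget. Consequences for
the estimator comparison are discussed below. The `"direct"` engine
remains available for independent per-condition noise at a ~66× cost.

## Spectral features

Spectra are Savitzky--Golay smoothed (window 11 samples, order 3 —
unstated in the study design; these are common defaults and both are
exposed). The 12 descriptors are, in fixed order: the five peak-analysis
features (amplitude, location, full width at half height, topographic
prominence, full width at half prominence) of the *most prominent* peak —
prominence being the natural criterion when a single peak must be chosen —
then the mean signal power, then six statistics (skewness, variance,
kurtosis, mean, RMS, SD) of the Teager--Kaiser energy profile
$\psi[x](n) = x(n)^2 - x(n-1)x(n+1)$ evaluated at interior samples only
(length $N-2$, no padding, keeping the operator exact). Statistic
conventions: variance and SD with the $n-1$ denominator; skewness and
kurtosis as standardized third/fourth population central moments, kurtosis
*not* excess (a Gaussian gives 3); both defined as 0 for a constant
profile. A spectrum without an interior local maximum (after smoothing)
yields all-zero peak features with a warning rather than an error, so
degenerate inputs flow through the pipeline flagged but alive. Peak
detection uses a $10^{-10}$ relative tolerance so numerically flat spectra
are treated as degenerate rather than as fields of rounding-noise peaks.

Correlation-based feature selection (CFS) is greedy forward selection
under the merit $m\,\bar r_{cf} / \sqrt{m + m(m-1)\bar r_{ff}}$, with
feature--target correlations averaged over both outputs, absolute Pearson
correlations throughout, correlation defined as 0 for constant columns,
and index-order tie-breaking. Selection runs on the training split only,
to keep the held-out evaluation honest.

## The estimator

`drs_ann()` is the package's one fitting function: a single-hidden-layer
feed-forward network (10 hidden units by default; input width 12, 5, 7 or
6 per feature set) with linear outputs, fitted by regularized BFGS via
the recommended `nnet` package. `nnet`'s hidden activation is the logistic
sigmoid rather than tanh; the two parameterize the same function class up
to an affine map of the weights, and the choice does not affect any
contract. Inputs are z-scored with training-set statistics; targets stay
on the fraction scale in [0, 1], so a reported MAE of, say, 0.04 reads
directly as 4 percentage points. Weight initialization is seeded, making
the train → predict → evaluate chain fully deterministic; predictions are
clipped to [0, 1] with a flag. Training uses light weight decay
($10^{-3}$) as regularization on the 53-sample training sets instead of
early stopping — with 66 samples a validation slice would be noisier than
the decay penalty it replaces.

The five criteria are MAE, MAPE, MSE, RMSE and $R^2 = 1 -
SS_{res}/SS_{tot}$, computed per output. MAPE is undefined at zero
targets; the 0% MetHb rows are excluded from the MAPE sum and the count
of exclusions is reported alongside. $R^2$ is reported missing when the
actual values have zero variance. `regression_fit()` provides the
predicted-versus-actual least-squares line and correlation that the
conventional regression plot shows, and `plot.drs_ann()` draws it.

## Problem sizes and reproduction

The shipped study runs the 66-condition grid at 400--1000 nm in 5 nm
steps with $2\times10^{4}$ packets per wavelength (about five minutes of
compute), then medians the test-set criteria over five (split,
initialization) seed pairs; `scripts/acceptance.R` reproduces exactly
this. The full-fidelity configuration ($10^{6}$ packets at 2 nm steps) is
available behind the CLI `--full` flag but takes orders of magnitude
longer; accuracy at the reduced budget is already limited by the 66-sample
design, not by photon noise. Unit tests use far smaller budgets (hundreds
to $10^{5}$ packets, narrow wavelength bands) chosen so the full suite
runs in minutes.

Under these conditions the all-features network reproduces the headline
accuracy comfortably (test-set MAE on the fraction scale of a few
thousandths for MetHb, $R^2 > 0.98$ for both outputs). One published
qualitative finding does *not* reproduce under the shared-trajectory
generator: the ranking of feature subsets (all > peaks-only >
power+KTE). With shared trajectories, the Teager--Kaiser statistics are
nearly noise-free and remain highly informative, so every subset reaches
$R^2 > 0.95$ and subset differences fall within seed-to-seed variability.
The original ranking plausibly reflects independent per-condition photon
noise corrupting the noise-sensitive energy-operator features — an effect
the variance-reduced generator removes by construction. The corresponding
ordering check in the acceptance tests is kept faithful to the published
ranking and documents this divergence rather than being weakened.

## What the synthetic study does and does not show

The generator emulates smooth, hemoglobin-structured reflectance spectra
with valleys in the 400--600 nm band and realistic condition-to-condition
trends (MetHb raising absorption around its 630 nm band, saturation
shifting the Q-band region). It does not emulate instrument effects
(source spectrum, detector noise, calibration), inter-subject variation in
layer thicknesses, melanin content or scattering, probe-pressure effects,
or the venous/arterial compartment structure beyond the fixed SvO2 offset.
Passing tests therefore demonstrate the internal consistency and accuracy
of the method on the modeled tissue, not clinical performance; prediction
on measured spectra (`predict_external()`) assumes inputs already
expressed as reflectance on a covering wavelength band and should be
interpreted accordingly.

## Known limitations

* The bundled chromophore tables are approximate reconstructions (see
  above); absolute reflectance levels shift with better tables, though the
  pipeline is insensitive to monotone recalibrations of this kind.
* The blood term follows the printed double-counting sum; physically one
  may prefer `arterial_fraction = 0.5`.
* Epidermis/dermis refractive-index dispersion is reduced to a constant
  1.40 default (a function of wavelength may be supplied per layer).
* No polarization, fluorescence, or time-resolved transport; detectors
  are ideal discs.
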