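# kmexchange

Water exchange between cellular compartments leaves a fingerprint in
diffusion MRI: under the multi-compartment Kärger model (KM) the total
diffusivity stays constant with diffusion time while the diffusional
kurtosis decays, and the *shape* of that decay encodes the exchange
rates. `kmexchange` is for researchers analyzing diffusional kurtosis
imaging (DKI) time-series data — mean diffusivity MD(t) and mean
kurtosis MK(t) extracted per region of interest — who want a
model-robust summary of tissue water exchange rather than a fit of one
specific compartment model.

## What it computes

For a KM with water fractions `f_m`, diffusivities `D_m`, and exchange
rates `R_mn` (detailed balance assumed), the symmetrized generator
`G = S⁻¹RS`, `S = diag(√f_m)`, has eigenvalues `λ_n ≤ 0` and
eigenvectors `ν_n`, giving exchange times `τ_n = −1/λ_n` and partial
kurtoses `κ_n = (3/D̄²)(ηᵀ diag(D) ν_n)²` with `η = √f`, `D̄ = Σ f_m D_m`.
The package computes:

* the **mean KM exchange rate** `R_KM = Σ_{n≥2} (κ_n/K0)/τ_n`, a
  kurtosis-weighted average of inverse exchange times, defined for any
  number of compartments;
* the exact kurtosis time course
  `K(t) = Σ_{n≥2} κ_n Υ(t/τ_n)`, `Υ(x) = (2/x)(1 − (1−e⁻ˣ)/x)`;
* the **plain lower bound** `R_KM* = −3 d ln K/dt |_{t*}`, estimated in
  practice from the semi-log slope of MK versus diffusion time;
* the **enhanced lower bound** `R̂_KM = Ef·R_KM*` with
  `Ef = V(R_KM* t*)`, `V(x) = β⁻¹(x)/x`,
  `β(y) = 3[y − 2 + (y+2)e⁻ʸ]/[y − 1 + e⁻ʸ]` — a strictly stronger
  bound, exact for two-compartment models;
* the **diffusion elasticity** `ξ` (log-log slope of MD vs t), a screen
  for KM validity (`ξ = 0` under any KM);
* the closed-form **thin cylindrical neurite model** (extra-neurite
  space exchanging with oriented sticks) and accuracy surfaces for both
  bounds over its parameter space;
* an end-to-end **ROI pipeline** from delimited MD/MK tables to a bound
  report, and seeded **synthetic-data generators** for testing.

## Worked example

Simulate a two-compartment model with known mean exchange rate
50 s⁻¹, generate a noisy 3-animal ROI table on the 18/22/26/30 ms
design, and run the analysis:

```r
library(kmexchange)

m <- karger_model(fractions = c(0.5, 0.5), diffusivities = c(0.8, 1.6),
                  exchange_rates = matrix(c(0, 0.025, 0.025, 0), 2, 2))
modes <- spectral_modes(build_generator(m), m$fractions, m$diffusivities)
1000 * mean_exchange_rate(modes)
#> [1] 50

sim <- simulate_roi_series(m, noise_sd_mk = 0.02, noise_sd_md = 0.01,
                           n_animals = 3, region = "DH", group = "NC",
                           seed = 7)
analyze_group(sim)
#> Exchange-rate bound report (rates in 1/s)
#>   region group n_points      xi  xi_se rkm_star rkm_star_se t_star_ms    x   Ef
#> 1     DH    NC       12 0.00565 0.0173       52        18.9        24 1.25 1.32
#>   rkm_hat rkm_hat_se valid
#> 1    68.6       34.3  TRUE
```

The report says: the elasticity `xi` is consistent with zero (KM-valid
data); the semi-log MK slope gives a plain bound `rkm_star` of 52 s⁻¹
with a large SE at this noise level; at `x = R_KM*·t* = 1.25` the
enhancement factor is 1.32, giving an enhanced bound `rkm_hat` of
68.6 ± 34.3 s⁻¹ — a lower bound on the mean exchange rate, here pulled
above the truth by noise but within one standard error of it.

The enhancement chain on its own:

```r
enhanced_bound(38.3 / 1000, 24)   # rate in 1/ms, t* in ms
#> Exchange-rate lower bound
#>   R_KM* = 0.0383  t* = 24  x = 0.9192
#>   Ef = 1.205  R_KM^ = 0.04615
```

i.e. a measured plain bound of 38.3 s⁻¹ at `t* = 24 ms` is enhanced by
20% to 46.1 s⁻¹.

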