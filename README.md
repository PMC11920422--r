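# bioalbedo

Quantitative analysis of the *bioalbedo* effect: snow and glacier algae
darken the ice surfaces they bloom on, the darker surface absorbs more
shortwave radiation, and the extra absorbed energy becomes extra melt. The
package is aimed at cryosphere field scientists working with field
spectrometer scans, PAR/temperature weather-station records and
multispectral imagery of glacial surfaces, and implements the full chain
from raw scans to the algal share of surface melt.

## What it computes

**Reflectance.** Field spectra are processed into hemispherical directional
reflectance factors from bracketed reference-panel scans,
ρ_λ = L_target,λ / mean(L_panel,λ) · β_λ.

**Instantaneous radiative forcing.** The extra power absorbed by an algal
patch relative to clean snow or ice,

    IRF = ∫₄₀₀⁷⁰⁰ E_e(λ) (ρ_clean(λ) − ρ_algae(λ)) dλ   [W m⁻²],

with E_e derived from PAR (4.57 µmol J⁻¹, uniform over 400–700 nm).

**Density calibration.** IRF = a·ln(density) + b, fitted by OLS at a
reference PAR, applied with linear PAR scaling and a zero clamp.

**Bloom mapping.** Pixels are classified as algae-containing when the
continuum-scaled chlorophyll band depth I_B5 = (C − R_B5)/C is strictly
positive, where C is the linear continuum between the flanking band
centres; extent is algal pixels × pixel area.

**Melt.** A 5-minute energy-balance model (shortwave + humidity-adjusted
bulk sensible heat over a melting surface) run with and without the algal
forcing; the difference is the algal melt, with uncertainty propagated from
the calibration's residual SD.

A seeded synthetic-data module (`make_surface_spectrum`,
`apply_algal_signal`, `make_density_irf_dataset`, `make_weather_series`,
`make_scene`) generates parametric inputs with known ground truth for all
of the above.

## Worked example

```r
library(bioalbedo)

# forcing at the mean observed density, at reference PAR
reg <- irf_regression(5.52, -24.03, residual_sd = 10.8, reference_par = 351)
predict_irf(2.5e5, reg)
#> [1] 44.58

# one sunny modelled day on weathering crust
w <- make_weather_series(mean_par = 399, mean_temp = 2.42, seed = 1)
res <- run_melt_model(w, surface_params(0.55, 550, "weathering_crust"),
                      reg, density = 2.5e5)
res$daily
#>         date total_melt_mm clean_melt_mm algal_melt_mm percent_contribution lowering_mm
#> 1 2023-02-06         28.14         15.03         13.11                46.58       51.17

# bloom extent on a noisy synthetic scene with known truth
sim <- make_scene(shape = c(50, 50), bloom_fraction = 0.2, noise_sd = 0.005,
                  seed = 1)
classify_scene(sim$scene)
#> <bloom_map: 500 / 2500 valid pixels algal (20.0%), extent 0.00128 km2>
```

Reading the numbers: at 2.5 × 10⁵ cells ml⁻¹ the calibration predicts
44.58 W m⁻² of algal forcing at the reference irradiance. Over the modelled
day that forcing adds 13.11 mm w.e. to the 15.03 mm the clean crust would
have melted — a 46.6% contribution (total 28.14 mm w.e., equivalent to
51.2 mm of surface lowering at 550 kg m⁻³). The classifier recovers the
constructed 20% bloom fraction exactly despite per-band noise; at a 1.6 m
pixel the 500 algal pixels cover 0.00128 km². The percentage contribution
is large because the calibration's forcing at mean density rivals the
shortwave input of an overcast day — see the methods vignette
(`vignettes/bioalbedo-methods.Rmd`) for a discussion of the conventions and
this sensitivity.

A thin command-line wrapper over the same functions ships in
`inst/cli/bioalbedo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bioalbedo.R",package="bioalbedo"))')" \
    simulate --what scene --seed 7 --out out/
```

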