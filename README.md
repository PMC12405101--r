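# lichenline

Reconstructing reindeer forage-lichen cover and biomass from
heterogeneous greyscale imagery, and modelling herding-district lichen
dynamics under grazing.

Pale mats of forage lichens (*Cladonia*, *Flavocetraria*,
*Stereocaulon*) are the critical winter food of reindeer and, luckily
for retrospective analysis, the brightest widespread surface in northern
tundra landscapes. That makes decades of single-band imagery — old
panchromatic aerial photographs, early satellite frames, modern drone
mosaics — usable as a lichen record, provided the scenes can be put on a
common radiometric scale. `lichenline` is aimed at landscape ecologists
and rangeland analysts who want that whole chain as tested, reusable
code:

* **Calibration** — scenes are converted to greyscale (equal-weight band
  mean) and calibrated to an anchor scene by OLS over pseudo-invariant
  reference areas (dark lakes and fens, bright sandpits): `y = βx + α`
  per platform, with R² reported; very-high-resolution mosaics get a
  two-step local refinement.
* **Mapping** — field plots link grey level to 2D cover (%) and dry
  biomass via `v = (c/100)h` (dm³ m⁻²) and `b = 22v` (g m⁻²); two OLS
  regressions are applied pixelwise with physical clamping (negative
  cover → 0; biomass capped at its value at 100 % cover), then summarised
  as zonal border comparisons, district means (1 g m⁻² ≡ 1 t km⁻²),
  resolution-rescaling coefficients and wMAPE = Σ|O−S| / Σ|O|.
* **Dynamics** — the district model
  `b_{t+1} = b_t + f_t(b_t R_t − b_t) − i d_t − b_t d_t l` with
  `R_t = 1.95 b_t^{-0.1}`, intake `i` from energetics
  (20 MJ d⁻¹ / 10.8 MJ kg⁻¹ × 365 d ≈ 676 kg per reindeer-year),
  reindeer-year densities `d_t`, a Jensen-type landscape factor `f_t`,
  and a trampling-loss parameter `l` fitted by bounded least squares.
* **Synthetic landscapes** — a seeded generator builds ground-truth
  cover/biomass/land-cover rasters, stable reference areas, border-fence
  districts, plot campaigns and census series, so the full pipeline runs
  and is tested without any external data.

Everything is tidyverse-shaped: tabular results are tibbles, fitted
objects have `tidy()`/`glance()` methods, result types have
`autoplot()`.

## Worked example

```r
library(lichenline)

cfg <- pipeline_config(
  landscape = list(extent_m = c(1500, 1500), base_pixel_m = 2,
                   n_lakes = 8, n_fens = 4, n_sandpits = 6),
  seed = 11)
rep <- run_pipeline(cfg)
rep
#> <run_report> seed 11, config d8dafbad4c3abde39859b6da29078a83
#>   calibrations: 4 scenes, R^2 0.85-1.00
#>   regression R^2: cover 1.00, biomass 0.97 (held-out 1.00, 0.99)
#>   fitted loss: sideA l=0.076 (true 0.069), sideB l=0.019 (true 0.019)
#>   mapping wMAPE vs truth: 16.1%

rep$rescale_table
#> # A tibble: 4 × 3
#>   pixel_m mean_biomass_t_km2 coefficient
#>     <dbl>              <dbl>       <dbl>
#> 1       2               147.       1
#> 2      10               147.       1.000
#> 3      30               147.       1.000
#> 4      60               112.       0.761
```

Reading the output: four heterogeneous scenes (drone-like to 60-m early
satellite) calibrated onto the anchor with reference-area R² between
0.85 and 1.00; the plot regressions explain nearly all cover variance
and most biomass variance on the held-out site; the loss parameter
fitted to each district's synthetic biomass history recovers the
generating values (0.069 for the year-round district, 0.019 for the
winter-only district); mapped district biomass differs from the known
truth by a 16 % weighted absolute error; and re-mapping the same scene
at coarser pixels loses biomass (24 % at 60 m) because bright patches
average below the cover zero-crossing before clamping.

The analytic anchors of the growth law are available directly:

```r
growth_law_anchors(model_params())
#> # A tibble: 1 × 3
#>   b_at_max_growth max_growth b_zero_growth
#>             <dbl>      <dbl>         <dbl>
#> 1            277.       30.8          795.
```

— maximum annual growth ≈ 31 g m⁻² near 300 g m⁻² standing biomass, and
zero net growth at ≈ 800 g m⁻².

A thin CLI over the same functions ships in
`inst/scripts/lichenline.R` (`run-all`, `simulate-data`), driven by a
YAML configuration.

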