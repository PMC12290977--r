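# osmotda

Quantitative analysis of osmotic impregnation of plant tissue — the
process in which a food matrix (e.g. apple cubes in concentrated grape
juice) simultaneously loses water and takes up solutes and bioactive
compounds. The package is aimed at food-process engineers and image
analysts who want to (i) monitor how *uniformly* a sample is being
impregnated from plain photographs of its cross-sections, and (ii)
estimate mass-transfer kinetics and effective diffusivities from
gravimetric time series, correcting for the shrinkage of the sample.

Four pieces of machinery, usable separately or through one pipeline:

**Topological image analysis.** A grayscale cross-section image is
filtered by intensity: at each threshold ℓ the superlevel set
{pixels ≥ ℓ} is a binary image whose Euler characteristic
χ = #components − #holes is computed as V − E + F on the closed cubical
complex of its pixels (8-connected foreground, 4-connected holes).
χ(ℓ) over all 256 gray levels is the Euler characteristic curve (ECC).
Images produced by a diffusive staining process behave like Gaussian
random fields and give a characteristic double-peaked ECC — one positive
peak (bright domains) and one negative trough (dark domains). The
difference max(χ/N) − min(χ/N) (the **Max–Min metric**, N = foreground
pixel count) is a scalar proxy for impregnation non-uniformity.

**Peleg sorption kinetics.** Uptake increases Y(t) are fitted with
Y(t) = Y₀ + t/(k₁ + k₂t); the capacity constant gives the equilibrium
increase Yₑ = Y₀ + 1/k₂.

**Shrinkage-corrected effective diffusivity.** The unaccomplished ratio
Ψ = 1 − Y/Yₑ of a cube follows the diagonal series
Ψ(τ\*) = (8³/π⁶) Σᵢ (2i+1)⁻⁶ exp(−3(2i+1)²π²τ\*/4), where
τ\* = ∫₀ᵗ D/L(u)² du and L = L₀(V/V₀)^{1/3} shrinks with the measured
dimensionless volume. The **modified slope method** inverts the series at
each observation, differences the resulting τ\* values into stepwise
interval diffusivities, and averages them over the progress variable
(∫D dΨ / ∫dΨ). The classical non-shrinkage slope method (OLS of ln Ψ on
t, D = −slope·4L₀²/3π²) is provided for comparison, and
e(D) = D_no-shrink / D_shrink quantifies how much ignoring shrinkage
overestimates D.

**Correlation.** Pearson correlation (with t-test p-value) between the
Max–Min metric time series and the stepwise diffusivities, paired by
nearest time.

A seeded synthetic-data generator (finite-difference solution of the
diffusion equation rendered as stained-tissue images with Gaussian
texture; Fickian kinetics through the same series model; exponential
shrinkage) makes every stage testable end to end without laboratory
data.

## Worked example

```r
library(osmotda)

cfg <- simulation_config(D_true = 2e-10, shrink_final = 0.75, seed = 42)

## kinetics -> Peleg fit
kin <- generate_kinetics(cfg, Y_e = 0.436, substance = "water loss")
fit <- peleg_fit(kin)
fit
#> Peleg fit 'water loss' (n = 14)
#>   k1 = 49516.2 +/- 1.2e+03   k2 = 1.49602 +/- 0.038
#>   Ye = 0.66844   R2 = 0.9992   RMSE = 0.004071

## unaccomplished ratio -> shrinkage-corrected diffusivity
psi <- psi_from_kinetics(kin, Ye = 0.436)
est <- modified_slope_method(psi, generate_shrinkage(cfg), cfg$L0)
est
#> Diffusivity estimate (shrinkage method), 'water loss'
#>   D_avg = 2.001e-10 m^2/s over 5 points; R2 = 1.0000, RMSE = 0.0001639
#>   stepwise D in [2e-10, 2e-10] m^2/s

overestimation_ratio(slope_method_no_shrink(psi, cfg$L0), est)
#> [1] 1.163

## images -> ECC -> Max-Min and double peak
imgs <- generate_impregnation_images(cfg)
ec <- euler_curve(imgs[[2]])
ec
#> euler_curve: 256 levels (superlevel), chi in [-40, 26], max-min 0.007161
detect_double_peak(ec, window = 11)$double_peak
#> [1] TRUE
```

Reading the output: the modified slope method recovers the diffusivity
the series was generated with (2.001×10⁻¹⁰ vs 2×10⁻¹⁰ m²/s) even though
the sample shrinks to 75 % of its volume, while ignoring shrinkage would
overestimate D by 16 % here (e(D) = 1.163). The Peleg fit describes the
finite-horizon curve extremely well (R² = 0.999) but its extrapolated
Yₑ = 0.668 overshoots the design equilibrium 0.436 — hyperbolic
extrapolation of an exponentially saturating series; see the methods
vignette. The ECC of the 5-minute image spans χ ∈ [−40, 26] with the
double-peak structure expected of a diffusion-stained texture. The
equilibrium relation applied to a capacity constant k₂ = 2.29 gives
`equilibrium_value(list(Y0 = 0, k2 = 2.29))` = 0.4367 g water/g fresh
product.

`run_pipeline(cfg, out_dir = "out")` executes all stages and writes the
summary CSVs (`peleg_summary.csv`, `diffusivity_summary.csv`,
`correlation_summary.csv`, `max_min_series.csv`, per-time ECC curves)
plus a JSON manifest; identical seeds give byte-identical output.

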