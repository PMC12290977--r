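---
title: "Models and numerical methods in osmotda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in osmotda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

osmotda analyzes osmotic impregnation along two routes that meet at the
end: a *topological* route (images → Euler characteristic curves → the
Max–Min uniformity metric) and a *kinetic* route (uptake series → Peleg
equilibria → shrinkage-corrected Fickian diffusivities). This vignette
is the package's own account of the models, the conventions and
numerical choices behind them, and what the bundled synthetic data can
and cannot demonstrate.

## The kinetic route

### Mass-transfer bookkeeping

All uptake quantities are *increases* per gram of fresh product:
water loss `WL = (m_p0 M0 − m_OP M_OP)/m_p0` and solute gain
`SG = (m_OP(1 − M_OP) − m_p0(1 − M0))/m_p0` from sample masses and
wet-basis moisture fractions, with the identity
`WL − (m_p0 − m_OP)/m_p0 − SG = 0` holding exactly (it is tested to
machine precision on random consistent inputs). Moisture converts
between wet and dry basis as `d.b. = w.b./(1 − w.b.)`. These assume
negligible leaching of native solids, the standard assumption for
osmotic processing.

### Peleg kinetics

Uptake follows the two-parameter hyperbola
`Y(t) = Y0 + t/(k1 + k2 t)`; `k1` (s per substance unit) is the
reciprocal initial rate, `k2` (1 per substance unit) the capacity
constant, and the equilibrium increase is `Ye = Y0 + 1/k2`.
Choices in `peleg_fit()`:

* **Y0 is fixed, not fitted** — to the t = 0 observation (0 for series
  started from fresh tissue). The model treats `Y0` as a datum; fitting
  it would let the hyperbola trade initial value against rate on short
  series.
* **Initialization by linearization.** OLS on `t/(Y − Y0) = k1 + k2 t`
  gives starting values, removing sensitivity to nonlinear-solver
  starts; Levenberg–Marquardt (`minpack.lm::nlsLM`) refines them. If
  the refinement fails on exactly-linearizable (zero-residual) data,
  the linearized estimates are returned.
* Diagnostics are `R² = 1 − SSE/SST` and RMSE on the original scale;
  standard errors come from the Jacobian-based covariance at the
  optimum.
* A constant series (unidentifiable `k2`) and a negative linearized
  `k2` (non-Peleg shape) are errors, not silent misfits.

Times are seconds internally; the CSV reader accepts a `time_min`
column and converts on read, since minute-denominated schedules are
common.

### The cube series and its 8/15 convention

The unaccomplished ratio `Ψ = 1 − Y/Ye` of a cube is modeled with the
diagonal series

`Ψ(τ*) = (8³/π⁶) Σ_{i≥0} (2i+1)⁻⁶ exp(−3(2i+1)²π²τ*/4)`,

`τ* = ∫₀ᵗ D/L(u)² du`, `L = L0 (V/V0)^{1/3}`. Because
`Σ(2i+1)⁻⁶ = π⁶/960`, this series equals **8/15 ≈ 0.533 at τ* = 0, not
1**: the diagonal form keeps only the equal-index terms of the full
triple product over the three axes. The package uses the printed
diagonal form *consistently on both sides*: the synthetic-kinetics
generator rescales, `Y(t) = Ye (1 − Ψ(τ*)/Ψ(0))`, so that `Y(0) = 0`
exactly, and the estimator treats observed ratios above `psi_model(0)`
as too early for the series and excludes them. Because the series'
higher terms decay as `(2i+1)⁻⁶`, the rescaling shifts `τ*` by a nearly
constant offset (< 3·10⁻⁴ for τ* > 0.02), which cancels in the
differences the estimator uses; round-trip tests confirm recovery
within 2 % without shrinkage. The full product-form solution is out of
scope; mixing the two forms would be inconsistent.

`psi_model()` truncates when a term falls below 1e-14 (cap 200 terms) —
at τ* = 0 that is ~98 terms and reproduces 512/960 to ~4·10⁻¹³.
`invert_psi()` brackets via the one-term approximation and bisects the
monotone series to an interval below 1e-13, giving round-trip accuracy
better than 1e-6 over τ* ∈ [0, 2] (tested on 100 random points).

### The modified slope method

Given observed `Ψ_k` at times `t_k`, a shrinkage curve, and the initial
half-length `L0`:

1. exclude `Ψ > psi_model(0)` (counted and reported as
   `n_excluded_early`);
2. enforce monotone nonincreasing `Ψ` by dropping points that rise
   above the running minimum (noise cannot make `τ*` decrease; dropped
   count reported);
3. invert the series at each kept point to get `τ*_k`;
4. interval diffusivity
   `D_k = L̄_k² (τ*_k − τ*_{k−1})/(t_k − t_{k−1})`, with `L̄_k` the
   half-length at the interval midpoint from the linearly interpolated
   dimensionless volume;
5. average: for an isotropic cube with `D` a function of the single
   progress variable `Ψ`, the triple progress integral
   `∫∫∫D dΨdΨdΨ / ∫∫∫dΨdΨdΨ` reduces to `∫D dΨ / ∫dΨ`, evaluated as the
   `|ΔΨ|`-weighted mean of the interval values — the only reading of
   the weighted average that is well-defined from discretely observed
   data.

At least 3 usable points (2 intervals) are required. `R²`/RMSE are
computed on the Ψ scale by re-predicting the kept points from the
averaged `D` and the shrinking path, with the model curve normalized by
its τ* = 0 value to match the observed `Ψ(0) = 1` convention.

`L0` is the **half-edge** of the cube (0.00609 m for a 1.2 cm cube):
slab-type series use half-thickness, and the measured sample dimension
enters only through this constant.

The classical non-shrinkage method regresses `ln Ψ` on `t` (points with
0 < Ψ < 1) and sets `D = −slope · 4L0²/(3π²)`. Because the diagonal
series is first-term-dominated to within ~0.14 %, this line is
essentially exact at *all* τ*, not only late times. The ratio
`e(D) = D_no-shrink/D_shrink` exceeds 1 whenever the sample truly
shrinks (the fixed, too-long `L0` inflates `D`); equality within 3 % is
recovered when shrinkage is absent. Published e(D) magnitudes of order
10–500 for 20–60 % shrinkage are not reproducible from the ratio as
literally defined — the package implements the literal definition and
makes no attempt to match those magnitudes.

### Why the pipeline does not use the fitted Ye for Ψ

The Peleg hyperbola approaches equilibrium like 1/t; the Fickian series
approaches exponentially. Fitted to a finite-horizon Fickian series
(810 min, where Ψ has only decayed to ~0.1), the hyperbola describes
the data superbly (R² > 0.999) yet extrapolates an equilibrium ~50 %
too high (0.668 vs a design value of 0.436 under default settings).
Forming `Ψ = 1 − Y/Ye` with that inflated `Ye` compresses the observed
range of Ψ and biases `D` low by a factor of ~4. In simulation mode the
design equilibrium of each substance is known, so `run_pipeline()` uses
it for Ψ and reports the Peleg fit separately as the finite-time
estimate it is. With laboratory data run to actual osmotic equilibrium
this mismatch is far smaller, but users fitting short experiments
should prefer an independently measured equilibrium when forming Ψ.

## The topological route

### Pixel topology

χ is computed as `V − E + F` on the **closed cubical complex** whose
2-cells are the foreground pixels, with shared edges and vertices
identified. Closed squares meeting at a corner are connected, so this
convention means 8-connectivity for foreground components and
4-connectivity for background; a "hole" is a background component that
does not touch the image border. The implementation counts V, E, F with
four vectorized shifts of the padded mask; an independent flood-fill
oracle (components minus enclosed holes) agrees on 1,000 random grids
in the test suite. χ is additive over disjoint regions, and pixels
outside the foreground mask never enter the complex — border-touching
background is never a hole.

### Filtration, normalization, Max–Min

The default filtration is **superlevel** (keep intensity ≥ level) over
all 256 gray levels: sweeping downward first isolates bright (lightly
stained) domains as components, then dark (heavily stained) domains as
holes, which is the natural reading of removing low-intensity regions.
A sublevel flag is provided since the opposite convention is equally
computable. `chi_norm` divides χ by the foreground pixel count so
curves from different sample sizes are comparable; published normalized
magnitudes for this kind of data cannot be reproduced exactly because
the constant used there is unstated, so the normalization here is
documented and configurable by construction (the metric is a max–min
difference, so any fixed positive constant rescales it without
reordering samples). The Max–Min metric `max(chi_norm) − min(chi_norm)`
is nonnegative, invariant to reversing the level order, and equals
`1/N` for a constant image on a simply connected N-pixel mask.

### Double-peak detection

An image whose intensity is a stationary Gaussian-like field yields an
ECC with one positive peak and one negative trough. `detect_double_peak()`
smooths `chi_norm` with a centered moving average (default window 5
levels) and counts interior runs above `+tol` and below `−tol`
(default `tol = 1/N`, one χ unit): the flag is TRUE iff there is
exactly one of each. The 1/N tolerance deliberately rejects the unit
step of a constant image. For full 256-level curves of the synthetic
images, ±1-unit wiggles at single-level resolution can fragment the
runs, so the package's own analyses and tests widen the window to 11
levels there; both parameters are exposed.

### Segmentation

Samples photographed against a blue backdrop are segmented by a
channel-margin rule — background is where blue exceeds max(red, green)
by ≥ 20 gray levels — followed by keeping the largest 4-connected
foreground component (`EBImage::bwlabel`) and filling interior holes
(`EBImage::fillHull`), since backdrop-colored specks inside tissue are
part of the sample. An image with no foreground is a signaled
segmentation failure.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions for every property test.

* **Images.** The diffusion equation on a square with Dirichlet
  boundary `C = 1` and `C(0) = 0` is integrated by explicit FTCS with
  `dt = 0.2 dx²/D` (safely inside the 2-D stability bound 0.25;
  user-supplied steps violating the bound are rejected before
  integration). Against the separable analytic series for the square,
  the trapezoid-weighted mean uptake agrees within 1 % on the default
  96×96 grid. Rendering maps concentration to intensity linearly,
  `255(1 − C)` — a modeling choice, since the true stain-to-gray
  response of photographs is unknown — and adds (i) a tissue texture
  field: white noise smoothed by a Gaussian kernel of width
  `texture_scale` px, scaled to `texture_amp` gray levels, *anchored at
  mean −2.5·texture_amp* so texture strictly darkens; and (ii)
  independent per-image pixel noise. The anchoring matters: a zero-mean
  texture on unstained tissue (base 255) clips half the pixels at the
  white point, and that clipped set percolates (site threshold ≈ 0.41
  for 8-connectivity), destroying the bright-domain ECC peak. With the
  darkening texture, early-time tissue is an unclipped Gaussian field
  just below white and shows the double peak, as it should. One texture
  field per run (tissue structure is persistent); pixel noise is
  redrawn per image; both derive from the single configuration seed, so
  equal seeds give bit-identical output.
* **Kinetics.** `τ*(t)` is accumulated by composite trapezoid on a
  4,000-point grid over the analytic shrinkage curve, then
  `Y = Ye(1 − Ψ(τ*)/Ψ(0))`. Noise can be additive (substance units)
  and/or multiplicative (relative), both seeded.
* **Shrinkage.** `V/V0 = v_f + (1 − v_f) e^{−rt}`: monotone relaxation
  from exactly 1 to a plateau, the qualitative shape of measured
  osmotic shrinkage.

### Default study conditions

| parameter | default | why |
|---|---|---|
| `D_true` | 2×10⁻¹⁰ m²/s | center of reported effective diffusivities for osmotic water/solute transfer in fruit |
| `L0` | 0.00609 m | half-edge of a 1.2 cm cube |
| `t_samples` | 0–810 min (14 points) | a typical osmotic immersion schedule, dense early, extending to 48,600 s |
| `grid_n` | 96 | resolves the boundary layer; keeps the FTCS run and 256-level ECC sweeps desk-scale |
| `boundary_value` | 1.0 | saturated surface, dimensionless |
| `noise_sigma` | 2 gray levels | sensor-scale pixel noise |
| `texture_scale` | 3 px | tissue feature size ≪ sample size, ≫ pixel |
| `texture_amp` | 12 gray levels | visible texture; calibrated (with the −2.5σ anchor) so early-time ECCs show the double peak |
| `shrink_final` | 0.75 | 20–25 % volume loss, typical of osmotic dehydration |
| `shrink_rate` | 1×10⁻⁴ s⁻¹ | shrinkage equilibrates within a few hours, faster than mass transfer |

Property tests run the recovery grid D ∈ {1, 2, 4}×10⁻¹⁰ m²/s ×
`shrink_final` ∈ {1.0, 0.75, 0.5}, noiseless (error ≤ 5 %) and with 1 %
multiplicative noise (20 seeded replicates per cell, median error
≤ 10 %). These sizes — 96² pixels, 14 time points, 20 replicates — are
the package's chosen desk-scale study conditions.

### What passing tests do and do not show

The generator emulates boundary-driven Fickian uptake, Peleg-shaped
saturation, monotone shrinkage, and Gaussian-field image texture. It
does **not** emulate: 3-D voxel structure (images are 2-D sections);
corner rounding and anisotropic deformation of real cubes (the mask
stays square); concentration-dependent D; external mass-transfer
resistance; vacuum-pulse physics; or the unknown nonlinear
stain-to-gray response of real photographs. Passing round trips
therefore demonstrate *internal consistency* of the estimators under
the stated model, not field accuracy on laboratory images; published
per-treatment diffusivities cannot be recomputed here because the
underlying kinetic observations exist only as figures.

## Correlation stage

Pearson r with a two-sided t-test p-value; constant series are a
signaled error, not r = NA. The Max–Min metric series is paired with
stepwise diffusivities at interval midpoints by nearest time within a
tolerance (default: half the minimum metric sampling interval), and at
least 3 pairs are required. Pairing a per-interval quantity with a
per-time metric is an interpretation — the construction behind
published per-treatment correlation scalars is not fully specified —
so tests assert the sign-recovery property (metrics built to increase
or decrease linearly in D give |r| > 0.99 with the built sign) rather
than any printed coefficient. No multiplicity correction is applied.

## Known limitations

* The diagonal cube series caps Ψ at 8/15; observations above it
  (early times) are unusable for inversion, which with sparse schedules
  can leave few intervals for slow substances.
* The Ψ-weighted average weights intervals by observed progress; other
  defensible weightings (time-weighted, unweighted) would differ on
  strongly concentration-dependent data.
* The Max–Min metric depends on the (configurable) normalization
  constant and on smoothing; only comparisons under a fixed convention
  are meaningful.
* `equilibrium_value()` applied to short-horizon Peleg fits inherits
  the extrapolation bias discussed above.
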