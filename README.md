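# delimech

Mechanics and sensory texture of thin sheet-like meat products.

Deli meat slices — and their plant-based imitations — are thin membranes
whose mechanics are best measured by planar **biaxial extension**: a square
sample is stretched along two orthogonal in-plane axes with different
stretch ratios (five modes: `strip-x`, `strip-y`, `off-x`, `off-y`,
`equibiax`). `delimech` is an R package for scientists analyzing such
tests. It covers the full path from raw force–displacement recordings to
constitutive models and on to the statistics that connect physical
stiffness with how consumers perceive texture:

1. **Raw data processing** — convert forces (mN) and gauge lengths (mm)
   into stretches and Piola stresses (kPa) via
   `λ₁ = l₁/L₁`, `P₁₁ = F₁/(L₂ t)`, find the preload-defined reference
   configuration, extract stretch–recovery cycles, and resample/average
   loading and unloading curves on a common stretch grid.
2. **Classical model fitting** — incompressible, isotropic hyperelasticity
   with the plane-stress pressure eliminated analytically:

       P₁₁ = 2[λ₁ − λ₁⁻³λ₂⁻²] ∂ψ/∂I₁ + 2[λ₁λ₂² − λ₁⁻³] ∂ψ/∂I₂

   The neo-Hookean energy `ψ = c₁/2 (I₁−3)` and Mooney–Rivlin energy
   `ψ = c₁/2 (I₁−3) + c₂/2 (I₂−3)` are linear in their parameters, so both
   are identified by ordinary linear least squares over all five loading
   modes simultaneously. Shear modulus `μ = c₁` (or `c₁+c₂`) and stiffness
   `E = 3μ` follow from incompressibility (`ν = 0.5`).
3. **Automated model discovery** — an eight-term invariant-based strain
   energy library (linear, exponential, quadratic, exponential-quadratic
   shapes in `I₁−3` and `I₂−3`, each with an external kPa-scale weight and
   an internal dimensionless weight) trained by Adam gradient descent on
   non-negative weights with an L1 penalty `α‖w‖₁`. Sweeping `α` upward
   until exactly two terms survive yields an interpretable sparse model;
   the surviving pair is refit without penalty.
4. **Sensory statistics** — scoring of the food-neophobia (10 items,
   7-point) and meat-attachment (16 items, 5-point) questionnaires,
   per-feature one-way ANOVA over a 12-feature Likert texture panel, and
   Spearman rank correlations between physical stiffness and sensory
   features with *exact* permutation p-values for n ≤ 10 products.
5. **Synthetic ground truth** — a seeded generator for biaxial recordings
   (five modes, loading/unloading hysteresis, multiplicative noise) and
   for survey panels with a tunable latent stiffness–texture link, so
   every stage of the pipeline is testable against known truth.

The package ships `deli_meat_means()`: measured mean stress–stretch curves
for eight commercial products, four plant-based (PT, PH, PD, PP) and four
animal (AT, AC, AH, AP), five modes × two directions × 11 points each.

## Worked example

```r
library(delimech)

# Fit the neo-Hookean model to the plant-turkey mean data
fit <- fit_hyperelastic(deli_meat_means("PT"), "neo-hooke")
fit
#> Incompressible hyperelastic fit: neo-hooke
#>   product: PT
#>   coefficients (kPa): c1 = 127.2
#>   shear modulus mu = 127.2 kPa, stiffness E = 3 mu = 381.5 kPa
#>   R2 = 0.82 +/- 0.15 (rss, per curve)
```

Plant turkey is a stiff material: a shear modulus of 127 kPa and a
stiffness of about 380 kPa, roughly three times stiffer than typical
animal deli products. The R² line summarizes per-curve goodness of fit
(`1 − SSres/SStot`, truncated at zero) across the eight retained curves —
held channels of the strip modes are excluded there but included in the
least-squares fit itself.

```r
# Discover the best two-term strain energy for the same product
disc <- discover_model(deli_meat_means("PT"), cann_control(seed = 1))
disc
#> Discovered two-term constitutive model
#>   product: PT
#>   active terms: 1 (I1 linear), 2 (I1 exponential)
#>     w1 = 6.858 kPa, w1* = 7.546
#>     w2 = 4.873 kPa, w2* = 2.231
#>   selected at alpha = 0.00316; R2 = 0.82 +/- 0.15 (rss, per curve)
```

The sparsity sweep keeps a linear and an exponential first-invariant term:
plant turkey behaves like a neo-Hookean solid with mild stiffening. A
product whose truth is Mooney–Rivlin instead yields the `{I1 linear,
I2 linear}` pair (see the test suite, where this is exercised against the
synthetic generator).

```r
# Does physical stiffness predict a sensory feature rated on 1..5?
stiffness  <- c(378, 343, 213, 113, 134, 117, 117, 49)   # kPa, 8 products
brittle    <- c(4.4, 4.1, 3.6, 2.4, 2.8, 2.5, 2.7, 2.1)  # panel means
spearman_cor(stiffness, brittle)
#> Spearman rank correlation: rho = 0.994, p = 9.921e-05 (exact_permutation, n = 8)
```

With only eight products the permutation null is enumerated exactly
(8! = 40,320 orderings) rather than approximated.

## Layout

- `R/biaxial_io.R` — recordings, conversion, cycles, resampling, dataset dialect
- `R/kinematics.R` — invariants, energy-model interface, biaxial Piola stress
- `R/classical_fits.R` — `fit_hyperelastic()` and the `hyperfit` methods
- `R/model_discovery.R` — the eight-term network, `train_cann()`, `discover_model()`
- `R/sensory_stats.R` — questionnaires, Likert summaries, ANOVA, Spearman
- `R/synthetic_data.R` — seeded generators with ground truth
- `vignettes/deli-meat-mechanics.Rmd` — models, conventions and design choices
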