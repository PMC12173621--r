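---
title: "Biaxial mechanics of deli meats: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biaxial mechanics of deli meats: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the conventions it adopts where several are defensible, and the
reasoning behind the design choices. It is written for a user who wants to
know *why* the package computes what it computes, not just how to call it.

## The experiment and its kinematics

A thin square sample (a deli slice) is held by rakes forming a roughly
12 × 12 mm gauge region and stretched along two orthogonal in-plane axes.
Five loading modes couple the two stretches differently: the *strip* modes
hold one axis at λ = 1, the *off* modes stretch both with one leading, and
*equibiax* stretches both equally. Forces are measured in mN, gauge lengths
in mm, and the sample thickness t in mm; with these units the Piola
(nominal) stresses

$$\lambda_1 = \frac{l_1}{L_1}, \quad \lambda_2 = \frac{l_2}{L_2}, \quad
P_{11} = \frac{F_1}{L_2\,t}, \quad P_{22} = \frac{F_2}{L_1\,t}$$

come out directly in kPa. The reference gauge lengths $L_1, L_2$ are taken
at the first recorded step at which *both* axial forces reach the preload
(30 mN by default). The preload is applied on both axes, so we treat the
two axes symmetrically in the detection rule; an asymmetric rule ("either
force") would bias the reference toward the softer axis.

The material is treated as incompressible ($I_3 = 1$, thickness stretch
$\lambda_3 = 1/(\lambda_1\lambda_2)$), isotropic, and hyperelastic with a
strain energy $\psi(I_1, I_2)$. Incompressibility is enforced analytically
— the pressure-like multiplier is eliminated through the
zero-thickness-stress condition $P_{33} = 0$ — rather than penalized,
because the experiments never probe the thickness direction and a penalty
would only add a tuning constant. The resulting plane-stress relation,

$$P_{11} = 2\left[\lambda_1 - \tfrac{1}{\lambda_1^3\lambda_2^2}\right]
\frac{\partial\psi}{\partial I_1}
 + 2\left[\lambda_1\lambda_2^2 - \tfrac{1}{\lambda_1^3}\right]
\frac{\partial\psi}{\partial I_2},$$

is verified in the test suite against central finite differences of the
full three-dimensional tensor relation $P = \partial\psi/\partial F - p
F^{-T}$ to a relative tolerance of $10^{-6}$. Stretches are guarded to
[0.5, 2]: the experiments live in [1, 1.25], and evaluations far outside
that range usually indicate a unit mistake rather than a physical state.

## From recordings to curves

Each mode is cycled three times; the final cycle is analyzed, split into
its loading (stretch non-decreasing) and unloading (non-increasing)
halves. Curves are resampled by piecewise-linear interpolation on an
equidistant grid of the mode's *leading* stretch — the held channel of a
strip mode has no stretch axis of its own and is interpolated against the
leading stretch as well. The data are dense and monotone in stretch, and
no smoothing is part of the measurement model, so linear interpolation is
sufficient and unbiased. The default grid has 11 points, matching the
packaged mean dataset.

Averaged curves are re-anchored so the first grid point is exactly
(λ = 1, P = 0): the interpolated stress at the grid origin — in practice
the preload baseline — is subtracted channel-wise. The packaged dataset
follows the same convention, with every curve starting at 1.00/0.00.

When several curves are averaged, the common grid runs from λ = 1 to the
*smallest shared* maximum stretch. Instruments do not always reach the
prescribed displacement, so replicate curves end at slightly different
stretches; restricting to the shared support avoids averaging a varying
number of curves per grid point, at the cost of discarding the extreme tip
of the longest curves. This shared-support rule is a package choice, and
worth remembering when comparing absolute stress levels near peak stretch.

## Classical fits and their conventions

Both classical models are linear in their parameters, so fitting is
ordinary linear least squares stacking both stress components of every
state across all five modes — about 110 states and 220 equations per
product at the default grid. Hold-direction stresses of the strip modes
are *included* in the fit (the loss sums both components without
exception) but *excluded* from the reported goodness of fit; both switches
are exposed (`include_hold`, `r2_include_hold`) because the two
conventions answer different questions: the fit wants every constraint the
experiment provides, while the fit-quality summary describes the curves a
reader actually inspects. All points carry equal weight — no per-mode
normalization — so stiff modes with larger stresses influence the
parameters more; this is the behavior of the plain stacked loss, stated
here so that nobody mistakes it for an accident.

Parameters are reported with no sign constraint: two-term fits of real
products routinely return a negative second coefficient, which is
physically admissible as long as the total shear modulus
$\mu = c_1 + c_2$ stays positive. Incompressibility fixes Poisson's ratio
at 0.5, so the stiffness is always $E = 3\mu$.

**Goodness of fit.** The default R² is computed *per retained curve* (x
and y channels of off-x/off-y/equibiax, only the stretched channel of the
strip modes — eight curves in all) as $1 - SS_{res}/SS_{tot}$, truncated
at zero, and summarized as mean ± sd across the curves. The truncation
keeps the summary inside [0, 1] for hopeless fits, at the cost of hiding
how bad a negative-R² curve really is — the untruncated values remain
available via `clip = FALSE`. Two alternatives are provided because they
answer different questions: `method = "pearson"` (squared correlation) is
insensitive to scale and offset errors and thus flatters a model with the
right shape but the wrong stiffness, and `by = "mode"` pools the two
directions of a mode into one value. The residual-based per-curve default
is the discriminating choice and is what the packaged reference analyses
report. Curves with constant measured stress (possible for a held channel
of a degenerate recording) have no defined R² and are excluded from the
mean with a warning.

**Two reporting conventions.** For replicated experiments the package
supports both: (a) fit each sample and report the across-sample mean ± sd
of the parameters (`fit_samples()`), and (b) fit the across-sample mean
curves once (`fit_hyperelastic()` on the averaged dataset). The two
conventions give similar central values but different uncertainties; any
report should label which one produced each number. Whether per-sample
fits use full-resolution or 11-point curves is exposed through the
`n_points` argument of the pipeline rather than fixed, since the
difference is within interpolation error for smooth curves.

## The discovery network

The discovery library is a sum of eight decoupled terms — linear,
exponential, quadratic, and exponential-quadratic shapes in $(I_1 - 3)$
and in $(I_2 - 3)$ — each carrying an internal dimensionless weight inside
the nonlinearity and an external kPa-scale weight outside it. Term 1 alone
is the neo-Hookean model ($c_1 = 2 w_1 w_1^*$) and terms {1, 5} embed
Mooney–Rivlin, identities the test suite asserts exactly.

Training minimizes the mean squared stress error over all five modes
simultaneously plus an L1 penalty, by Adam (step 10⁻³, up to 20,000
epochs, uniform(0, 1) seeded initialization) with analytic gradients.
Design choices that matter:

- **Non-negative weights.** Weights are clipped at zero after every
  update. Every term in the library is then a convex non-decreasing
  function of its invariant, the energy is non-negative on the tested
  stretch range, and terms cannot cancel each other — which is what makes
  a two-term answer interpretable. The cost is that materials genuinely
  needing a negative second-invariant contribution are pushed toward
  other term combinations.
- **Penalty on external weights only.** The external weights carry the
  stress scale (kPa); the internal ones are dimensionless curvature
  parameters. Penalizing both would mix units in one norm. The switch
  `penalize_internal` restores the all-weights norm for comparison.
- **Activity threshold.** A term counts as active when its weight product
  $w_k w_k^*$ exceeds 10⁻³ of the largest product — relative, because the
  stress scale varies by an order of magnitude across products.
- **Selection.** The penalty sweep (logarithmic, 10⁻⁴…1) ascends until
  exactly two terms survive; the smallest such penalty distorts the
  surviving weights least. The selected pair is then refit with the
  penalty removed, so reported weights are unbiased by the selection
  device; the penalized weights are kept alongside for inspection. If no
  penalty in the sweep yields exactly two terms, the function fails
  loudly with the full active-term profile rather than guessing.
- **Non-uniqueness.** Only the product $w_k w_k^*$ is identified for the
  linear terms, and near-degenerate term pairs can trade off; tests
  therefore assert predicted stresses and active-term identities, not
  individual weight values.

Training uses all available data; train/test splits are out of scope for
a 16-parameter model fit to hundreds of points. Early stopping triggers
when the loss is numerically stationary over a 500-epoch window, which
cuts most runs well short of the epoch cap.

## Sensory statistics

The two questionnaires are scored by summing item responses after
reflecting reverse-coded items ($x \mapsto s + 1 - x$ on an $s$-point
scale). The ten-item neophobia survey uses its standard reverse key
(items 1, 4, 6, 9, 10); the sixteen-item meat-attachment questionnaire has
reverse-worded aversion items whose *positions* depend on the administered
form, so the package deliberately ships no default key for it — pass the
positions explicitly. Totals are bounded by construction: 10–70 and 16–80.

Likert texture scores are treated as interval data and compared across
products by plain one-way ANOVA with participants as independent
observations (no repeated-measures correction); the test suite verifies
that the realized type-I error rate under a null panel stays at the
nominal 5 %. Zero-variance features are flagged as degenerate rather than
significant.

Stiffness–texture association uses Spearman rank correlation on
*product-level* feature means — eight points when eight products are
tested. At that sample size the t approximation is unreliable, so for
n ≤ 10 the two-sided p-value is exact, enumerating all n! rank orderings
(chunked over the first position above n = 8 to bound memory at about
26 MB). Ties get midranks and the tie-corrected Pearson-on-ranks formula,
which reduces to $1 - 6\sum d^2 / (n(n^2-1))$ without ties. Correlations
are reported signed; with many feature pairs and no multiple-testing
correction, flagged pairs at p < 0.05 are descriptive, not confirmatory —
a correction was left out deliberately so the flags match the unadjusted
convention common in small sensory panels, and the full p matrix is
returned for anyone who wants to adjust.

## The synthetic generator

The generator exists so that every pipeline stage can be validated against
known truth. It emulates:

- the five-mode protocol (strip/off/equibiax), 1 %/s stretch rate, three
  stretch–recovery cycles, 30 mN preload, 12 × 12 mm gauge; prosciutto-
  style products run to λ = 1.25 instead of 1.1;
- the off-mode trailing axis as the square root of the leading stretch,
  which reproduces the relative displacements of the laboratory protocol
  (a trailing stretch of 1.0488 at a leading 1.1, and 1.118 at 1.25);
- loading/unloading hysteresis as a symmetric multiplicative split about
  the elastic curve, $P = P_{el}(1 \pm g\sin \pi s)$ with $s$ the loading
  progress — the sine closes the loop at both turning points (real
  hysteresis loops meet at the reversal), and the symmetry makes
  loading/unloading averaging exactly unbiased, matching the package's
  averaging convention;
- multiplicative lognormal noise by default: stress magnitudes span an
  order of magnitude across modes, and additive noise would drown the
  soft modes while barely perturbing the stiff ones (an additive option
  exists);
- the preload as an additive force baseline carried through the test and
  removed downstream by re-anchoring, so the noiseless
  simulate–convert–resample–fit loop recovers the generating parameters
  to better than 0.1 %.

The synthetic eight-product panel mirrors the stiffness ladder of
commercial products (about 380 down to 45 kPa in E) and includes one exact
Mooney–Rivlin product so that discovery has a recoverable
{I1 linear, I2 linear} ground truth.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: rate dependence and viscoelastic creep
(hysteresis here is a static split, not a time effect), fiber or
micro-bubble microstructure and any anisotropy, instrument under-travel
(simulated ramps always reach their target), slipping rakes, and
participant-level idiosyncrasies in the survey model beyond iid Gaussian
noise on a latent scale.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for a laptop-class
single core: 11-point grids, panels of 3–8 samples, 20 replicate panels
for parameter-recovery statistics, 500 simulated null panels for the
ANOVA type-I check, 5–10 training seeds for the stochastic discovery
checks. These sizes were chosen once, for statistical sufficiency at
desk scale.

## Known limitations

- The constitutive description is elastic and isotropic; products with
  visible oriented fibers are averaged over orientation by protocol, not
  modeled.
- R² conventions differ across the literature; always state the one used
  (this package's default: per-curve residual-based, truncated, hold
  channels excluded).
- Exact permutation p-values stop at n = 10; beyond that the t
  approximation is used.
- The meat-attachment questionnaire cannot be scored without supplying
  its reverse-key positions.
- Discovered weights are reported from the unpenalized refit; comparing
  them across penalty settings requires the recorded penalized weights.
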