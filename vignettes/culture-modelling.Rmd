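---
title: "Modelling and optimizing microalgal photobioreactor cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing microalgal photobioreactor cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoculture)
```

`phycoculture` models autotrophic batch cultures of microalgae in sparged
bubble-column photobioreactors and optimizes their operating conditions.
This vignette explains the model, the statistical machinery around it, and
the numerical and design choices the package makes — including the places
where the published numbers it reproduces are internally inconsistent and
what the package does about that.

## The culture model

The state is six variables: biomass `X`, nitrate `N`, phosphate `P`,
dissolved CO₂ `C`, dissolved O₂ `O2` (all in mg/L) and `pH`. Nitrate and
phosphate are carried as the mass of their salts (KNO₃ and the potassium
phosphate buffer), because yields for this system are conventionally
quoted per salt; readers expecting elemental N and P should divide by the
corresponding mass fractions. Time is in days.

Growth is multi-substrate Monod kinetics,

$$\mu = \mu_{max}\,\frac{N}{K_N+N}\,\frac{P}{K_P+P}\,\frac{C}{K_C+C}\,
\frac{I}{K_I+I},$$

a product of independent saturating limitations. The model deliberately has
no photoinhibition term: over the 13–65 µmol m⁻² s⁻¹ range of interest the
light response is monotone, and the light Monod factor captures it. (One
published parameter table labels $K_I$ a carbon-dioxide constant; it is the
light half-saturation constant, as its units show.)

### Light attenuation

Cells shade each other and foul the reactor wall, so the light reaching the
culture is less than the incident `I0`. The default law is *bounded
shading*,

$$I(X) = I_0\left(1 - \alpha\,\frac{X}{K_{IX}+X}\right),$$

which equals `I0` at zero biomass and saturates at the floor
`I0·(1 − α)`. With the reference parameters (α = 0.263, K_IX = 0.0252
mg/L) the floor is ~74% of incident light and is reached almost
immediately, since K_IX is far below working biomass densities.

Two alternative readings are selectable through
`reactor_config(attenuation_model =)`, because the attenuation law in the
source material is typographically ambiguous. The *literal* typeset form,
`I0·(1 − α(1+X)/(K_IX+X))`, is dimensionally inconsistent (it adds 1 to a
concentration) and goes strongly negative at low biomass with the
reference constants, so it is clamped at zero; note that after clamping it
*increases* with biomass toward the same `1 − α` floor, which is one more
reason it is not the default. The *available fraction* form
`I0·α·K_IX/(K_IX+X)` decays to zero. Only the bounded-shading default is
both non-negative and non-increasing over the observed biomass range.

A related published remark says the α value implies light "reduces by
about 75%". Under the bounded form, α = 0.263 means light is reduced *to*
about 74%, not *by* 75%; the package implements the equations, not the
remark.

### Mass balances, gas transfer, and pH

$$\frac{dX}{dt} = (\mu - \mu_d)X \qquad
\frac{dN}{dt} = -Y_{NX}\mu X - \mu_{mN} N \qquad
\frac{dP}{dt} = -Y_{PX}\mu X - \mu_{mP} P$$

$$\frac{dC}{dt} = -Y_{CX}\mu X + k_La_C(C^*_C - C) - \mu_{mC} C \qquad
\frac{dO_2}{dt} = Y_{O_2X}\mu X + k_La_{O_2}(C^*_{O_2} - O_2) - \mu_{mO_2} O_2$$

Each substrate is consumed proportionally to growth (the yields
$Y_{\cdot X}$) plus a first-order maintenance term; the sparged gas phase
exchanges CO₂ and O₂ with the broth through standard $k_La(C^*-C)$ terms.

pH is a linear surrogate: as photosynthesis draws down dissolved CO₂ the
broth alkalinizes, and the model takes the change as proportional,
$dpH = -K_{pH}\,dC$ with $K_{pH} > 0$. (The typeset source prints the
equation without a sign; the accompanying text says pH rises as CO₂ falls,
and the text wins.) Because this is an exact affine relationship, the
package does not integrate pH as a sixth ODE state at all: it integrates
the five mass balances and reconstructs
`pH(t) = pH0 − K_pH·(C(t) − C0)` afterwards. The invariant
`pH(t) − pH(0) = −K_pH·(C(t) − C(0))` therefore holds to machine
precision, not merely to solver tolerance. The surrogate has no carbonate
speciation in it, so extreme parameter choices can push pH outside the
physical 0–14 range; input validation bounds only the *initial* pH.

### Defaults, integration, and degenerate inputs

Default parameters (`chlorella_kinetics()`) are the fitted values for the
reference *C. sorokiniana* strain — e.g. μmax 2.19 d⁻¹, K_N 31.5 mg/L,
kLa_C 3.45 d⁻¹, C*_C 0.81 mg/L, K_pH 6.11 L/mg. Default initial
conditions are X₀ = 100 mg/L (the experimental inoculum), N₀ = 670 and
P₀ = 800 mg/L (the best-performing salt levels from the nutrient screen),
gases at their equilibrium concentrations, pH 7. The experiments used a
12:12 light/dark cycle but the model, like its source, assumes constant
light; a square-wave photoperiod (`photoperiod_fraction`) is available as
an off-by-default extension.

Integration uses `deSolve::ode(method = "lsoda")` with rtol 1e-6 and atol
1e-9, both recorded in the configuration. During stiff steps the solver may
probe slightly negative concentrations; the right-hand side clamps the
state at zero *inside* the evaluation (rather than post hoc) so Monod
factors never go negative. The test suite verifies the integrated
trajectory against an independently coded fixed-step fourth-order
Runge–Kutta oracle at dt = 1e-3 day to a pointwise relative error below
1e-4 on all six variables.

Under the defaults the trajectory reproduces the expected batch phases: a
lag to ~day 4, exponential growth to ~day 8, then a stationary phase as
nitrate runs out (below 1% of N₀ between days 9 and 11).

### Two growth rates, one doubling time

The reference study reports both μmax = 2.19 d⁻¹ (in its fitted parameter
table) and an "optimized" specific growth rate of 0.61 d⁻¹ in its text,
without reconciling them. The package exposes both and corrects neither:
simulation defaults use 2.19 (the parameter-table value, which produces
the published trajectory shape), while the famous 1.1-day doubling time is
`doubling_time(0.61)` = ln 2 / 0.61 ≈ 1.14 ≈ 1.1 d. Note that μmax is a
*maximum* rate; the realized μ under shading and substrate limitation in
the simulation is far below 2.19.

## Parameter estimation

`fit_culture()` minimizes the sum over variables and observation times of
squared residuals. Two decisions matter more than the optimizer:

**Weights.** The faithful objective sums *raw* squared differences across
variables whose scales differ by three orders of magnitude (nitrate in
hundreds of mg/L, dissolved CO₂ below 1 mg/L). With raw weights the
gas-transfer coefficient kLa_C is effectively invisible to the objective
and cannot be recovered. `weights = "raw"` remains the default for
fidelity, but `weights = "variance"` (inverse observation variance per
variable) is the recommended mode and is what the package's own recovery
studies use; under it, {μmax, K_N, kLa_C} are recovered within 15% from
synthetic data with 2% multiplicative noise and 15 daily observations.

**The optimizer.** The contract is a bounded derivative-free local search
with multistart. The package runs Nelder–Mead (`stats::optim`) on a
logistic transform of the box constraints (Brent in one dimension), from
`n_starts = 5` points drawn uniformly within bounds from the seed, with
relative convergence tolerance 1e-8 and at most 2000 evaluations per
start. The best local optimum wins; results are bit-reproducible for a
fixed seed, and no global-optimality claim is made. Missing observation
cells (e.g. dissolved O₂ measured only once a day in the light phase) are
skipped in the objective, never imputed.

Goodness of fit is reported per variable as the squared Pearson
correlation between observed and predicted series — scale- and
offset-invariant, and undefined (reported `NA`) when either series has zero
variance. A caution that the package's tests make explicit: when a
variable's true signal range is comparable to the noise (dissolved O₂
varies by only ~1% over the reference trajectory), no estimator can reach
high r² on it; at 2% noise the recovery criterion is parameter error, and
r² ≥ 0.95 across all six variables is only achievable in the small-noise
regime (≈0.2% in the tests).

## The factorial response surface

The 3² design crosses CO₂ at 0.03/10/20% with light at 13/39/65
µmol m⁻² s⁻¹, three replicates per treatment. `fit_quadratic()` fits the
full second-order polynomial by OLS in *natural* factor units — the
published reduced equations are printed in natural units, and coefficients
are then directly comparable — with coded −1..1 fitting available as an
option (`coded = TRUE`), which is also what the classical orthogonal
cell-mean ANOVA decomposition assumes.

`anova()` reports partial (Type III) sums of squares: each
single-degree-of-freedom term's SS is the increase in residual SS its
deletion would cause, computed as t²·MS_err from the OLS fit; the test
suite checks this identity against a literal delete-and-refit oracle. The
error term comes from replicate-level scatter, which is why the package
insists on replicate-level tables (and why the synthetic module can
reconstitute replicates from published cell means ± SD, matching each
cell's sample moments exactly).

`prune_terms()` applies the published selection rule: a *single pass* that
drops every term with p > α (default 0.05) from the full model and refits.
Hierarchy is deliberately not enforced — the published biomass model keeps
the A·B interaction while dropping A². Dropped terms keep coefficients of
exactly zero. No stepwise search, no lack-of-fit partitioning, no
central-composite designs: the scope is the 3² full factorial.

A replication note: the published ANOVA tables have error df 19 (biomass)
and 16 (lipid), i.e. 25 and 22 runs of the 27 entered those fits. From the
printed treatment means and SDs alone that exclusion cannot be
reconstructed, so replicates reconstituted from the printed summaries give
slightly different p-values (the biomass B² term, printed p = 0.031,
typically lands just above 0.05). The package reproduces the published
pruning decisions exactly when given the published p-values, and
approximately (majority of random seeds) from reconstituted or
truth-plus-noise synthetic data.

## Desirability optimization

`desirability_optimize()` implements Derringer–Suich for simultaneous
maximization: each response is scaled to
$d_i = \mathrm{clamp}\left(\frac{\hat y_i - low_i}{high_i - low_i},0,1\right)^{w_i}$
and combined as the geometric mean $D = (\prod d_i)^{1/k}$. Anchors
default to each model's predicted minimum and maximum over the factor box
(grid extrema refined by a bounded local polish, so that $d_i = 1$ is
attained exactly at the response's own maximizer); weights default to 1.
The search is a dense grid — steps of 0.05% CO₂ by 0.1 µmol m⁻² s⁻¹, with
the box endpoints always included — followed by an L-BFGS-B polish, and
the polished point is only accepted if it does not lose to the best grid
point. Grid ties break toward smaller CO₂, then smaller light.

Running the optimizer on the *published reduced equations* puts the joint
optimum at 20% CO₂ and ~13 µmol m⁻² s⁻¹ (the low-light box edge), with
predicted biomass ≈ 3.0 g/L. The published account instead reports an
optimum at (20%, 29.9 µmol m⁻² s⁻¹) with predicted biomass 2.01 g/L —
and evaluating the published biomass equation at that published optimum
gives ≈ 3.6 g/L, not 2.01. The printed equations, the printed optimum and
the printed predictions are mutually inconsistent (rounded coefficients or
a coded-units mix-up are plausible causes). The package takes no side: it
reproduces the printed equations as `reference_model()`, the printed
validation arithmetic as `reference_validation()` (2.01 g/L × 30.9% =
0.62 g/L of lipids; whole-percent errors 17, 6 and 13 via
`validation_error()`, which rounds half away from zero as printed tables
do), and documents the discrepancy rather than forcing agreement.

## Stoichiometry

The autotrophic growth equation
`CO2 + 0.93 H2O + 0.15 NO3- + 0.002 P -> CH1.71O0.4N0.15P0.002 + 1.42 O2 + 0.15 OH-`
is handled by a small reaction grammar (`parse_reaction()`): terms are
separated by spaced `+`, coefficients are optional, formulas allow
fractional subscripts, and a trailing sign is one unit of charge — so the
charge of `NO3-` is unambiguous. Phosphorus appears as a bare element
because that is how the equation is written; no oxidation state is
implied. `element_balance()` reports products-minus-reactants residuals
per element and for charge; as printed, the equation balances C, H, N, P
and charge to within 0.01 and carries a ~0.01 oxygen residual, consistent
with rounding the O₂ coefficient from 1.415 to 1.42 (whether the rounding
sits in the O₂ or the water coefficient cannot be determined from the
printed equation; solving the oxygen balance with `solve_coefficient()`
gives 1.415 exactly). There is no electron-balance bookkeeping and no
automatic balancing beyond one unknown.

## Synthetic data: what it does and does not show

No raw measurements are published for this system, so the package
generates its own, clearly labelled as synthetic in their metadata:

* `generate_timeseries()` — the ODE trajectory sampled daily (default days
  0–14, mirroring the daily measurement schedule) with per-variable noise:
  multiplicative Gaussian by default (2% is the package's standard
  "realistic assay" level, of the order of spectrophotometric and probe
  repeatability), always-additive noise for pH (a log-scale quantity), and
  optional per-variable missingness for sparsely logged sensors.
* `generate_factorial()` — full level crossing × replicates around known
  quadratic truth surfaces with Gaussian response noise; the pooled
  published treatment SDs (≈0.41 g/L biomass, ≈5.4% lipid) are the
  noise level used in the stability studies.
* `reconstitute_replicates()` — three pseudo-replicates per cell shifted
  and rescaled to match published cell means and SDs *exactly* (the ±
  values are taken to be standard deviations of triplicates; the source
  does not say SD vs SEM).

Passing tests on these data demonstrate internal consistency — the
estimators recover the truth that generated the data under the stated
noise — not agreement with the unpublished raw measurements. Real culture
data have features the generator deliberately omits: diel oscillations of
dissolved O₂ under the 12:12 photoperiod, autocorrelated sensor drift,
non-Gaussian outliers, and evaporation. The published trajectory-fit r²
values (0.974 biomass … 0.898 pH) depend on those raw data and are
therefore context, not targets.

## Problem sizes and determinism

The package's own verification runs at desk scale, chosen to exercise each
property well past its failure modes: the solver oracle at 14,000 RK4
steps; recovery studies on 15 observation times with 5 (default) or 3
multistarts; 1,000 null simulations for the ANOVA type-I error rate
(observed ≈0.055 at α = 0.05); 60-seed pruning-stability runs; and a
0.5-resolution exhaustive grid as the desirability oracle. Every
stochastic component takes an explicit integer seed, uses it through a
local RNG scope that restores the caller's RNG state, and is byte-stable
across runs with the same seed.

## Known limitations

No temperature dependence, evaporation, spatial light gradients or
radiative transfer; no carbonate speciation (pH is a linear surrogate); no
heterotrophic or mixotrophic metabolism; no photoinhibition term; local
(not global) optimization for parameter fitting; point estimates only, no
confidence intervals. The factorial machinery is specific to two factors
and a full quadratic; it is not a general RSM toolbox.
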