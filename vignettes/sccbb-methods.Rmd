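---
title: "Models and methods behind sccbb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sccbb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccbb)
```

`sccbb` covers the quantitative chain of a single-cell culturomics
workflow: plan a limiting dilution, screen the resulting plates, and then
optimize the yield of a selected producer strain with a sequential
design-of-experiments (DOE) campaign. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices where the
design was genuinely open.

## 1. The Poisson occupancy model

When a homogenized cell suspension is distributed over the wells of a
microplate, the number of cells per well is modelled as Poisson with mean
$\lambda$ (cells per well):

$$P(X = k) = \frac{\lambda^k}{k!} e^{-\lambda}, \qquad
  \lambda = \text{density (CFU/mL)} \times \text{well volume (mL)}.$$

The assumptions are independent, well-mixed cells: no clumping, no cell
death during plating, no interaction between cells. Aggregation-prone
samples violate this; the model presumes the upstream homogenization step
was effective, and `sccbb` makes no correction for clumping (no
most-probable-number multi-dilution machinery either — a single dilution
level is calibrated directly).

Everything of practical use comes from the $k = 0$ term:

* **Planning.** A target blank fraction $p_0$ fixes
  $\lambda = -\ln p_0$ and hence the density $\lambda / V$
  (`density_for_blank_fraction()`). For the canonical 384-well, 60 µL
  format and $p_0 = 0.243$, this gives 23.6 ≈ 24 CFU/mL. Note the
  mutual rounding: 24 CFU/mL back-transforms to
  $e^{-1.44} = 23.7\%$ blanks, not exactly 24.3%. The package treats the
  blank-fraction → density direction as canonical.
* **Calibration.** The observed blank count on a plate estimates
  $\hat\lambda = -\ln(n_\text{blank}/n_\text{wells})$
  (`calibrate_lambda()`). The confidence interval is the exact
  Clopper–Pearson binomial interval on the blank fraction transformed
  through $-\ln$; the exact interval was chosen because a single plate
  gives small counts where asymptotic intervals under-cover. A saturated
  plate (no blanks) leaves $\lambda$ unidentifiable and raises an error
  rather than reporting $\hat\lambda = \infty$.
* **Acceptance band.** The bench rule `dilution_acceptable()` accepts a
  plate whose blank fraction falls in 24–30%, inclusive at both ends and
  configurable. Inside this band most occupied wells received one or two
  cells.

**Purity.** For a community with relative abundances $p_i$, the
probability that an occupied well is monoclonal is

$$P(\text{pure} \mid X \ge 1)
  = \frac{\sum_{k \ge 1} P(X = k) \sum_i p_i^k}{1 - P(X = 0)},$$

implemented as a truncated series, stopping once the retained Poisson mass
exceeds $1 - 10^{-12}$ so the truncation error is explicitly bounded
(`purity_given_growth()`). The closed form
$\sum_i (e^{-\lambda(1 - p_i)} - e^{-\lambda})/(1 - e^{-\lambda})$ serves
as the independent cross-check in the tests. Purity decreases in
$\lambda$ and in community evenness; observed purity fractions cannot be
inverted to a unique $(\lambda, \text{profile})$ pair, so the simulator
demonstrates attainability of observed purity splits, not identity.

**Dilution series.** `plan_dilution_series()` decomposes the ratio
stock/target greedily, largest step first, each step at most `max_step`
(default 10×). Greedy coarse-then-fine matches bench serial-dilution
practice; the step products reproduce the ratio to $10^{-9}$ relative.
Volumes are taken in µL at the interface and converted to mL once,
internally; densities are always CFU/mL.

## 2. Plate screening and collection summaries

`call_growth()` thresholds blank-corrected OD600. No instrument-specific
cutoff is assumed; the default 0.1 is a conventional turbidity floor and
is a plain argument. The optical-distortion readout (the grid viewed
through the well, distorted by a surfactant-laden concave meniscus) enters
as a manual boolean per well — scoring is by eye, and no image processing
is attempted. The record validator enforces that a distortion call can
only sit on a turbid well.

`evenness()` reports Shannon $H = -\sum q_i \ln q_i$ (nats, via
`vegan::diversity()`) and Pielou $J = H / \ln S$; $J$ is defined as 0 for
a single-genus collection, where the normalisation would be 0/0.
`bin_similarity()` partitions 16S identities into
$(99, 100]$, $[98.65, 99]$ and $[0, 98.65)$ — the species threshold is
inclusive in the middle bin, matching the conventional "98.65–98.99%"
labelling of near-threshold isolates, and the bins are checked to be an
exhaustive partition.

## 3. The sequential DOE chain

### Plackett–Burman screening

`generate_pb12()` builds the standard cyclic 12-run design: eleven cyclic
shifts of the generator row $(+\,+\,-\,+\,+\,+\,-\,-\,-\,+\,-)$ plus an
all-minus run. Any balanced orthogonal 12-run construction yields
identical effect/se/t statistics, so the choice of generator is
statistically immaterial; the cyclic one is used because it is the
standard. With $k \le 11$ factors the remaining columns are simply unused
— residual degrees of freedom come from fitting intercept plus $k$ main
effects on 12 runs ($\mathrm{df} = 12 - k - 1$), not from dummy columns.
For a five-factor screen this gives df = 6, which is the only convention
that reproduces vendor-style screening tables' t→p pairs.

`fit_pb()` reports each factor's *effect* (mean response at high minus
mean at low, i.e. twice the coded regression coefficient) with the shared
standard error $2\sqrt{\mathrm{MSE}/12}$ that orthogonality guarantees.
`significant_factors()` applies a two-sided $\alpha$ (default 0.05) and
annotates effect signs. Carrying a non-significant factor into the ascent
(as is sometimes done for factors of known physiological relevance, e.g.
phosphate) is an explicit user choice, not an automatic rule.

### Steepest ascent

`build_ascent_path()` lays uniform natural-unit increments from a start
to an end point; the default usage spans each carried factor's screening
range in the direction of its effect sign. The published increments are
treated as user input — whether they derive from effect magnitudes or
simply span the screening ranges is not decidable from a run sheet, so
the module does not guess. `select_center()` takes the argmax of the
observed yields (first trial on ties — deterministic and conservative)
and warns when the maximum sits on the last trial, where the true optimum
may lie beyond the path.

### Box–Behnken response surface

`generate_bbd()` produces the 12 edge midpoints of the 3-factor cube plus
optional centre replicates. The centerless variant is supported
deliberately: it is what a corrected-total df of 11 implies, and it has a
structural quirk — every run satisfies $x_1^2 + x_2^2 + x_3^2 = 2$, so
the three quadratic columns are collinear with the intercept and the full
10-term quadratic model matrix has rank 9. `detect_aliasing()` finds this
by QR rank analysis and drops quadratic terms until the matrix is full
rank. Which quadratic to drop is arbitrary (any 9 of the 10 terms are
estimable); the default drops the *last declared factor's* quadratic,
because determinism is required and the convention matches tables where
the final factor's squared term carries 0 df. `prefer_drop` overrides it.
One centre point restores all 10 terms. Lack-of-fit testing is out of
scope: it needs replicated centre points the centerless design lacks.

`fit_quadratic()` is ordinary least squares on the coded terms.
`anova_partial()` computes partial (Type-III-style) sums of squares — the
SSE increase when each term alone is removed from the full model — so
per-term SS do not sum to the model SS, matching DOE-software ANOVA
tables; F statistics use the full-model residual mean square, and an
interpolating fit (0 residual df) raises an explicit error. The model R²
is reported from the package's own fit.

### Coding and the box optimum

Coded and natural units relate through $u = \text{centre} + x \cdot
\text{step}$. For the shipped L01 study the centres are the best ascent
trial's levels (2.5 g/L NaNO₃, 23.75 g/L PO₄³⁻, 126 h) and the steps are
the ascent increments (0.5, 1.25, 6): this is the unique coding under
which the fitted surface's maximizer decodes to the published optimal
medium, and it is the natural one — the follow-up design brackets the
best ascent trial by one ascent step.

`optimize_box()` maximizes the fitted quadratic over $[-1, 1]^k$
*exactly*, by face enumeration: each of the $3^k$ faces of the cube fixes
a subset of coordinates at ±1; on each face the stationary point of the
restricted quadratic is solved in closed form and kept if feasible, and
vertices are always candidates. No iterative ascent, no tolerance to
tune; a dense-grid oracle is retained in the tests only. Faces whose
restricted Hessian is singular — e.g. any face leaving free a factor that
enters only linearly, as cultivation time does in the L01 surface after
its quadratic was aliased out — have no interior stationary point and are
covered through their boundary sub-faces. Coordinates that land on ±1 are
flagged: the optimum may lie beyond the explored range, which for a
factor like time is exactly what the linear-in-time model implies.
Reported natural optima are rounded at step/10 resolution (one decimal
for the L01 factors); raw values are always retained in the returned
object.

## 4. Activity statistics

`flag_active()` uses the equal-variance (Student's) two-sample t-test,
two-tailed — not Welch, matching the classical triplicate-measurement
protocol — and gates the decision on direction: a sample is *active* only
if significant **and** its mean tension is below the control's. A
significant increase is not surfactant activity. Two identical replicate
sets have no variance to test against and report $p = 1$ rather than an
error. At least two replicates per group are required.

`estimate_cmc()` models tension vs $\log_{10}$(concentration) as a
continuous two-segment line — a decreasing limb with slope $s < 0$
joined at the breakpoint to a flat plateau — which is the classic shape
of a tension–concentration curve around the critical micelle
concentration. For each candidate breakpoint the two remaining
parameters are linear and solved in closed form; the breakpoint is chosen
by least squares over an exhaustive grid of 200 candidates between the
2nd and $(n-1)$th observed log-concentrations. A deterministic grid was
preferred over nonlinear optimization because segmented fits are
initialization-sensitive; the cost is a resolution floor equal to the
grid spacing, which the zero-noise tests bound. A curve whose best fit
has no decreasing limb is reported as an explicit "no CMC detected"
outcome, and a tension *rise* before the breakpoint larger than three
robust residual SDs triggers a warning. The estimate is equivariant under
rescaling all concentrations (the CMC scales by the same factor).

## 5. What the synthetic generators emulate — and what they do not

`simulate_plate()` draws Poisson($\lambda$) cells per well, assigns each
cell a strain from the abundance profile, and thins each cell by an
independent Bernoulli(`growth_prob`) "founds a culture" draw — so growth
thinning composes with seeding as Poisson thinning and the effective
intensity of grown cells is $\lambda' = \lambda \cdot p_\text{growth}$,
which is what purity checks must use. OD is a two-level signal (blank
baseline vs baseline + fixed growth signal), sufficient to exercise
growth calls but deliberately free of growth kinetics, plate-edge
effects, cross-feeding or condensation artefacts. Passing tests therefore
validate the bookkeeping and the occupancy arithmetic, not any claim
about real plates' optics or biology.

`simulate_responses()` adds iid Gaussian noise to a known quadratic
surface evaluated at the design runs: correct for exercising the OLS
machinery, but real fermentation errors can be heteroscedastic and
run-order correlated, which the ANOVA here does not model.
`simulate_tension_curve()` generates the ideal two-segment shape plus
noise on log-spaced concentrations; real curves can show a pre-CMC
shoulder or a slowly drifting plateau that the two-segment model absorbs
into residual error.

All generators take an explicit seed, use a single global RNG stream, and
record their configuration (seed included) in the returned object, so
every simulation in the tests is bit-reproducible.

## 6. Problem sizes and numerical choices

The validation suite runs the occupancy/purity Monte-Carlo at $10^6$
wells per $\lambda \in \{0.5, 1.44, 3\}$ (three binomial standard errors
as the agreement band), 500 replicate noisy response-surface fits for the
SS-decomposition and unbiasedness checks, and 200 replicate noisy tension
curves (σ = 0.5 mN/m, the scale of triplicate tensiometer scatter) for
median CMC recovery within 10%. Noise for the response-surface
simulations defaults to σ = 0.07 g/L in the tests, the scale implied by a
residual mean square of ≈0.005 on a 3-df residual. Numerical guards worth
knowing: Poisson series truncation at $1 - 10^{-12}$ retained mass;
an exact-fit guard in `fit_pb()` that zeroes rounding residue so constant
responses report $p = 1$; rank decisions via QR; and the box optimizer's
1e−9 feasibility slack for stationary points on face boundaries.

## 7. Known limitations

* The occupancy model ignores clumping and death; it calibrates a single
  dilution level rather than estimating density from a dilution ladder.
* Distortion scoring is manual by design; no optics are modelled.
* Only the 3-factor Box–Behnken geometry is generated (with any number of
  centre points); central-composite designs and multi-response
  desirability optimization are out of scope.
* The CMC breakpoint resolution is bounded by the candidate grid; curves
  flat to within noise are reported as "no CMC detected" rather than
  extrapolated.
* Published screening/ANOVA tables can only be checked for internal
  consistency (t→p, F→p, effect/se structure) when the underlying run
  responses are not available; the package never guesses unpublished
  responses.
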