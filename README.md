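# sccbb

Computational support for single-cell-based high-throughput cultivation and
functional screening of biosurfactant-producing bacteria, and for the
sequential design-of-experiments (DOE) optimization of biosurfactant yield
that follows once a producer strain is in hand.

The package is written for microbiologists running limiting-dilution
culturomics in microplates and for anyone optimizing a fermentation medium
with the classic screening → ascent → response-surface workflow.

## What it computes

**Limiting-dilution planning.** Cells deposited in microplate wells by
limiting dilution follow a Poisson law, P(X = k) = λᵏ e^(−λ)/k!, with λ the
mean number of cells per well. The blank-well fraction of an incubated plate
estimates e^(−λ), which drives everything: choosing a cell density for a
target blank fraction (`density_for_blank_fraction()`), planning the serial
dilution to reach it (`plan_dilution_series()`), recalibrating λ from an
observed plate with an exact Clopper–Pearson interval (`calibrate_lambda()`),
and predicting the fraction of occupied wells that hold a pure culture for a
given community profile (`purity_given_growth()`).

**Screen bookkeeping.** OD600 growth calls against a blank reference
(`call_growth()`), plate summaries feeding the calibration
(`summarize_screen()`), Shannon/Pielou evenness of isolate collections
(`evenness()`), and binning of 16S similarities around the 98.65% species
threshold (`bin_similarity()`).

**Sequential DOE.** The 12-run Plackett–Burman screen with main-effect
t-tests (`generate_pb12()`, `fit_pb()`), steepest-ascent paths
(`build_ascent_path()`, `select_center()`), the 3-factor Box–Behnken design
including its centerless variant whose three quadratic columns are collinear
with the intercept (`generate_bbd()`, `detect_aliasing()`), quadratic
fitting (`fit_quadratic()`), partial-sum-of-squares ANOVA
(`anova_partial()`), and exact maximization of the fitted surface
Y = b₀ + Σbᵢxᵢ + Σbᵢⱼxᵢxⱼ + Σbᵢᵢxᵢ² over the coded cube [−1, 1]ᵏ by face
enumeration (`optimize_box()`).

**Activity statistics.** Surfactant-activity calls from replicate surface
tensions by one-directional Student's t-test (`flag_active()`) and critical
micelle concentration (CMC) estimation by a continuous two-segment fit in
log concentration — a decreasing limb joined to a flat plateau
(`estimate_cmc()`).

**Synthetic data.** `simulate_plate()`, `simulate_responses()` and
`simulate_tension_curve()` generate every input the pipeline assumes, with
explicit seeds, so each stage is testable end to end.

The `l01_*` functions ship the worked glycolipid-yield optimization for
*Pseudomonas* sp. L01 (screening table, ascent run sheet, fitted quadratic
yield surface and its ANOVA) used throughout examples and tests.

## Worked example

```r
library(sccbb)

# Plan single-cell seeding of a 384-well plate at a 24.3% blank target
density_for_blank_fraction(0.243, plate_spec(384, 60))
#> [1] 23.57823            # CFU/mL; bench practice rounds to 24

plan_dilution_series(2.4e6, 24, plate = plate_spec(384, 60))
#> <seeding_plan>
#>   stock:  2.4e+06 CFU/mL
#>   target: 24 CFU/mL
#>   steps:   10x -> 10x -> 10x -> 10x -> 10x
#>   lambda = 1.44 cells/well, expected blanks = 23.7%

# After incubation, recalibrate lambda from the observed blanks
calibrate_lambda(96, 384)
#> <occupancy_model> lambda = 1.386 (blank fraction 0.25)
#>   95% CI: [1.216, 1.573]

# Optimize the L01 glycolipid yield surface over the coded design cube
m <- l01_yield_model()
predict(m, c(0, 0, 0))
#> [1] 8.21                # g/L at the design centre
optimize_box(m)
#> <box_optimum>
#>   coded:   NaNO3 = -0.1902, PO4 = -0.3852, time = 1*
#>   natural: NaNO3 = 2.40489, PO4 = 23.2685, time = 132
#>   predicted response: 8.30594
#>   (* at box boundary: the optimum may lie beyond the design range)
```

The optimum says: 2.4 g/L NaNO₃, 23.3 g/L PO₄³⁻ and 132 h of cultivation,
for a predicted crude-glycolipid yield of ≈8.31 g/L; time sits on the design
boundary because the fitted surface is linear in time (its quadratic term is
aliased on the centerless design).

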