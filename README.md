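# chitopt

Response-surface modelling and Pareto optimization of the alkaline
deacetylation of chitin to chitosan.

Chitosan from crustacean waste is characterized by two properties that
pull against each other: the **degree of deacetylation** (DD, % of
glucosamine units — as high as possible) and the **viscometric molar
mass** (MM, kDa — high *or* low depending on the application). Both are
controlled by the same deacetylation conditions: NaOH concentration
(x₁), liquid:solid ratio (x₂) and duration (x₃). `chitopt` implements
the full optimization workflow for this trade-off:

* **Design of experiments** — rotatable central composite designs in
  coded factors (`ccd_design()`), with the exact coded⇄real linear map
  (`code_levels()`, `decode_levels()`).
* **Characterization** — the closed-form response conversions:
  potentiometric titration `Q = C_M·ΔV/m` and
  `DD% = 100·203·Q/(1 + 42·Q)`; the Mark–Houwink–Sakurada inversion
  `M_v = ([η]/K)^(1/a)` (K = 13.8·10⁻³ mL/g, a = 0.85); mass yield
  (`characterize()`).
* **Response-surface models** — OLS fits of the full second-order
  polynomial `y = b₀ + Σbᵢxᵢ + Σbᵢⱼxᵢxⱼ + Σbᵢᵢxᵢ²` with coefficient
  t-tests, R² and the overall F-test (`fit_response_surface()`,
  `tidy()`, `glance()`), judgment-based term reduction (`reduce_fit()`,
  `prune_terms()`).
* **Optimization** — exact stationary-point maximization of a fitted
  quadratic over the coded box (`maximize_quadratic()`), a
  deterministic full-lattice Pareto oracle (`grid_front()`), and a
  real-coded NSGA-II with nondominated archive (`nsga2()`), reported as
  operating-condition tables (`front_report()`) or plots (`autoplot()`).
* **Synthetic data** — `simulate_responses()` draws CCD tables from
  known quadratic surfaces plus Gaussian noise so the whole pipeline is
  testable end to end; `recovery_experiment()` checks coefficient bias
  and confidence-interval coverage by Monte Carlo.

The 17-run shrimp-waste deacetylation experiment ships as a packaged
dataset (`shrimp_ccd()`), and `run_reproduction()` recomputes every
published quantity from it in one call.

## Worked example

```r
library(chitopt)

tbl <- shrimp_ccd()                         # 17 coded runs + DD, MM, yield
fit_mm <- fit_response_surface(tbl, "mm_kda")
glance(fit_mm)
#>   r.squared adj.r.squared sigma statistic p.value    df df.residual  nobs
#> 1     0.945         0.873  107.      13.3 0.00128     9           7    17
```

The full molar-mass model explains 94.5% of the response variance and is
significant (F-test p = 0.0013). Dropping the three terms whose
coefficients are indistinguishable from zero (the x₂ linear and its
interactions — all orthogonal to the retained terms, so nothing else
moves) gives the reduced model:

```r
mm_red <- reduce_fit(fit_mm, mm_reduced_terms())
tidy(mm_red)
#>   term  estimate std.error statistic     p.value
#> 1 1        762.       56.9     13.4  0.000000103
#> 2 x1       230.       26.7      8.60 0.00000621
#> 3 x3        41.5      26.7      1.55 0.152
#> 4 x1:x3     78.3      34.9      2.24 0.0486
#> 5 x1^2    -146.       29.4     -4.96 0.000567
#> 6 x2^2    -103.       29.4     -3.50 0.00569
#> 7 x3^2    -203.       29.4     -6.89 0.0000424

opt <- maximize_quadratic(as_quadratic_model(mm_red))
opt$par                                     #  x1 0.8583  x2 0  x3 0.2680
opt$value                                   #  865.73 kDa
decode_levels(tibble::as_tibble(as.list(opt$par)))
#>      x1    x2    x3 naoh_pct ratio duration_min
#> 1 0.858     0 0.268     53.6    18         128.
```

The molar mass peaks at 865.7 kDa for 53.6% NaOH, ratio 18 and a 128-min
deacetylation. DD and MM cannot be maximized at the same point, so the
trade-off is a Pareto front:

```r
models <- list(dd_reduced_model(), mm_reduced_model())
front <- nsga2(models, senses = c("max", "max"), seed = 1)
head(front_report(front), 1)
#>      x1    x2    x3 naoh_pct ratio duration_min dd_pct mm_kda
#> 1 0.668 -1.68 0.478     51.7  9.60         134.   101.   557.
autoplot(front)
```

Each report row is one nondominated compromise: moving along the front
trades deacetylation degree against molar mass. The deterministic
lattice oracle `grid_front(models, c("max", "max"))` gives the reference
front the genetic algorithm is validated against; `run_reproduction()`
runs everything (both responses, both trade-off problems, both methods)
and writes models, ANOVA tables and front CSVs.

## Vignette

`vignettes/chitosan-deacetylation-optimization.Rmd` documents the
models, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations.
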