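---
title: "Response-surface modelling and Pareto optimization of chitosan deacetylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface modelling and Pareto optimization of chitosan deacetylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitopt)
```

## The problem

Chitosan is produced by alkaline deacetylation of chitin, here extracted
from shrimp-waste exoskeletons. Two properties decide what a chitosan
batch is good for: the **degree of deacetylation** (DD, the percentage of
glucosamine units; high-DD chitosan is > 70%) and the **viscometric
molar mass** (MM, in kDa; "high" above 700 kDa, "low" 50–150 kDa). Both
are driven by the same three operating parameters of the deacetylation
step — NaOH concentration, liquid:solid ratio and process duration — but
in conflicting directions: conditions that push DD up tend to
depolymerize the chains and pull MM down. Choosing operating conditions
is therefore a genuine multiobjective problem, and this package
implements the complete workflow: a designed experiment, quadratic
response-surface models for DD and MM, and Pareto optimization of the
two fitted surfaces.

## The designed experiment

The design is a rotatable central composite design (CCD) in coded
variables: a $2^3$ factorial block at coded $\pm 1$, one axial pair per
factor at $\pm\alpha$, and three replicated center runs — 17 runs for
$k = 3$. Coded and real values are linked by the exact linear map
$x_i = (\text{real} - \text{center}_i)/\text{step}_i$ with centers
(45%, 18, 120 min) and steps (10%, 5, 30 min).

Two presentation details of the source tables are worth making explicit:

* The axial magnitude is taken as exactly **1.68**, as printed alongside
  the data, rather than the exact rotatable value $2^{3/4} = 1.6818$.
  All coefficient targets are quoted to ~0.5%, which absorbs the
  difference.
* The real-valued axial labels (28, 62, 9.5, 26.5, 70, 170) are rounded
  presentations of the linear map (which gives 28.2, 61.8, 9.6, 26.4,
  69.6, 170.4); `decode_levels()` is authoritative and matches the
  labels to within one printing unit. One published decode is internally
  inconsistent: the optimum $x_1 = 0.8583$ is quoted as NaOH = 53.28%,
  while the linear map gives $45 + 8.583 = 53.58\%$. We follow the
  linear map.

## Response variables

The characterization conversions are closed forms:

* Potentiometric titration: $Q = C_M \Delta V / m$ (mol amino groups per
  g), and $\mathrm{DD}\% = 100 \cdot 203\,Q/(1 + 42\,Q)$, where
  203 g/mol is the chitin monomer and 42 g/mol the acetyl group. The
  printed form of this equation is ambiguous about the $\times 100$
  factor; we fix it dimensionally — typical $Q \approx 0.004$ mol/g then
  gives DD in the observed 60–97% range. DD saturates at
  $100 \cdot 203/42 \approx 483\%$ mathematically, so values above 100%
  are physically impossible measurement artifacts: they are **flagged
  with a warning, never silently capped**.
* Viscometry: the Mark–Houwink–Sakurada equation $[\eta] = K M_v^a$
  inverted as $M_v = ([\eta]/K)^{1/a}$ with $K = 13.8\times10^{-3}$ mL/g
  and $a = 0.85$ for chitosan in the standard acetate buffer. The
  inverse is algebraically exact (round-trips at $10^{-10}$ relative).
  MM is carried in kDa ($M_v/1000$) throughout.
* Yield: extracted chitosan over extracted chitin, in percent.

## Model fitting and reduction

Each response is fitted by ordinary least squares to the full
ten-term second-order polynomial in the coded factors
$y = b_0 + \sum b_i x_i + \sum b_{ij} x_i x_j + \sum b_{ii} x_i^2$.
Standard errors come from the residual variance and the inverse
normal-equations diagonal, coefficient p-values from two-sided t-tests
on $n - p = 7$ residual degrees of freedom, and the model F-test
compares regression to residual mean squares on $(9, 7)$ degrees of
freedom (the simultaneous, overall-regression decomposition — this
reproduces the published p-values 0.0052 and 0.0012 from
$R^2 = 0.91/0.94$). Replicated center points are treated as ordinary
runs; a pure-error/lack-of-fit split is available separately through
`lack_of_fit()` as a diagnostic.

Model reduction is deliberately **judgment-based, not automated**: the
published reduced models are reproduced with explicit keep-lists
(`dd_reduced_terms()`, `mm_reduced_terms()`), because the DD model
retains the weakly significant liquid:solid linear term ($p = 0.41$) so
the factor keeps some influence on predictions. `prune_terms()` offers
p-value screening with protected terms, but only as an advisory input to
`reduce_fit()`. On a CCD the linear and interaction columns are mutually
orthogonal and orthogonal to the quadratics, so dropping only
linear/interaction terms (the MM reduction) leaves every retained
estimate unchanged — a property the tests assert both on the packaged
data and on synthetic refits.

## Optimization

**Single objective.** A quadratic has a closed-form stationary point:
writing the model as $c_0 + b^\top x + x^\top A x$, the gradient is
$b + 2Ax$ and `maximize_quadratic()` solves $2Ax = -b$ directly. If the
Hessian is negative definite and the solution lies inside the coded box,
that interior maximum is exact; otherwise (saddles, convex directions,
exterior stationary points, or a singular Hessian, which warns) the box
is searched on a 51-per-axis lattice and polished with L-BFGS-B. For the
reduced MM model the interior route applies and lands on
$x = (0.8583, 0, 0.268)$, 865.7 kDa.

**Feasible region.** The box $[-1.68, 1.68]^3$, not the rotatable
sphere: the published trade-off selections reach $x_2 = -1.68$ and
$x_3 = 1.67$, which only the cube contains.

**Pareto fronts.** Two routes, deliberately independent:

* `grid_front()` evaluates both objectives on a full lattice
  (201 points per axis, ~8.1 million points, by default) and keeps the
  nondominated set using an $O(n \log n)$ sweep (two objectives) that is
  itself tested against a brute-force $O(n^2)$ oracle built on
  `dominates()`. Deterministic, exact to lattice resolution — the
  reference the genetic algorithm is judged against.
* `nsga2()` is a real-coded NSGA-II: fast nondominated sorting,
  crowding-distance diversity with infinite crowding at the boundaries,
  binary tournament on (rank, crowding), bound-aware simulated-binary
  crossover and bound-aware polynomial mutation with a final clip.
  Minimization is a sign flip internally; reports are in natural units.
  Defaults follow common practice where the source states only the
  population size: population 100, 200 generations, crossover
  probability 0.9 with distribution index 15, per-gene mutation
  probability $1/k$ with index 20, and an explicit seed (runs are
  reproducible and restore the caller's RNG state).

`nsga2()` additionally keeps an **external archive** of every
nondominated solution evaluated during the run and returns the archive's
nondominated set (disable with `nsga2_control(archive = FALSE)` to get
the classical final-population rank-0 set). The archive matters here:
the max-DD/min-MM front has two branches that cross in objective space,
and a 100-member population retains a few stragglers near the crossing
that are dominated by points the run itself evaluated. With the archive,
the max-DD/max-MM front sits within 0.5% of each objective's range of
the 201-per-axis grid oracle across seeds, and no lattice point improves
on any returned solution by more than 0.05 DD points and 1 kDa
simultaneously.

## What the optimization reproduces

Running `run_reproduction()` recomputes, from the packaged table alone:
the full ANOVA tables for both responses; the reduced models; the
interior MM maximum; both Pareto fronts by GA and by grid; and a
pass/fail comparison against the published values. The two published
trade-off regions emerge as expected: DD of 97.5–98.5% is attainable
together with MM above 840 kDa (NaOH just above 50%, duration around
128 min, ratio near the center), while MM below 200 kDa coexists with DD
up to about 97.5% (NaOH just under 50%, ratio at the low axial bound,
durations around 165 min). The published selected rows from both fronts
evaluate back to their printed objective values through the reduced
models and are nondominated, within evaluation tolerance, against the
recomputed fronts.

## The synthetic-data generator

`simulate_responses()` emulates the data-generating process the
experiment is assumed to follow: a known quadratic surface per response
evaluated on the CCD plus i.i.d. homoscedastic Gaussian noise. The
defaults are the study conditions — the fitted reduced DD and MM
surfaces as truth, the 17-run design, and noise standard deviations
calibrated to the residual scatter of the corresponding fits
(8.6 DD-percentage points and 107 kDa). Three center replicates are far
too few to support a richer error model; the center-replicate spread in
the packaged data (MM 670–820 kDa) hints at larger-than-average error
near the center, which is noted but not modelled. Simulated DD values
outside [0, 100] are flagged, not truncated, so fits see exactly
surface-plus-noise.

`recovery_experiment()` closes the loop: repeated simulate–refit cycles
confirm zero bias without noise, near-unbiasedness under noise, and
~95% empirical coverage of the nominal t-intervals (500 replicates in
the test suite, a Monte-Carlo precision of about ±1 percentage point of
coverage).

What passing these tests shows is that the *pipeline machinery* is
calibrated; it does not validate the quadratic-surface assumption or the
noise model against real deacetylation chemistry, which only new
experiments could.

## Numerical choices and problem sizes

* Fits use the QR decomposition; the normal-equations solution is kept
  as an independent oracle in the tests (agreement to $10^{-8}$
  relative).
* Rank-deficient model matrices are rejected with the collinear terms
  named, never silently pivoted away.
* The grid oracle defaults to 201 points per axis (cap `max_points = 2e7`); the dominance sweep handles ~8 million
  points in seconds. Test-suite property checks use 21–101 points per
  axis and 150–500-point random sets against the $O(n^2)$ oracle; the
  full 201-per-axis comparison runs in the acceptance checks.
* Crowding-distance ties at front boundaries get infinite crowding, so
  extreme solutions are always retained.

## Known limitations

* The fitted surfaces are quadratics on coded $[-1.68, 1.68]^3$ and
  extrapolate poorly: the DD model exceeds 100% near some box corners
  and the MM model goes negative in others. Fronts computed from the
  models inherit this; the physically meaningful region is the
  neighborhood of the design.
* On the max-DD/min-MM problem the front is disconnected (a narrow
  branch at short durations and high NaOH), and a population of 100
  misses that branch in some seeds even with the archive; the
  max-DD/max-MM results are robust across seeds. The grid oracle covers
  both problems deterministically and is the recommended cross-check.
* Yield is carried through the pipeline as data but never modelled, and
  no inflection-point detection from raw titration curves is provided —
  only the volume difference between the two inflection points is
  consumed.
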