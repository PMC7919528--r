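---
title: "Quantifying plasmid acquisition costs: models and methods"
author: "acquicost maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasmid acquisition costs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acquicost)
```

## The problem

When a bacterium receives a conjugative plasmid it must immediately
replicate the new DNA, express its maintenance and (often) conjugation
machinery, and re-balance its metabolism. The result is a *transient*
growth defect in newly formed ("de novo") transconjugants — slower maximum
growth and/or a longer lag — that disappears within roughly a day as the
lineage adapts. This **acquisition cost** is distinct from the familiar
long-term **fitness cost** of carriage, and it is invisible to standard
fitness assays, which use established transconjugant clones. `acquicost`
implements the full quantitative workflow for measuring acquisition costs
from plate-reader data and for propagating them into population dynamics.

## Growth-curve estimation

All fits operate on the log fold-change
$y(t) = \ln(\mathrm{OD}'(t) / \overline{\mathrm{OD}'(0)})$ of the
background-subtracted signal (mean of the first three readings as the
reference, detection floor $10^{-3}$ OD), which makes estimates invariant
to the OD-to-cell-density conversion. Four estimators are provided:

* **Baranyi–Roberts** (`fitGrowthCurve(..., "baranyi")`):
  $y = y_0 + \mu A(t) - \ln\!\big(1 + (e^{\mu A(t)}-1)/e^{C}\big)$ with the
  lag adjustment
  $A(t) = t + \tfrac{1}{\mu}\ln(e^{-\mu t} + e^{-\mu\lambda} -
  e^{-\mu(t+\lambda)})$.
* **Modified Gompertz** and **modified Logistic** (Zwietering forms, inner
  constants $+1$ and $+2$ respectively).
* **Numerical-derivative ("max-slope") method**: smooth $y$ with a 5-sample
  centred moving average, find the maximum discrete derivative inside the
  exponential region (10–90 % of the maximum of $y$; earliest index on
  ties), and take the secant slope through the samples two steps above and
  below that point. The **geometric lag** is the x-intercept of the
  tangent at the maximum-rate point, clamped at zero.

### Weighting

Plate-reader noise is (to good approximation) additive in OD, so after the
log transform its variance is $\sigma^2/\mathrm{OD}^2$ — enormous for
low-density points. Unweighted least squares in $y$ is therefore dominated
by the noisiest part of the curve. Parametric fits use inverse-variance
weights with a 10 % relative-error floor,
$w_i = 1/(0.1^2 + (\hat\sigma/\mathrm{OD}_i)^2)$, where $\hat\sigma$ is
estimated from the median absolute first difference of the OD series. For
noiseless input the weights collapse to uniform. Optimization is bounded
Levenberg–Marquardt (tolerances $10^{-10}$, 500 iterations) started from
the derivative-method estimates, with three deterministically jittered
restarts; a flat curve yields `converged = FALSE` rather than an error.

### What recovery can and cannot achieve

Two structural facts shape the attainable accuracy, and we state them
explicitly because they bound what any pipeline of this design can do:

1. **Estimator–model mismatch.** The Gompertz and Logistic sigmoids are
   not consistent estimators of Baranyi parameters. Fitted to
   Baranyi-shaped data they misjudge the sharpness of the lag exit and the
   approach to stationary phase; across realistic designs we measure
   median rate errors of roughly 2–10 % and *lag* errors of 20–40 % for
   these two forms, at any amplitude. The Baranyi fit itself recovers
   $\mu$ to well under 1 % and $\lambda$ to about 7 % (median) at
   $\sigma_{od} = 0.005$.
2. **The derivative method is bounded by the curve's maximum local
   slope**, which for log-amplitude $A$ is approximately
   $(1 - 2e^{-A/2})\,\mu < \mu$ because the lag-exit and saturation
   transitions overlap. With the observable amplitude capped at
   $A = \ln(\mathrm{OD}_{sat}/\mathrm{OD}_{floor}) \approx 4.5\!-\!5.5$ by
   instrument physics, the method under-reads $\mu$ by 10–16 %. This is a
   property of the estimator class, not of the implementation; all four
   methods nevertheless rank conditions identically (the qualitative
   consistency that matters for cost comparisons).

The recovery benchmark uses curves whose whole time course is observable
(initial OD 0.02 — four noise SDs above background — rising to a dense
stationary OD of 2). Plate experiments that *start* below the detection
limit (e.g. a 2,000-cell inoculum is about $10^{-6}$ OD) cannot reveal the
generating lag from OD data at all; that is precisely why the
time-to-threshold metric below, and not curve fitting, is the primary
quantification of the acquisition cost.

## The time-to-threshold standard curve

During exponential growth $\ln T(t) = \ln T_0 + \mu (t - \lambda)$, so the
first time $t^*$ at which a culture reaches a fixed threshold density
$T^*$ is linear in $\ln T_0$ with slope $-1/\mu$ — regardless of how much
of the early curve is below detection. The workflow
(`acquisitionCostFromPlate()`):

1. Set $T^*$ to 50 % of the maximum background-subtracted OD across the
   experiment (one threshold per experiment, keeping every crossing inside
   the shared exponential phase).
2. Measure $t^*$ per well; a crossing must be sustained for two
   consecutive samples (noise guard) and is linearly interpolated between
   the bracketing samples.
3. Regress $t^*$ on $\ln T_0$ over an adapted-transconjugant dilution
   series (default: seven 10-fold dilutions, technical triplicates). The
   regression direction puts the noisy measurement on the left-hand side;
   prediction inverts the line.
4. For each de novo well, predict the apparent inoculum
   $T_{pred} = \exp((t^* - b)/m)$ and form the cost ratio
   $\overline{T_{pred}} / \overline{T_0}$ against the CFU-verified truth.
   A pure extra lag $\Delta\lambda$ yields
   $T_{pred}/T_0 = e^{-\mu\Delta\lambda}$; a rate deficit compounds with
   time to threshold, so the ratio responds monotonically to both effect
   axes.
5. Test $H_1\!: T_{pred} < T_0$ with a one-tailed Welch $t$-test on
   $\log_{10}$ densities. Replicates are treated as biological: the
   synthetic generator draws each well's true inoculum from a 10 % CV
   lognormal around the nominal value (recorded exactly in the metadata,
   as CFU verification would). With literally identical inocula the
   two-sample test degenerates into a one-sample test against a constant
   whose independence assumptions the shared standard curve violates
   (measured false-positive rates of 8–10 % at a nominal 5 %); with
   replicate variability the unpaired test is conservative, which is the
   safe direction for claiming costs.

Wells that never cross the threshold are excluded with a warning (and the
experiment lengthened: slow-growth cases at 2,000 cells/well need ~26 h to
cross, so those runs sample 36 h, consistent with reading "at least 24 h
until stationary phase").

The `normalizedLag()` helper implements the lag comparison convention of
multiplying each lag by its well's true inoculum and dividing by the mean
adapted lag. The resulting quantity has units of h·CFU per h — not a pure
number; we implement the convention as used for cross-condition
comparisons and flag that interpretation of its units is up to the caller.

## The three-population conjugation model

Densities are normalized to a common carrying capacity. Plasmid-free cells
$S^0$ grow at $\alpha\mu$ ($\alpha > 1$: the plasmid is costly to carry),
de novo transconjugants $S^D$ at $\rho\mu$ ($\rho \in [0,1]$), adapted
transconjugants $S^A$ at $\mu$:

$$\dot S^0 = \alpha\mu S^0 F - \eta S^0 S^A + \kappa S^A - D S^0$$
$$\dot S^D = \rho\mu S^D F + \eta S^0 S^A - \beta S^D - D S^D$$
$$\dot S^A = \mu S^A F + \beta S^D - \kappa S^A - D S^A$$

with $F = 1 - S^0 - S^D - S^A$. Conjugation ($\eta$) converts plasmid-free
cells into de novo transconjugants, which mature into adapted cells at the
transition rate $\beta$; segregation ($\kappa$) returns adapted cells to
the plasmid-free pool; $D$ is continuous dilution. The de novo pool
neither conjugates nor segregates by default (its machinery expression is
transient); `deNovoConjugates = TRUE` enables the robustness variant in
which it donates too. Note the segregation term is a *loss* from $S^A$
balancing the gain in the $S^0$ equation, so the exchange terms move mass
without creating it — a property the tests verify directly. As
$\beta \to \infty$ the model collapses to the classical two-population
model (`simulateOriginalModel()`), and the tests check the sup-norm error
in $S^1 = S^D + S^A$ decreases through $\beta = 10, 10^2, 10^3$.

The observable growth rate of the combined transconjugant pool is the
abundance-weighted mean
$\mu_{obs}(t) = (S^D \rho\mu + S^A \mu)/(S^D + S^A)$, bounded in
$[\rho\mu, \mu]$.

Integration uses `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`; tiny
negative excursions are clipped to zero after the fact. Serial transfer
(`serialTransfer()`) integrates 24-h batches from a 1:1 plasmid-free :
adapted mix at a starting total of $10^{-4}$ of capacity (a saturated
culture after one 10,000-fold dilution), records the plasmid fraction at
each batch end, then divides the state by the transfer dilution.

## Steady states, segregation, and the boundary map

`steadyStateGrowthRate()` integrates under continuous dilution until the
state moves less than $10^{-9}$ over 10 h (horizon 5,000 h) and evaluates
$\mu_{obs}$ at the endpoint; a transconjugant pool below $10^{-8}$ is
reported as extinct. A genuinely nontrivial steady state needs two things:
turnover ($D > 0$), and a *sustained* plasmid-free subpopulation —
otherwise conjugation stops producing de novo cells, $S^D$ drains through
$\beta + D$, and $\mu_{obs} \to \mu$ for every parameter combination. With
$\kappa = 0$ the long-run outcome is always one of plasmid washout or
plasmid-free washout, making the $\mu_{obs}/\mu$ landscape trivially
flat. The boundary map therefore uses a small segregation rate
($\kappa = 0.005\,h^{-1}$, with $D = 0.1\,h^{-1}$) in its default base
parameters: segregants regenerate $S^0$ at a level $\sim\kappa/\eta$, and
the steady state carries a standing de novo fraction
$S^D/S^1 \approx \eta S^0/(\beta + D)$.

`boundaryMap()` classifies each cell of a 25×25 grid
($\alpha \in [0.8, 1.5]$, $\beta$ log-spaced in $[10^{-4}, 1]$) by whether
$\mu_{obs}/\mu$ falls below a threshold (default 0.98; extinct cells are
excluded). The below-threshold region is empty when conjugation is
negligible ($\eta = 10^{-6}$), grows with the fitness cost $\alpha$, and
its *size* grows from $\eta = 0.1$ to $\eta = 1$; per-cell, however,
$\mu_{obs}/\mu$ is not monotone in $\eta$ — near the contour, raising
$\eta$ can lift the ratio as the plasmid-free pool collapses toward its
$\kappa$-sustained level — so strict set inclusion holds only away from a
thin boundary band. `thresholdSensitivity()` re-classifies one ratio
surface at several thresholds (nested by construction of the definition;
verified numerically) and reports Jaccard overlaps.

## Fitting the transition rate

`fitTransitionRate()` minimizes the sum of squared residuals between the
model's $S^1(t)$ — simulated from 100 % de novo cells at the observed
inoculum — and an observed outgrowth series, using Nelder–Mead simplex
search on $\log\beta$ (optionally with $\mathrm{logit}\,\rho$), three
perturbed starts, best kept. Residuals are computed on the linear density
scale by default (`logResiduals = TRUE` switches). Following the original
protocol, the initial $\beta$ guess is the geometric lag time of the
observed curve — a deliberate unit mismatch (h used as 1/h) that we keep
as the documented convention and expose via `initBeta`. Recovery on
synthetic data is essentially exact noiselessly (&lt;0.1 % for
$\beta \in \{0.01, 0.1, 1\}$) and within a few percent at
$\sigma = 0.003$ observation noise; when data are generated with fast
transition ($\beta \gtrsim 10$), any sufficiently large $\beta$ is
observationally equivalent and the fit reports a value at or near the fast
end with a near-zero objective, which is the correct reading of a
no-acquisition-cost plasmid. `predictedGrowthSummary()` closes the loop:
it simulates the fitted dynamics and re-derives the growth rate and
geometric lag an experimenter would measure from $\ln S^1$.

## The synthetic-data generator

`simulateGrowthCurve()` produces
$\mathrm{OD}(t) = c\,e^{y(t)} + \mathrm{blank} + \varepsilon$ with $y$ the
Baranyi solution, $c$ the OD-per-density conversion (default $10^{-9}$ OD
per CFU-per-well equivalent; the standard-curve method is invariant to
it), blank offset 0.04 OD and i.i.d. Gaussian noise (default
$\sigma = 0.003$ OD). Sampling is every 15 min for 24 h (97 points) unless
stated. Dilution series shift $y_0$ by $-\ln(\mathrm{factor})$ while
holding $\mu$, $\lambda$ and the saturation density fixed (wells share one
carrying capacity). De novo wells scale $\mu$ and add lag; their
per-replicate inocula can carry a lognormal biological CV. CFU counts are
Poisson draws for a 10 µl spot. One seed per generator call;
per-well noise streams use the documented derivation
$\mathrm{seed} + 7919\,i \bmod (2^{31}-1)$, so a well's noise does not
depend on plate composition, and equal seeds give bit-identical plates.

What the generator deliberately does **not** emulate: multiplicative or
drift noise, evaporation and edge effects, instrument nonlinearity at
high OD, background conjugation inside wells, diauxic shifts, and
well-to-well kinetic heterogeneity beyond the modeled inoculum CV. Tests
passing on these synthetics therefore certify the *method pipeline* — not
robustness to every artifact of real plates.

## Problem sizes and numerical choices

The shipped test-and-benchmark suite uses 100 noisy curves for recovery,
200 synthetic plates for the false-positive control, 25×25 steady-state
grids for the boundary map, 14-day serial transfers, and 100 random
systems for the conservation property; all run in a few minutes on one
CPU. Ties in the derivative maximum take the earliest index; negative
geometric lags clamp to zero with a warning; wells failing to cross the
threshold are excluded with a warning rather than failing the experiment;
optimizer failures return `converged = FALSE`. Thresholds strictly inside
$(0,1)$ are enforced for the boundary classification.

## Known limitations

* Lag estimates from OD data are meaningful only when the inoculum is
  above the detection limit; below it, use the time-to-threshold metric.
* Gompertz/Logistic lag values are method conventions, not Baranyi lags;
  compare within a method, never across.
* The two-sample cost test ignores the (shared) standard-curve
  uncertainty; with technical-replicate-only designs it can be mildly
  anticonservative.
* The steady-state boundary map is conditional on the chosen $\kappa$ and
  $D$; the batch-fit regime $\kappa \approx 0$ has no nontrivial
  steady state to classify.
* No spatial structure, stochastic dynamics, copy-number variation, or
  compensatory evolution in the ODE model.
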