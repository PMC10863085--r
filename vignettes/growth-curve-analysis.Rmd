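---
title: "Growth-curve models, fitting methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve models, fitting methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthfit)
```

This vignette is the package's account of the science it implements: the
growth models, the preprocessing conventions, the three fitting methods,
the derived statistics, and the synthetic benchmark — together with the
numerical choices and their rationale.

## The models and their assumptions

Everything is fitted on the log-population scale $y(t) = \ln(N(t)/N_0)$,
where $N$ is a population-size proxy (OD600 by default). The two sigmoids
are used in the Zwietering parameterization, so the fitted parameters are
directly the quantities a microbiologist reports:

$$y_{\mathrm{logistic}} = \frac{A}{1 + \exp\!\left[\tfrac{4\mu_{max}}{A}(\lambda - t) + 2\right]},
\qquad
y_{\mathrm{gompertz}} = A \exp\!\left\{-\exp\!\left[\tfrac{\mu_{max}\,e}{A}(\lambda - t) + 1\right]\right\}$$

with $A = \ln(N_\infty/N_0) > 0$ (dimensionless), $\mu_{max} > 0$ (h⁻¹)
the maximum slope of $y$, and $\lambda$ (h) the lag. Both curves are
strictly increasing, bounded in $(0, A)$, and attain slope $\mu_{max}$ at
their inflection point ($t_m = \lambda + A/2\mu_{max}$ for the logistic,
$\lambda + A/e\,\mu_{max}$ for the Gompertz). The assumptions are the
usual ones: a single lag–exponential–stationary transition, no diauxie,
no death phase, measurement proportional to population size. Curves that
violate them (diauxic shifts, lysis) should be fitted manually or with
Easy Linear rather than parametrically.

## Phase landmarks: standard and tight

Two conventions are implemented for the lag and the end of exponential
growth, selected by a single `lag_definition` switch that applies to both
ends of the interval (the two definitions form matched pairs; mixing them
would make the "tight" interval asymmetric for no obvious reason):

* **standard** — the tangent construction: the lag is where the
  inflection tangent crosses $y = 0$ (which is the parameter $\lambda$
  itself in this parameterization) and the phase ends where that tangent
  reaches $y = A$, i.e. at $\lambda + A/\mu_{max}$ for both models.
* **tight** — the zeros of the third derivative of $y(t)$: the smallest
  zero (where the slope increases fastest) starts the phase, the largest
  ends it. The tight interval is always strictly inside the standard one
  and hugs the visually log-linear segment more closely.

The third-derivative zeros are found numerically — sign-change bracketing
on a 4000-point grid spanning $[\lambda - A/\mu,\ \lambda + 3A/\mu]$
followed by bisection to $10^{-10}$ h — using analytically derived third
derivatives. For the logistic the zeros have closed forms (sigmoid levels
$(3 \pm \sqrt3)/6$, giving e.g. a tight lag of
$\lambda + \tfrac{A}{2\mu}(1 - \tfrac{\ln(2+\sqrt3)}{2})$); for the
Gompertz they sit at inner-exponential values $(3 \pm \sqrt5)/2$. The
test suite uses these closed forms as an independent oracle for the
numeric root finder (agreement to $10^{-8}$); the numeric route is the
implementation because it treats both models uniformly.

## Preprocessing conventions

* **Blanking** subtracts the *pointwise mean* of the assigned blank
  traces (by default the first three samples in the file), not a scalar;
  this removes slow drift shared by the blanks.
* **$N_0$ reference.** Measured data never comes with a true $N_0$; the
  log transform uses the smallest strictly positive blanked value as the
  reference. This makes $y \ge 0$ everywhere usable and ties the total
  doubling count $\log_2(N_{max}/N_{min})$ to the same floor.
* **Masking, not clipping.** Blank subtraction of noisy data can produce
  values $\le 0$, whose logarithm does not exist. Such points are masked
  and excluded from fitting; fabricating a clipped value would bias fits
  near the baseline. Masked points also break Easy Linear window
  contiguity.
* **Smoothing** is a centered rolling mean of half-width
  $\lfloor w/2 \rfloor$, truncated *symmetrically* at the edges so the
  series length is preserved, endpoints are left untouched, and a
  constant series is exactly invariant (an even $w$ therefore behaves
  like $w+1$). Smoothing, when requested, is applied before the log
  transform. **Caveat:** an averaging window comparable to a curve's
  rise time $A/\mu_{max}$ flattens the transition and biases
  $\mu_{max}$ downward — at a 0.5 h sampling interval, the window-10
  default of interactive use spans 5 h, which halves the apparent
  $\mu_{max}$ of fast growers. Smoothing is therefore *off* by default
  in every scripted pipeline here (`fit_plate()`, `run_validation()`)
  and should be enabled deliberately, for data whose noise rather than
  curvature dominates at the window scale.

## Fitting

**Parametric** fits minimize $\sum_i (y_i - y(t_i; A, \mu_{max},
\lambda))^2$ over the valid points with bounded Levenberg–Marquardt least
squares (at most 5000 function evaluations, relative convergence
$10^{-10}$). Starting values are data-driven: $A_0 = \max y$; $\mu_0$ the
steepest centered finite-difference slope; $\lambda_0$ the tangent
x-intercept at that point, clipped into the box. Bounds: $A \in (0,
2\max y]$, $\mu_{max} > 0$, $\lambda \in [\min t - \mathrm{span},
\max t]$. Standard errors come from the estimated covariance of the
least-squares problem and are `NA` when the normal matrix is singular.
Optimizer failure is reported as `converged = FALSE` rather than an
error, so whole-plate batch fits continue; genuinely degenerate inputs
(fewer than 5 valid points, a flat trace) are errors, because no
parameter vector is meaningful for them.

**Easy Linear** enumerates every contiguous run of exactly `window` valid
points, fits an ordinary least-squares line to each, and keeps the
largest slope. A candidate replaces the incumbent only if its slope is
larger beyond a $10^{-9}$ relative tolerance, so on exactly log-linear
data — where all windows tie up to floating-point noise — the *earliest*
window wins deterministically. The default window is 10 points; too small
a window chases noise upward, too large a window averages over curvature
downward (the suite checks that the estimate is non-increasing in window
size on noise-free sigmoids).

**Manual** fitting is the classical exponential approximation: an OLS
line over the valid points inside a user-chosen time interval, requiring
at least two points. Manual fitting over the Easy Linear winning window
reproduces the Easy Linear slope exactly.

## Derived statistics

Doubling time $\ln 2 / \mu_{max}$; doublings in exponential phase
$\mu_{max}(t_{end} - t_{start})/\ln 2$; total doublings
$\log_2(N_{max}/N_{min>0})$ from the measured trace. Note that the
phase doubling count is a *tangent* count: because $\mu_{max}$ is the
curve's maximum slope, it strictly exceeds the realised log gain
$(y(t_{end}) - y(t_{start}))/\ln 2$ (by roughly 24% over the standard
interval of a logistic, 12% over the tight one). **Yield** is reported as
the maximum of the measured blanked trace, uniformly across all three
methods; the fitted plateau $N_0 e^{A}$ is additionally exposed as
`yield_fitted` for parametric fits. Replicate groups (samples sharing a
name) are summarised with the mean and the *sample* standard deviation
($n-1$ divisor) over determined, non-excluded members; a single usable
member yields `NA` sd, an all-excluded group `NA` means plus its
exclusion counter.

Well positions are assigned row-major by sample ordinal when the sample
count matches a standard plate (6, 12, 24, 96, 384), so sample 14 of 96
is "B2"; other counts fall back to the plain ordinal. (Descriptions of
plate files sometimes count the time row as row 1, which shifts the
file-row-to-well mapping by one; the ordinal-based convention used here
is stated explicitly to avoid that ambiguity.)

## The synthetic benchmark

`run_validation()` draws growth parameters from uniform ranges chosen to
cover realistic microbial kinetics — $N_0 \sim U(0, 0.5)$,
$A \sim U(0.5, 4)$, $\mu_{max} \sim U(0, 2)$ h⁻¹,
$\lambda \sim U(0, 100)$ h, with draws of $N_0$ or $\mu_{max}$ below
$10^{-3}$ redrawn to avoid numerically degenerate curves — evaluates the
chosen sigmoid on a 0–200 h grid sampled every 0.5 h (long enough for
the longest lags to saturate for all but the slowest growers; curves
whose plateau lies beyond the grid are still fitted but flagged), adds
Gaussian noise *on the population scale* (emulating instrument noise on
OD; default sd 0.01 population units, typical of plate readers), refits
with the generating model, and reports per-parameter median relative
errors over the converged fits. A fixed seed makes the whole report
reproducible bit for bit.

Noise-free recovery is exact to numerical precision (medians
$\le 10^{-3}$; the acceptance script reports the maximum median over
both models, 100 curves each). Under noise the dominant error source is
structural, not the optimizer: when $N_0$ is drawn within a few noise
standard deviations of zero, the min-positive-$N_0$ log transform
inflates the baseline of $y$, and the least-squares optimum genuinely
moves away from the truth (on every such curve the fitted residual sum
of squares is *below* that of the true parameters). This is a property
of analyzing noisy near-zero inocula on the log scale, and real
plate-reader wells inoculated near the detection limit behave the same
way.

What the generator does *not* emulate: correlated (drift-like) noise,
evaporation, diauxic shifts, death phases, condensation artifacts, or
well-to-well cross-talk. Passing the benchmark therefore demonstrates
correctness of the fitting machinery under the stated model, not
robustness to every real-world pathology — that is what the manual
method and the exclusion flags are for.

## Problem sizes and runtime

The shipped tests run the benchmark at 100 curves per model (noise-free
and at sd 0.01), 50 curves per noise level for the monotonicity check,
and 10–12 curves on coarser grids where only reproducibility is at
stake; a 100-curve study on the default 401-point grid fits in under a
second per model on a single core, so plate-scale datasets (hundreds of
wells) are comfortably in range.

## Known limitations

* Only Logistic, Gompertz and exponential models; no Richards, Baranyi,
  diauxic or death-phase models.
* Unweighted least squares: all valid points count equally, so long
  stationary phases dominate the objective relative to short
  transitions.
* No outlier detection beyond nonpositive-value masking; exclusion is a
  user decision.
* The `xlsx` reader takes the first sheet only, and timestamps are
  assumed to be hours (no date parsing).
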