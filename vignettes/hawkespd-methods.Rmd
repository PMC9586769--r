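---
title: "Modelling cumulative drug effects in monitored physiological series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cumulative drug effects in monitored physiological series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkespd)
```

## The problem

A drug given repeatedly at the bedside does not act instantaneously: each
administration produces an effect that builds up over minutes, peaks, and
decays — and overlapping administrations accumulate.  `hawkespd` models a
regularly sampled monitored variable (the motivating case is one-minute
heart rate during an anticoagulant infusion regimen in intensive care) as

$$\lambda_t \;=\; \mu_t + \sum_{t_i < t} \gamma(t - t_i,\, d_i),$$

a Hawkes-style self-exciting structure in which the "events" are drug
administrations at times $t_i$ with doses $d_i$.  The baseline is a
sinusoid, $\mu_t = a_0 + b_0 \sin(\alpha_0 t + \beta_0)$, a deliberately
coarse description of circadian/routine variation that must stay strictly
positive; the excitation kernel factorizes into a dose response and a lag
profile:

$$\gamma(u, d) \;=\;
  \underbrace{\frac{1}{a_1 + b_1 e^{-\kappa_1 (m_1 + d)\, a_2}}}_{\text{dose sigmoid}}
  \;\cdot\;
  \underbrace{\frac{u^{\kappa_2 - 1} e^{-b_2 u}}{b_2^{\kappa_2}\,\Gamma(\kappa_2)}}_{\text{Gamma-shaped lag}} .$$

The sigmoid encodes a saturating dose response (more drug helps up to a
point), is bounded in $(0, 1/a_1]$ and non-decreasing in $d$ whenever
$\kappa_1 a_2 > 0$.  The lag factor is zero at lag zero (we require
$\kappa_2 > 1$), rises to a single mode at $(\kappa_2 - 1)/b_2$ minutes and
decays exponentially — delayed onset, then washout.  Eleven parameters
$\theta = (a_0, b_0, \alpha_0, \beta_0, a_1, b_1, \kappa_1, m_1, a_2,
\kappa_2, b_2)$ are estimated by bounded nonlinear least squares.

## Kernel normalization: a deliberate double reading

The lag factor above, taken exactly as written, is *not* a probability
density in either the rate or the scale parameterization of the Gamma
family: it decays like a rate-parameterized density but divides by
$b_2^{\kappa_2}\Gamma(\kappa_2)$, so its total mass per unit sigmoid is
$b_2^{-2\kappa_2}$.  At the package's canonical simulation truth
($\kappa_2 = 5$, $b_2 = 0.4$) that mass is $0.4^{-10} \approx 9537$
monitored-variable units per administration.

This matters for simulation studies.  With ~60 dose-25 administrations the
unnormalized kernel makes the drug term's variance around $3 \times 10^5$,
so additive Gaussian noise of variance up to 10 is invisible: the best
attainable $R^2$ stays above 0.9999 at every noise level in that range.  A
noise-robustness study in which variance-4–5 noise drags the best $R^2$
below 0.9–0.8 is only arithmetically possible when the kernels carry unit
mass, which also keeps a simulated series at a physiological scale (the
sinusoid contributes variance $b_0^2/2 = 12.5$, so best $R^2 \approx
12.5/(12.5 + \sigma^2)$ — about 0.74 at $\sigma^2 = 4.5$).

The package therefore keeps **both** forms and is explicit about which is
in use:

* `normalized = FALSE` (default of the model functions): the kernel exactly
  as written above — fidelity to the model's printed definition;
* `normalized = TRUE`: the proper rate-parameterized Gamma density
  $b_2^{\kappa_2} u^{\kappa_2-1} e^{-b_2 u} / \Gamma(\kappa_2)$, used by
  default in the simulation-study helpers (`noise_robustness()`,
  `parameter_sweep()`, `make_hr_fixture()`) for the scale reasons above.

Internally all kernel evaluation goes through log-gamma arithmetic, so
shapes near the upper bound $\kappa_2 = 22$ do not overflow.

## Data model and conventions

* Time is measured in minutes from the series start; grid index $k$ maps to
  $t_0 + k\,\Delta t$ with $\Delta t = 1$ minute by default.  Series and
  schedule are assumed to share one clock.
* Missing series values are forward-filled (back-filled head) by
  `read_series_csv()`; a file that is not a uniform grid after gap-filling
  is rejected.
* Duplicate administration times are rejected by default;
  `merge_duplicates = TRUE` sums the doses, which is well defined because
  the intensity sums kernels.
* Events at $t_i \ge t$ contribute nothing at $t$ (strict causality); for
  $\kappa_2 > 1$ the kernel is zero at lag 0 anyway, so the boundary
  convention is immaterial.
* Baseline positivity ($\mu_t > 0$) is checked at evaluation time, not at
  construction: admissible boxes contain violating corners (e.g. $a_0 = 1$,
  $b_0 = 10$), so `baseline_mu()` warns by default and errors in strict
  mode.

## Trend extraction: Haar MODWT

Monitored vitals mix measurement noise, beat-level variation, disease
trend and drug-driven trend.  Before fitting, the series is decomposed
with a maximal-overlap discrete wavelet transform using Haar filters —
scaling filter $(1/2, 1/2)$, wavelet filter $(1/2, -1/2)$, upsampled by
$2^{j-1}$ at level $j$ — giving full-length, shift-covariant detail
(`d1..dJ`) and scale (`s1..sJ`) coefficient series that stay aligned with
the original grid.  Defaults: $J = 4$ levels (a level-4 Haar smooth on a
one-minute grid averages over roughly a quarter hour, the time scale of
the drug effects being modelled), periodic boundary (reflection is
available; the periodic inverse is used on the internally stored mirrored
transform so reconstruction stays exact).  No phase-shift correction is
applied to the coefficients: the downstream Granger test and fit compare
series on a common grid and are indifferent to a common shift.

The implementation is verified by its own mathematics rather than by a
reference library: perfect reconstruction and energy conservation to
$10^{-8}$ relative, linearity, shift covariance, and agreement with a
brute-force cascade-filter convolution oracle are all asserted in the test
suite.  (The classical continuous-time inner-product definition of the
coefficients leaves the discretization open; the standard discrete pyramid
is the only form used here.)

## Choosing the modelling target: Granger selection

Which of the $2J$ coefficient series should the model fit?  The one most
predictable from the dosing record.  For each candidate $x$ the package
fits, by OLS on the common estimable sample,

$$x_t = c + \sum_{i=1}^{m} \alpha_i d_{t-i} + \sum_{i=1}^{m} \beta_i x_{t-i}
+ \varepsilon_t$$

against the restriction $\alpha_1 = \dots = \alpha_m = 0$, and forms
$F = \frac{(SSR_r - SSR_{ur})/m}{SSR_{ur}/(n-k)}$ with $k$ the number of
unrestricted parameters ($2m$ plus intercept).  The drug regressor is the
dose-mark series (zeros between administrations; an indicator encoding is
available).  The component with the smallest p-value wins; ties break
deterministically (scale before detail, then lower level).  Design
choices: lag $m = 4$ minutes by default — short relative to an ~800-sample
record yet spanning the near-term dependence a one-minute grid plausibly
carries — and no multiple-testing correction in the selection itself
(the report table carries a Bonferroni column for transparency).  The
candidates are tested as-is, without demeaning or differencing; formal
stationarity is not established first, a caveat that applies equally to
any autoregressive screen of this kind.  This is Granger *causality*
testing, not cointegration analysis; no error-correction structure is
estimated.

## Fitting

The loss is plain least squares on the grid.  Two residual conventions are
supported because the model admits both readings:

* `mode = "level"` (default): $L = \sum_t (x_t - \lambda_t)^2$ — the
  intensity *is* the monitored level.  This is the self-consistent reading:
  a fitted baseline level in the 70s only makes sense against a
  heart-rate-scale series, and the package's simulators default to it.
* `mode = "increment"`: $L = \sum_{t \ge 2} (\Delta x_t - \lambda_t)^2$
  with $\Delta x_t = x_t - x_{t-1}$ — the intensity as expected one-step
  increment, the literal point-process analogue.  The first grid point is
  dropped.

Minimization uses `optim(method = "L-BFGS-B")` — a bounded quasi-Newton
method with numerical gradients — inside the finite box returned by
`reference_bounds()` (users may widen or pin individual parameters).
Tolerance `tol` maps to the optimizer's relative-reduction control
(`factr`); default `1e-8` on the loss.  Non-finite losses are replaced by a
large finite penalty so a start in a degenerate corner is rejected rather
than fatal.

**Why multi-start alone is not enough.**  The loss is violently multimodal
in the baseline frequency $\alpha_0$: on an 800-minute record the basin
around the true frequency has width of order $2\pi/T \approx 0.008$ inside
a box spanning $[0.1, 10]$.  Blind restarts essentially never land in it.
The first start is therefore data-driven: the dominant periodogram
frequency of the demeaned target, refined by a golden-section search
within $\pm 1.5$ Fourier bins while the sinusoid's amplitude/phase and the
excitation scale are profiled linearly.  The excitation can be profiled
because, given $(\kappa_2, b_2)$ and a constant-dose schedule, the summed
lag profile is a fixed regressor whose coefficient is exactly the sigmoid
scale; a small $(\kappa_2, b_2)$ grid (5 × 6 values spanning the box)
picks the best combination, and the linear coefficient is folded back into
$a_1$.  The second start is the box midpoint and the rest are Latin
hypercube draws (`lhs::randomLHS`), all reproducible from `seed`.  With
this initializer, noiseless self-fits reach $R^2 \ge 0.999$ across seeded
replicates in the test suite — individual *parameters* are far less
identifiable than the fitted curve (see the sweeps below), which is why
the recovery contract is stated on the curve, not on $\theta$.

Goodness of fit is reported three ways, deliberately: $R^2 = (SST -
SSE)/SST$ (raw, never clipped — a nonlinear fit can go negative), the
sample Pearson correlation between observed and fitted with its two-sided
test p-value, and $\sqrt{\max(R^2, 0)}$.  The latter two coincide only for
linear OLS with intercept, so conflating "the correlation" with "$R$" is
unsafe for this model; reporting all three lets the reader compare.

## The simulation engine and what it does (not) emulate

`simulate_series()` evaluates the intensity on the grid by the *same* code
path as `intensity()` (there is no second model) and adds i.i.d. Gaussian
noise; "noise level" always means the noise *variance* here.
`make_hr_fixture()` is the canonical synthetic record: 812 one-minute
samples at heart-rate scale from the canonical truth
(`reference_params()`: $a_0 = 70$, $b_0 = 5$, $\alpha_0 = 1$,
$\beta_0 = 2$, $a_1 = 1$, $b_1 = 1$, $\kappa_1 = 0.3$, $m_1 = -20$,
$a_2 = 3$, $\kappa_2 = 5$, $b_2 = 0.4$), with exactly 63 dose-25
administrations drawn as exponential gaps (redrawn from derived sub-seeds
until all 63 land inside the record) and noise variance 4.  It is labelled
synthetic everywhere: it mimics the *shape* of a real ICU record (length,
sampling, dosing pattern, scale), not its physiology — no circadian
non-stationarity, no disease trend, no missingness, no measurement
artefacts, and event times are inputs rather than draws from the fitted
intensity.  Passing tests on these fixtures demonstrate correctness of the
machinery and reproducibility of the simulation study, not clinical
validity.

Study conditions used by the tests and the acceptance script, chosen once:
800 one-minute steps, 60 administrations of dose 25 at mean gap 13 minutes
(exponential), truth as above, unit-mass kernels, 20 replicate fits per
noise level with "best" = maximum $R^2$ (matching a best-attainable-fit
reading), 3 optimizer starts and a 100-iteration cap per replicate — the
data-driven start makes longer polishing redundant, and these sizes keep
the full study in the low minutes on one CPU.

## What the sweeps show

`parameter_sweep()` substitutes one parameter (all others held at truth;
`refit = TRUE` optionally re-estimates the rest) and records $R^2$ against
a noiseless simulation, so the truth scores exactly 1 and the curve's
sharpness measures identifiability:

* $\kappa_1$ peaks exactly at its true value (the sigmoid is strictly
  monotone in $\kappa_1$, so the argmax is unique);
* $b_1$, $a_1$, $a_2$ are comparatively flat across their full admissible
  ranges — they act only through the scalar sigmoid, whose value the data
  constrain far more weakly than the lag shape;
* $(b_2, \kappa_2)$ jointly show a high-$R^2$ ridge at a roughly constant
  ratio: the data pin down the lag profile's mode
  $(\kappa_2 - 1)/b_2 \approx 10$ minutes, not the two parameters
  separately.

One classical expectation does **not** hold and cannot: a sweep of the
baseline *level* $a_0$ over $[1, 100]$ moves the whole curve by up to 69
units against a clean-signal SD of about 3.6, so its $R^2$ collapses —
under any loss that penalizes level offsets, a level parameter is
necessarily the most identifiable one, not a flat one.  A flat $a_0$ sweep
would require an evaluation metric invariant to constant shifts, which
contradicts the $R^2$ definition used throughout.  The corresponding
acceptance expectation is left failing by design, with this analysis as
the explanation.

## Numerical choices and degenerate inputs

* Ties in the sweep argmax and in Granger selection resolve to the first
  candidate in a documented deterministic order.
* $F$-statistics are clamped at 0 against floating-point cancellation
  (nested OLS guarantees $SSR_r \ge SSR_{ur}$ mathematically).
* An identically zero drug-lag block returns $F = 0$, $p = 1$ (restricted
  and unrestricted fits coincide); any other rank deficiency errors.
* A constant observed series makes $R^2$ and the Pearson correlation
  undefined and raises an error rather than returning a sentinel.
* All randomness (schedules, noise, restarts, replicate sub-seeds) derives
  from explicit integer seeds; generators save and restore the session RNG
  state, so library calls never perturb user RNG streams.

## Known limitations

Single drug only (no mutual excitation between drug types); event times
are exogenous inputs, never sampled from the intensity; no standard errors
or confidence intervals for $\hat\theta$ (the least-squares surface is
ridge-shaped, so curvature-based intervals would mislead); the sinusoidal
baseline cannot absorb disease-driven trend, which therefore leaks into
the fitted drug term on real data; and two-phase splitting of long records
is out of scope — the pipeline fits one contiguous record at a time.
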