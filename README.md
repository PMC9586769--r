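# hawkespd

Drug-effect modelling of monitored physiological series via a
self-exciting point-process kernel.

## What it is for

Clinicians and pharmacodynamic modellers who give a drug repeatedly —
think of an anticoagulant infusion regimen on an intensive-care unit while
one-minute heart rate is being recorded — need to know how much of the
monitored variable's movement is attributable to the accumulated effect of
past doses.  `hawkespd` models a uniformly sampled monitored variable
$x_t$ as

$$\lambda_t = \underbrace{a_0 + b_0 \sin(\alpha_0 t +
\beta_0)}_{\text{baseline } \mu_t}
\;+\; \sum_{t_i < t}
\underbrace{\frac{1}{a_1 + b_1 e^{-\kappa_1 (m_1 + d_i) a_2}}
\cdot \frac{(t-t_i)^{\kappa_2-1} e^{-b_2 (t-t_i)}}
{b_2^{\kappa_2}\Gamma(\kappa_2)}}_{\text{excitation kernel }
\gamma(t-t_i,\,d_i)}$$

— a Hawkes-type self-exciting structure in which every administration
(time $t_i$, dose $d_i$) adds a dose-sigmoid-scaled, Gamma-shaped bump
that rises, peaks at $(\kappa_2-1)/b_2$ minutes, decays, and stacks with
its neighbours.  The eleven parameters are estimated by bounded
multi-start quasi-Newton least squares; model quality is reported as
$R^2$ and Pearson correlation.

Around that core the package provides the full workflow:

* **Data types and I/O** — `monitored_series()`, `event_schedule()`, CSV
  readers/writers with a forward-fill missing-value policy.
* **Haar MODWT** — `haar_modwt()` / `imodwt()` / `get_component()`:
  shift-covariant multiresolution decomposition into detail (`d1..dJ`)
  and scale (`s1..sJ`) series, used to isolate the trend the drug acts
  on.
* **Granger selection** — `granger_f_test()` and
  `select_target_variable()` pick the wavelet component most predictable
  from the dosing record.
* **Fitting** — `hawkes_fit()` with the classic modelling verbs
  (`summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
  `simulate`, `deviance`).
* **Simulation studies** — `simulate_series()`, `parameter_sweep()`,
  `noise_robustness()`, `make_hr_fixture()`.
* **Pipeline** — `run_pipeline()` (decompose → select → fit → report)
  and a thin command-line wrapper `exec/hawkespd` with subcommands
  `simulate | decompose | granger | fit | sweep | pipeline`.

## Worked example

Simulate a record at the package's canonical truth
(`reference_params()`), 800 one-minute samples with 60 administrations of
dose 25 and Gaussian noise of variance 25, then fit all eleven parameters
from data-blind starts:

```r
library(hawkespd)
sched <- generate_event_schedule(60, mean_gap = 13, dose = 25,
                                 seed = 1, horizon = 799)
sim <- simulate_series(reference_params(), sched, n_steps = 800,
                       noise_variance = 25, seed = 1)
fit <- hawkes_fit(sim$noisy, sched, n_starts = 3, seed = 1)
summary(fit)
```

```
Drug-effect model fit — level mode

       estimate   lower upper     note
a0     70.18299    1.00   100
b0      0.55728    0.10    10
alpha0  0.10568    0.10    10
beta0   2.38361    0.10    10
a1      1.01138    0.10    50
b1      0.01000    0.01    10 at lower
kappa1  0.50500    0.01     1
m1      0.00000 -100.00    98
a2      5.00500    0.01    10
kappa2  5.00183    2.10    22
b2      0.40014    0.01     2

SSE = 31239.8   SST = 234625637   R-squared = 0.999867
Pearson corr = 0.9999  (p = 0 );  sqrt(max(R^2, 0)) = 0.9999
Optimizer: best of 3 starts (start 1 won); iteration cap reached
```

Read this the way a practitioner should: the fitted **curve** is
essentially exact ($R^2 = 0.9999$), and the parameters that shape the lag
profile are sharply recovered (`kappa2` 5.002 vs 5, `b2` 0.4001 vs 0.4,
`a1` 1.011 vs 1 — the kernel's mode $(\kappa_2-1)/b_2 \approx 10$ minutes
is what the data pin down).  The sigmoid internals (`b1`, `kappa1`, `m1`,
`a2`) sit at their starting values because a constant-dose regimen only
identifies the sigmoid's *value*, not its shape, and the baseline
sinusoid is weakly identified here because the drug term dominates the
signal by two orders of magnitude.  Weak parameter identifiability with
excellent curve recovery is a documented property of this model, not a
failure of the optimizer — see the methods vignette
(`vignettes/hawkespd-methods.Rmd`).

Individual model pieces are just as accessible:

```r
excitation_kernel(c(2, 10, 30), dose = 25, params = reference_params())
#> [1]  28.93178 737.07707  20.02821     # rise, peak at lag 10, decay
```

The end-to-end pipeline on the built-in synthetic bedside fixture (812
one-minute samples, 63 dose-25 administrations):

```r
rep <- run_pipeline(simulate = TRUE, output_dir = "out", seed = 1)
rep$selected_label          # wavelet component chosen by the Granger step
rep$fit$r_squared
```

or, from a shell, `hawkespd pipeline --simulate --seed 1 --out out`.

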