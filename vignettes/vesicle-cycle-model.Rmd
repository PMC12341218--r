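---
title: "The three-state vesicle cycle: model, observables and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-state vesicle cycle: model, observables and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpool)
library(dplyr)
```

## The model

`svpool` models spontaneous synaptic vesicle cycling in a single presynaptic
pool with three states: the fraction ready for release ($u_1$), the fraction
fused with the plasma membrane ($u_2$), and the fraction being recycled
after endocytosis ($u_3$). Three first-order rate constants drive the cycle

$$
\frac{du_1}{dt} = -\alpha u_1 + \beta u_3,\qquad
\frac{du_2}{dt} = \alpha u_1 - \sigma u_2,\qquad
\frac{du_3}{dt} = \sigma u_2 - \beta u_3,
$$

with $\alpha$ the exocytosis (activation) rate, $\sigma$ the endocytosis
rate, and $\beta$ the recycling rate returning retrieved vesicles to the
release-ready pool. All three are in s$^{-1}$; $u_1+u_2+u_3=1$ is conserved
exactly. The baseline values shipped in `default_rates()` are the
literature estimates $\alpha = 0.008$, $\beta = 0.5$, $\sigma = 1.67$
s$^{-1}$: exocytosis is by far the slowest step, so at rest almost the whole
pool is release-ready,

```{r}
steady_state(default_rates())
```

The model is deliberately minimal: it is linear, single-pool, and
deterministic at the state level. Stochasticity enters only at the event
layer, where individual miniature EPSCs (mEPSCs) are drawn from the release
flux (below). Assumptions worth keeping in mind:

* the pool is well mixed — no spatial structure, no separate reserve pool;
* rates are piecewise-constant in time — perturbations are steps, because no
  ramp shape is available to constrain anything smoother;
* the fraction-based states describe an effectively infinite vesicle
  reservoir; finite-pool fluctuations are not propagated into the state.

## Exact propagation

Because the system is linear with piecewise-constant coefficients, the flow
over any constant-rate interval is the matrix exponential of the generator

$$
M = \begin{pmatrix} -\alpha & 0 & \beta\\ \alpha & -\sigma & 0\\
0 & \sigma & -\beta \end{pmatrix},
\qquad u(t+\Delta t) = e^{M\Delta t}\,u(t).
$$

`propagate()` and `simulate_pool()` evaluate this through the
eigendecomposition of $M$ (with a scaling-and-squaring fallback should a
rate combination render $M$ numerically defective). There is no step size
and no discretisation error: refining the output grid leaves the states at
shared times unchanged to $10^{-12}$, and the test suite holds the
propagator against an independent forward-Euler integration at
$dt = 10^{-4}$ s and against `Matrix::expm()`. Forward Euler is kept purely
as a test oracle. The same spectral decomposition gives a closed-form time
integral of the release flux (used by the point-process likelihood), exact
per segment.

A simplex violation beyond $10^{-9}$ is treated as a bug and rejected, never
renormalised; the propagator only rounds off sub-$10^{-12}$ negative dust
that complex-arithmetic cancellation can leave behind.

## The staged LPA perturbation

Lysophosphatidic acid (LPA) signalling is represented purely as a staged
change of rates (`scenario_params()`): the recycling rate collapses at
$t_\beta$, and the exocytosis rate is multiplied by `alpha_factor` (default
1.5) a fixed `lead` (default 60 s) later, with $\sigma$ untouched. The
phrase that motivates the recycling change — a reduction of $\beta$ "by
0.01" — admits two readings, and both are implemented:

* **multiplicative** (default): $\beta \to 0.01\beta = 0.005$ s$^{-1}$, a
  near-collapse of recycling. This is the default because only this reading
  produces the qualitative behaviour the scenario exists to show (a
  recycling collapse strong enough to deplete the ready pool within the
  60-s lead);
* **absolute**: $\beta \to \beta - 0.01 = 0.49$ s$^{-1}$, a 2% change with
  no visible consequence on this horizon.

Neither reading is asserted to be the historically intended one.

### What the exact trajectory shows about masking

The scenario's point is that an early recycling collapse can *mask* a
subsequent release increase: by the time $\alpha$ steps up, $u_1$ has been
drained, so the observable release flux $\alpha(t)u_1(t)$ — and with it the
mEPSC frequency — falls rather than rises. `masking_check()` quantifies
this against the $\alpha$-only control.

Running the default scenario exactly gives a sharper picture than the
qualitative claim:

```{r}
p <- scenario_params()
traj_full <- simulate_pool(build_lpa_schedule(p))
traj_ctrl <- simulate_pool(build_lpa_schedule(p, alpha_only = TRUE))
masking_check(traj_full, traj_ctrl)
```

At the $\alpha$ step, $u_1(300) = 0.6566$: slightly *more* than $1/1.5$ of
its resting value, because the depletion during the 60-s lead is governed by
the slow relaxation mode of the collapsed-recycling system
($|\lambda_{\mathrm{slow}}| = 0.0130$ s$^{-1}$), not by $\alpha$ alone. The
post-step flux therefore overshoots the resting baseline by 0.54% for about
0.6 s before decreasing monotonically below it. Strict masking — flux never
exceeding baseline — would require a lead of 61 s or more at these rates;
at 60 s the transient is *practically* occluded (no event-train analysis
could resolve a half-percent excursion lasting under a second) but not
mathematically suppressed. `masking_check()` therefore reports the peak
ratio and an explicit tolerance argument (`tol = 0` by default, strict),
and it searches the exact right-hand limits at the rate breakpoints in
addition to the sampled grid, so the verdict cannot flip with the sampling
resolution. The acceptance suite asserts the strict claim and documents its
failure rather than hiding the 0.54% excursion behind a tolerance.

The same exact solution shows that the fused fraction $u_2$ ends the 18-min
horizon at $0.45\times$ its resting value, not above it: with recycling
collapsed, the fused pool's inflow $\alpha u_1$ shrinks as $u_1$ drains,
while its outflow rate $\sigma$ never changes. A persistently elevated
fused fraction arises in this model only under the absolute reading of the
$\beta$ change (where $u_1$ stays high), or through a reduced $\sigma$ —
which is exactly what the fluorescence-decay observable below measures
independently.

## Observables

* **mEPSC rate** — `mepsc_rate()` maps the flux to an expected event rate
  $n_{\mathrm{pool}}\,\alpha(t)u_1(t)$, with `n_pool` the effective
  releasable pool size. One fused vesicle is one detected event; detection
  losses are folded into `n_pool`, which is justified by amplitude
  distributions being condition-invariant.
* **SynaptopHluorin fluorescence** — `phluorin_signal()` reads out
  $F(t) = F_0 + g\,u_2(t)$, since the probe fluoresces only while the
  vesicle lumen faces extracellular pH. After an exocytosis transient with
  $\alpha \approx 0$, $u_2$ relaxes as $e^{-\sigma t}$, so the fitted decay
  constant of `fit_exp_decay()` estimates the membrane residence time
  $1/\sigma$ — the model's point of contact with re-acidification
  measurements.
* **Calcium traces** — `ca_peak()` implements the top-five rule: the peak
  is the mean of the five highest post-stimulus values minus the baseline.
  The baseline is the mean of all pre-stimulus samples by default; the
  averaging window is configurable because conventions differ between rigs.
  `normalize_to_reference()` expresses peaks as a percentage of a maximal
  (glutamate) response.
* **Dose-response** — `fit_boltzmann()` fits
  $R(c) = r_{\min} + (r_{\max}-r_{\min})/(1+e^{(\log_{10}EC_{50}-\log_{10}c)/k})$
  on the $\log_{10}$ concentration axis with the slope $k$ in decades.
  Initialisation is data-driven (asymptotes from the response extremes,
  midpoint from the half-maximum crossing, slope 0.5), with up to ten
  perturbed restarts before a failure is reported; a constant response is
  rejected as unidentifiable rather than fitted.

## Synthetic data

Every input the analysis consumes can be generated in-package, seeded:

* `sample_event_train()` draws inhomogeneous Poisson events by
  Lewis–Shedler thinning. The envelope is taken from the rate function's
  own attribute when it was built by `scenario_rate_fn()` (a dense
  per-segment probe with 0.1% headroom — within a constant-rate segment
  $u_1$ is a three-term exponential mixture with at most one interior
  extremum, so a dense grid bounds it tightly) and every candidate is
  checked against it, so a broken envelope aborts instead of biasing the
  sample.
* Amplitudes are log-normal truncated at a detection floor (inverse-CDF
  truncation, so no rejection loop), independent of event times and of
  condition. The scale (median ≈ 20 pA) is an arbitrary but realistic
  choice; no published value constrains it.
* `synth_ca_trace()` builds the somatic calcium transient as a
  difference-of-exponentials ($\tau_d = 4\tau_r$) whose peak lands at the
  requested latency — drawn uniformly from 75–85 s post-stimulus by
  default — sampled at 2-s intervals.
* `synth_dose_response()` perturbs the Boltzmann curve (default EC50
  1.2 µM, 0.1–50 µM range, 5 replicates) with 10% multiplicative noise.
* A single global seed is expanded into per-stream seeds inside
  `run_synth()`, so adding one generator call never shifts another
  stream's draws; reruns are byte-identical, which the suite checks by MD5.

What the generators deliberately do **not** emulate: raw current traces and
the mini-detection step (trains enter as event lists), fluorescence movies,
bleaching and drift, correlated noise, and any cell-to-cell variability
beyond the Poisson and amplitude randomness. Passing tests therefore show
that the analysis recovers what this statistical structure encodes — not
that real recordings satisfy that structure.

## Inference

`poisson_loglik()` scores an event train against a rate function by
$\sum_i \log\lambda(t_i) - \int_0^T\lambda$, with the integral exact (spectral)
for scenario rate functions and adaptive quadrature between breakpoints
otherwise. `fit_scenario()` maximises it over a chosen subset of
$\{$`alpha_factor`, `beta_scale`, `lead`, `n_pool`, `t_exo_up`$\}$ —
automating, as estimation, the otherwise manual matching of the rate
perturbation to an observed mEPSC frequency reduction. Numerical choices:

* one free parameter: Brent search on the bounds, repeated on three
  sub-intervals as a cheap guard against the mild non-convexity the `lead`
  parameter can induce; several free parameters: seeded multi-start
  L-BFGS-B (5 starts);
* `beta_scale` is searched on $\log_{10}$ scale, since the two textual
  readings of the recycling change differ by two orders of magnitude;
* confidence intervals by profile likelihood at a 1.92-nat drop (95%, 1
  df), because search bounds may be active where a curvature-based interval
  would be meaningless; with several free parameters the others are pinned
  at the joint estimate (a pseudo-profile), which is documented rather than
  hidden;
* `t_exo_up` is fixed by default: jointly with `lead` it is only weakly
  identifiable from a single train, and the perturbation time is normally
  known by design of the experiment.

With the default conditions (`n_pool` 200, 18-min train, ~1000 events) the
median relative error on `alpha_factor` is about 5–12% over seeds, and the
error shrinks as $1/\sqrt{n_{\mathrm{pool}}}$ — the suite checks this with
one common seed block across pool sizes 50/200/800 (a paired comparison, so
seed luck cannot masquerade as a size effect).

## Problem sizes used by the test suite

Simulation-based checks are sized to run in seconds to a few minutes while
keeping their statistical power: 200 seeds for the Poisson count/dispersion
check (600-s trains at 1 Hz), 20 seeds for the curve-fit recovery
experiments, 20 seeds per pool size for the likelihood-recovery experiment,
and dt = $10^{-4}$–$10^{-3}$ s for the Euler oracle comparisons (run in a
matrix-power form that is algebraically identical to the sequential loop).

## Known limitations

* The three-state cycle has no reserve pool, no calcium dependence and no
  spatial structure; it describes spontaneous (TTX-insensitive) release
  only, and $\sigma$ lumps every post-fusion retrieval step into one rate.
* The staged perturbation is a step function; real receptor signalling has
  its own kinetics that are simply not modelled here.
* The masking verdict is parameter-sensitive near the default operating
  point (a 1-s change in lead flips the strict flag); conclusions should be
  drawn from the reported peak-flux ratio, not the boolean alone.
* Fluorescence is assumed linear in $u_2$ with white additive noise;
  ratiometric calibration to absolute calcium concentrations is out of
  scope, so calcium traces are analysed in whatever units they arrive in.
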