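# svpool

Synaptic vesicle pool kinetics and miniature-EPSC analysis in R.

Lysophosphatidic acid (LPA) and similar presynaptically acting lipids can
*reduce* the frequency of spontaneous miniature excitatory postsynaptic
currents (mEPSCs) even while increasing vesicle exocytosis — if vesicle
recycling collapses shortly before release speeds up, the release-ready
pool is drained and the expected frequency increase never becomes visible.
`svpool` packages the minimal quantitative machinery needed to study this:
a single-pool three-state kinetic model of the vesicle cycle, its staged
rate perturbation, the observables that report on it (mEPSC event trains,
SynaptopHluorin fluorescence, ratiometric calcium traces, Boltzmann
dose–response curves), seeded synthetic-data generators for all of them,
and maximum-likelihood recovery of perturbation parameters from event
trains. It is aimed at synaptic physiologists and modellers who want the
pool-depletion argument as runnable, testable code.

## The model

Vesicle fractions ready for release (u₁), fused with the membrane (u₂) and
in recycling (u₃) evolve by

    du₁/dt = −α·u₁ + β·u₃
    du₂/dt = +α·u₁ − σ·u₂
    du₃/dt = +σ·u₂ − β·u₃

with exocytosis rate α, endocytosis rate σ and recycling rate β
(baseline α = 0.008, β = 0.5, σ = 1.67 s⁻¹). The system is linear, so
`svpool` propagates it *exactly* (matrix exponential per constant-rate
segment — no step size, no discretisation error). The staged LPA scenario
collapses β (×0.01 by default) 60 s before multiplying α by 1.5; the
release flux α(t)·u₁(t) times an effective pool size is the expected mEPSC
rate, from which event trains are simulated (Lewis–Shedler thinning) and
against which they are fitted (inhomogeneous-Poisson likelihood with an
exact flux integral).

## Worked example

```r
library(svpool)

steady_state(default_rates())
#> <pool_state> u1 = 0.979633, u2 = 0.00469285, u3 = 0.0156741
```

At rest, 98% of the pool is release-ready and 0.47% is fused. Now the
staged scenario against its α-only control:

```r
p <- scenario_params()                       # β×0.01 at 240 s, α×1.5 at 300 s
traj_full <- simulate_pool(build_lpa_schedule(p))
traj_ctrl <- simulate_pool(build_lpa_schedule(p, alpha_only = TRUE))
masking_check(traj_full, traj_ctrl)
#> # A tibble: 2 × 5
#>   scenario   baseline_flux peak_flux_ratio t_peak masked
#>   <chr>              <dbl>           <dbl>  <dbl> <lgl>
#> 1 full             0.00784            1.01    300 FALSE
#> 2 alpha_only       0.00784            1.50    300 FALSE
```

The α-only control's release flux jumps to 1.5× baseline at the step. In
the full scenario the preceding recycling collapse has drained u₁, so the
same step peaks at only 1.005× baseline — a 0.5%, sub-second excursion,
after which the flux falls monotonically below baseline: the release
increase is practically occluded (note it is not *strictly* masked at
these exact rates, hence `masked = FALSE`; the flag uses a strict
tolerance by default). `autoplot(release_flux(traj_full))` shows the
excursion.

Event-level round trip — simulate a train at the scenario rate, then
recover the exocytosis factor by maximum likelihood:

```r
rf <- scenario_rate_fn(p, n_pool = 200)
train <- sample_event_train(rf, duration = 1080, seed = 5)
fit_scenario(train, seed = 3)
#> <scenario_fit> logLik = -1007.55, 1012 events
#>   alpha_factor = 1.288  [95% profile CI 1.06, 1.591]
```

The generating value 1.5 sits inside the 95% profile interval. Dose-response
fitting works the same way from tabular data:

```r
fit_boltzmann(synth_dose_response(seed = 2))
#> <boltzmann_fit> EC50 = 1.193 uM, slope = 0.37 dec, range [1.85, 100.8], RSS = 2355 (n = 35)
```

(10% multiplicative noise on a true EC50 of 1.2 µM.) All fit objects
support `tidy()`, `glance()` and `autoplot()`.

A JSON-configured pipeline (`run_simulate()`, `run_synth()`, `run_fit()`)
writes CSV/JSON outputs that are byte-identical under a fixed config and
seed; `inst/cli/svpool.R` wraps it for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "svpool.R", package = "svpool"))')" \
    simulate --out outdir
```

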