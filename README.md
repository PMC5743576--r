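# foragepulse

Tools for modelling and analysing the short-term behavioural responses of
sit-and-wait consumers to pulsed resource subsidies — the situation of
brown anoles (*Anolis sagrei*) confronted with a sudden deposition of
seaweed wrack and its associated detritivore prey. The package is aimed at
behavioural ecologists who run paired-plot pulse experiments with
focal-animal video observation, and at modellers who want a minimal,
fully-reproducible mechanistic account of transient consumer responses.

## The model

Individuals occupy one of two behavioural states, **active** (foraging,
moving) or **inactive** (sit-and-wait), switching by a discrete-time
Markov chain with column-stochastic matrix *P* (columns = source state):

```
P = | p_AA  p_AI |      baseline: p_AA = 0.55, p_AI = 0.05
    | p_IA  p_II |                p_IA = 0.45, p_II = 0.95
```

whose stationary active fraction `p_AI / (p_AI + p_IA)` is 10% — the
canonical time budget of an actively-foraging anole. Perch height (cm,
ground = 0) is emitted from state-dependent gamma distributions with the
active mean below the inactive mean. A resource pulse at one time step
can act through **synchrony** (a fraction *f* = 0.9 of individuals
initiates active foraging) and/or **satiation** (the matrix switches to
one with a 5% stationary active fraction), giving four scenarios —
control, synchrony, satiation, combined — whose expected mean-perch
trajectories follow the Chapman–Kolmogorov recursion `pi[t+1] = P pi[t]`
and whose stochastic counterparts are simulated for populations of
individuals.

The analysis side implements the matching field pipeline: time-weighted
mean perch height per observation bout, move/attack rates with exposure
offsets, activity classification at the strict 0.8 moves/min threshold,
maximum-likelihood gamma emission fitting from classified control bouts,
and mixed-model likelihood-ratio tests (lme4) for treatment-by-time,
perch-vs-distance and treatment-by-stage effects. A synthetic field-study
generator produces complete event-level bout tables with configurable,
exponentially-decaying treatment effects for power and type-I-error
validation.

## A worked example

```r
library(foragepulse)

baseline_matrix()
#> Two-state transition matrix (columns = source state):
#>           from
#> to         active inactive
#>   active     0.55     0.05
#>   inactive   0.45     0.95
#> Stationary distribution: active 0.1000, inactive 0.9000

## synchrony scenario: 90% of individuals activate at step 50
traj <- analytic_trajectory(pulse_scenario("synchrony", seed = 1))
round(c(before = traj[49], at_pulse = traj[50]), 1)
#>   before at_pulse
#>     75.0     34.5
transient_duration(traj, perturbation_step = 50)
#> [1] 5
```

The population mean perch height sits at 75 cm (10% active at 30 cm, 90%
inactive at 80 cm), collapses to 34.5 cm when 91% of the population is
active at the pulse, and relaxes back within 5% of the disturbance in 5
steps (the chain's second eigenvalue is 0.5, so the excess halves each
step).

```r
study <- generate_study(study_config(seed = 1))   # synthetic pulse experiment
summaries <- summarize_bouts(study)               # one row per bout
nrow(summaries)
#> [1] 132

fit_emission_model(study)                         # gammas from control bouts
#> Gamma perch-height emissions:
#>   active:   shape 2.707, scale 13.43 cm (mean 36.4 cm)
#>   inactive: shape 2.348, scale 36.56 cm (mean 85.8 cm)
#>   fitted from n = 146 active, 769 inactive observations

test_treatment_by_time(summaries, "perch")
#> Likelihood-ratio test for `treatment:time_since_subsidy`: chisq = 5.420, df = 1, p = 0.0199 (significant at alpha = 0.05)
#>   model: lmer: tw_mean_perch ~ treatment * time + baseline + (1|plot) + (1|block), ML
```

The generator injected a decaying perch-height reduction in treated
plots; the interaction test recovers it (treated perch heights rise back
toward control levels with time since the subsidy). `run_demo(out_dir,
seed)` runs the whole chain — generation, summaries, emission fit, all
hypothesis tests, and all four scenarios (stochastic + analytic) — and
writes CSV/JSON outputs plus a manifest; `inst/cli/foragepulse.R`
exposes the same steps as shell subcommands (`simulate`, `generate`,
`analyze`, `fit-emissions`, `demo`).

## Layout

* `R/` — model (`transition-matrix.R`, `emissions.R`, `scenario.R`,
  `trajectory.R`), pipeline (`bouts.R`, `fit-emissions.R`,
  `tests-glmm.R`), generator (`generate.R`), orchestration (`demo.R`)
* `vignettes/synchronized-satiation.Rmd` — the methods vignette: model
  assumptions, pipeline statistics, generator design and calibration,
  numerical choices, limitations
* `tests/testthat/` — unit, property and acceptance-grade checks
* `scripts/acceptance.R` — headline-quantity reproduction (above)
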