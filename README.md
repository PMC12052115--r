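# triggerpp

Covariate-adjusted triggering (self-exciting) point processes for
recurrent-event prediction.

## The problem

In cohorts of patients with recurrent adverse events — the motivating
application is repeated opioid overdoses among Medicaid recipients — two
forces drive when the next event happens: stable patient-level risk
(demographics, geography, treatment status) and *self-excitation*, where
an event transiently raises the risk of the next one. Memoryless models
(Poisson regression, constant- or time-varying-rate processes) capture
only the first force. `triggerpp` fits a Hawkes-type process whose
conditional intensity for recipient *i*, in days since the recipient's
index date, is

```
lambda_i(t | H_i(t)) = theta * t^(theta-1) * exp(alpha' x_i)
                       + sum_{j : t_ij < t} beta * gamma * exp(-gamma * (t - t_ij))
```

a power-law baseline scaled log-linearly by static covariates `x_i`, plus
an exponentially decaying excitation kernel driven by the recipient's own
past events. `beta` is the branching ratio (expected directly triggered
events per event), `1/gamma` the mean lifetime of the excitation in days.
The compensator `Lambda_i(t)` is closed form, so likelihood, event-count
prediction, and the decomposition of predicted counts into
baseline-explained vs triggering-explained shares are all exact.

The package provides:

* exact log-likelihood and bounded L-BFGS-B maximum likelihood
  (`log_likelihood()`, `fit_mle()`), with AIC/BIC;
* homogeneous and non-homogeneous Poisson benchmarks under the same
  interfaces (`fit_hpp()`, `fit_nhpp()`);
* an exact cluster (branching) simulator with ground-truth
  immigrant/offspring labels, plus an independent Ogata thinning sampler
  (`simulate_cohort()`, `thinning_simulate()`);
* the replicated 80/20 hold-out protocol with per-window MAE/MAPE,
  baseline/triggering decomposition, and the one-sided t-test on the
  replicated triggering estimates (`run_replications()`,
  `triggering_significance()`);
* cohort construction from raw calendar-dated event tables with
  index-date rules and an exclusion log (`build_cohort()`), deterministic
  CSV cohort IO (`read_cohort()`, `write_cohort()`), and a small CLI
  (`inst/cli/triggerpp`: `simulate | fit | predict | evaluate |
  build-cohort`).

## Worked example

```r
library(triggerpp)

cfg    <- sim_config(n_recipients = 200, obs_length = 365, seed = 42)
cohort <- simulate_cohort(cfg)   # synthetic overdose-like cohort
fit    <- fit_mle(cohort)
print(fit)
```

```
triggering model fit (converged)
Triggering point process parameters
  theta (baseline shape): 0.1946
  alpha (covariates):     sex.male= 0.06999, age_group.35-49=-0.05683, ...
  beta  (branching ratio): 0.3306
  gamma (decay, 1/day):    0.09324
  log-lik -3426.281 | AIC 6880.56 | BIC 6950.16 (k = 14, events = 1066)
```

The generating parameters of this synthetic cohort are `theta = 0.2`,
`beta = 0.3`, `gamma = 0.1`: the fit recovers a declining baseline, about
0.33 triggered events per event, and an excitation lifetime of ~11 days.

```r
rep1 <- run_replications(cohort, windows = c(30, 90, 180), n_reps = 5, seed = 1)
print(rep1)
sig <- triggering_significance(rep1$beta_hats)
cat(sprintf("t = %.2f, p = %.2g\n", sig$t_stat, sig$p_value))
```

```
Replicated evaluation (full model): 5 replications, 160/40 split
   L   MAE MAPE_pct triggering_share
  30 2.849    2.454            0.258
  90 6.694    4.113            0.312
 180 9.320    4.890            0.319
t = 28.24, p = 4.7e-06
```

Per prediction window `L`: the mean absolute error between predicted and
realized test-set counts, the same error as a percentage, and the share
of predicted events attributable to the triggering mechanism (~31% here,
consistent with the generating branching ratio). The t-test addresses
`H0: beta = 0` across replications — see the methods vignette for why its
p-value should be read as evidence, not a calibrated error rate.

Per-recipient risk stratification uses the closed-form compensator:

```r
r <- cohort$recipients[[1]]
overdose_risk(fit$params, r, 180)   # P(>= 1 event by day 180)
#> 0.973
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's full pipeline from scratch against the installed
package — simulates the default synthetic cohort under `--seed`, fits the
triggering model and the Poisson benchmarks, runs the replicated
evaluation with its decomposition and significance test — and writes the
JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/triggering-point-process.Rmd`) documents
the model and its assumptions, the estimation choices (bounds, starts,
BIC convention, degenerate-input handling), what the synthetic-data
generator does and does not emulate, and known limitations.
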