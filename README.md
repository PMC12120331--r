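# cardiotag

Analysis pipeline for archival heart-rate tag deployments on large fish,
built around an 80-day cage deployment on an Atlantic bluefin tuna. The
package is for fish physiologists and biologging analysts who want to go
from raw 10-minute tag records — integer heart rate with a quality index,
peripheral temperature, activity — to a defensible statement about how
daily heart rate responds to temperature and feeding.

## The model

Daily median heart rate is modelled as an identity-link Poisson
regression on the daily covariates (total feed TF in tons, median
temperature TPm in °C, temperature IQR TPiq, median activity ACm in
milli-g):

    HRm_t ~ Poisson(mu_t),   mu_t = alpha + sum_i beta_i * X_{i,t}

with an optional change-point: one coefficient switches between
`beta_plus` and `beta_minus` according to whether a governing temperature
variable exceeds an estimated threshold. The best-supported structure for
this deployment is `alpha + TF:thresh + TPm` — a linear temperature
effect, plus a feeding effect that is strong below a temperature
threshold (the post-prandial specific-dynamic-action response) and
vanishes above it. All 21 nested structures are fit by MCMC
(componentwise random-walk Metropolis, 3 chains × 10,000 kept draws after
10,000 burn-in) and compared by DIC, with Gelman–Rubin convergence
checks, effective-parameter counts (pD) and R².

Because the original tag records are not publicly deposited, the package
ships a synthetic-data generator that emulates the deployment (10-minute
cadence, temperature declining 27.5 → 19 °C, feed 0–20 tons with fasting
spells, ~85% QC pass rate, deployment median heart rate ≈50 bpm), so the
full pipeline and the estimator are testable offline against known truth.

## Worked example

```r
library(cardiotag)

sim   <- simulate_deployment(deployment_config(seed = 1))
qc    <- filter_records(sim$records)
print(qc$report)
daily <- daily_summaries(qc$records, sim$feeding)
fit   <- fit_model(best_model_spec(), daily,
                   mcmc = mcmc_config(n_burn = 2000, n_keep = 5000, seed = 1))
print(fit)
```

```
QC report: 11520 records, 9888 kept (85.8%)
  dropped: 1632 by quality index, 0 HR too high, 0 HR too low
Threshold Poisson regression fit: alpha + TF:thresh + TPm
  n = 80 days; Dbar = 510.0, pD = 5.52, DIC = 515.6, R2 = 0.757
     parameter estimate     sd   q2.5   q97.5  rhat
         alpha 49.09000 0.8077 47.540 50.7100 1.001
      beta_TPm  2.09700 0.3168  1.474  2.7300 1.000
  beta_plus_TF -0.06441 0.2979 -0.652  0.5002 1.001
 beta_minus_TF  1.96500 0.1866  1.600  2.3390 1.002
        thresh 24.31000 0.4550 23.330 25.4500 1.000
```

Reading the fit: at average conditions this synthetic fish runs ~49 bpm;
each °C of warming adds ~2.1 bpm; below the ~24.3 °C threshold each ton
of feed adds ~2.0 bpm, while above it the feeding coefficient's credible
interval spans zero — feeding responses disappear in warm water. All
R-hat values sit at 1.0, so the three chains agree.

The full analysis — simulation, QC, aggregation, the 21-model DIC scan,
the best-model refit with predictions, and a parameter-recovery study —
is laid out as numbered drivers under `analysis/` (run them in order from
the repository root; outputs land in `results/`). `run_pipeline()` does
the same end to end from a single `pipeline_config()`.

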