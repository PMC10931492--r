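# lhpulse

Bayesian inference of pulsatile luteinizing hormone (LH) dynamics from
sparse serum profiles.

LH is secreted in discrete pulses driven by the hypothalamic GnRH pulse
generator, on top of a lower basal mode, and cleared roughly
exponentially. Given a short profile (typically one sample every 10
minutes for 8 hours) corrupted by assay noise, `lhpulse` infers:

* when the pulse generator was ON (a posterior probability trace over
  time, with threshold-based pulse calls),
* interpretable physiology — switch timescales τ<sub>ON</sub>,
  τ<sub>OFF</sub>, secretion scale *k*, clearance rate *d* (half-life
  ln 2 / *d*), and pulsatility strength *f* — with full posterior
  uncertainty.

The generative model is a discrete-time state-space system: a two-state
telegraph process for the pulse generator, a logistic-squashed
Ornstein–Uhlenbeck basal drive, a deterministic secretion/clearance
equation

```
LH' = LH + (k (f·H + (1−f)·B) − d·LH) dt
```

and multiplicative Gaussian assay noise with fixed coefficient of
variation (default 0.041). Inference is by particle Gibbs: conditional
sequential Monte Carlo with ancestor sampling for the latent path,
adaptive Metropolis–Hastings for the switch timescales, and a simplified
manifold MALA step (analytic gradient + Gauss–Newton metric) for
(*k*, *d*, *f*). A composite model fits pre-/post-intervention series
jointly with a shared clearance rate. An exact grid-filter oracle, a
synthetic-profile generator with clinical-group presets, and a CLI are
included. See `vignette("lhpulse-methods")` for the full model and
sampler description.

## Worked example

```r
library(lhpulse)

# simulate an 8-hour profile, sampled every 10 min, from the
# pre-menopausal preset (tau_on 20, tau_off 60, k 0.15, half-life 80, f 0.8)
sim <- lh_simulate(group_presets()$pre_menopausal, duration = 480,
                   sample_interval = 10, seed = 42)
print(sim$series)
#> LH series [sim]: 49 observations, 0-480 min, median 4.87 IU/L

cfg <- gibbs_config(n_iterations = 4000, burn_in = 1000, thin = 5,
                    seed = 1, store_latent_every = 1)
fit <- run_gibbs(sim$series, config = cfg)
print(fit)
#> LH particle-Gibbs posterior: 600 retained draws (4000 sweeps)
#>   acceptance: switch 0.28, secretion 0.72; 600 stored paths
#>  parameter         mean       median          q05         q95
#>     tau_on 14.025573361 12.493364408  6.508320970 25.54808857
#>    tau_off 39.926667960 35.385858911 19.526607398 73.88396777
#>          k  0.156029498  0.152163628  0.135874172  0.19028238
#>          d  0.008791616  0.008584805  0.007392145  0.01083794
#>          f  0.822441242  0.823725724  0.719161632  0.91434252

calls <- pulse_calls(fit, threshold = 0.5)
print(calls)
#> 7 pulse(s) called at threshold 0.50: onsets at 0, 40, 167, 240, 383, 412, 449 min
#>   mean inter-pulse interval 74.8 min
```

All five true parameters fall inside their 90% credible intervals, and
the called onsets track the simulated generator's ON episodes.
`write_lh_outputs(fit, calls, "outdir")` writes parameter draws,
summaries, the pulse-probability trace, pulse calls (CSV and BED-like)
and a JSON manifest from which the run is bit-for-bit reproducible.

## Command line

```sh
lhpulse simulate --preset pre_menopausal --n 5 --seed 1 --out profiles/
lhpulse fit --input profiles/subject_01.csv --out fit01/ --seed 7
lhpulse pulses --fit-dir fit01/ --threshold 0.6
lhpulse compare --pre baseline.csv --post treated.csv --out cmp/
```

Input CSVs need `time_min` and `lh_iu_l` columns. Options may also be
given in a YAML config file (`--config`); command line beats config
beats defaults. `compare` fits the composite pre/post model in which an
intervention may change drive and secretion but not clearance.

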