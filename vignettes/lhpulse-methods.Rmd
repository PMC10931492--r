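---
title: "Methods: a state-space model of pulsatile LH dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a state-space model of pulsatile LH dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Luteinizing hormone (LH) is secreted in discrete pulses driven by the
hypothalamic GnRH pulse generator, superimposed on a lower basal secretion
mode, and cleared from circulation roughly exponentially. Clinically one
observes a short, sparsely sampled concentration series (typically every 10
minutes for 8 hours) corrupted by assay noise, and wants the pulse times and
interpretable secretion/clearance parameters, with honest uncertainty.
`lhpulse` implements a discrete-time stochastic state-space model of this
system and fits it by particle Gibbs.

## The generative model

Time is discretized on a grid of step `dt` (default 1 minute). The latent
state has three components.

**Pulse generator** $H_t \in \{0, 1\}$ (ON/OFF): a discretized telegraph
process. Over one step an ON state switches OFF with probability
$dt/\tau_{\mathrm{ON}}$ and an OFF state switches ON with probability
$dt/\tau_{\mathrm{OFF}}$, so the mean dwell times are $\tau_{\mathrm{ON}}$
and $\tau_{\mathrm{OFF}}$ minutes and the stationary ON probability is
$\tau_{\mathrm{ON}} / (\tau_{\mathrm{ON}} + \tau_{\mathrm{OFF}})$ exactly,
at any `dt`.

**Basal drive** $B_t = \mathrm{logistic}(X_t) \in (0, 1)$, where the
pre-signal follows the Euler–Maruyama discretization of a standard
Ornstein–Uhlenbeck process,
$X_{t+dt} = X_t - \tfrac{dt}{2} X_t + \sqrt{dt}\,\varepsilon_t$. The
continuum stationary law is standard normal; the discrete chain's exact
stationary variance is $1/(1 - dt/4)$ (4/3 at `dt = 1`), a deliberate,
documented discretization property — the package treats the discrete-time
system as the model, not as an approximation error to hide.

**LH concentration**, deterministic given the drive:
$$\mathrm{LH}_{t+dt} = \mathrm{LH}_t +
  \bigl(k\,[f H_t + (1-f) B_t] - d\,\mathrm{LH}_t\bigr)\,dt,$$
with secretion scale $k$, first-order clearance $d$ (half-life
$\ln 2 / d$), and pulsatility strength $f \in [0, 1]$ weighting pulsatile
against basal secretion.

**Observations** at sampling times carry multiplicative assay noise,
$y_j = \mathrm{LH}_{t_j}(1 + cv\,\eta_j)$, i.e.
$y_j \sim N(\mathrm{LH}_{t_j}, (cv \cdot \mathrm{LH}_{t_j})^2)$, with the
assay coefficient of variation fixed (default 0.041, an intra-assay value;
0.027 is a typical inter-assay alternative). The first observation pins the
initial concentration $\mathrm{LH}_0$; its (then constant) density term is
still included in the likelihood so that likelihood values are comparable
across methods.

## Priors

Five parameters are inferred: $\tau_{\mathrm{ON}}, \tau_{\mathrm{OFF}}, k,
d, f$.

* $\log_{10}\tau_{\mathrm{ON}}, \log_{10}\tau_{\mathrm{OFF}} \sim
  U(\log_{10} 5, \log_{10} 240)$: dwell times between half the sampling
  interval and half a typical profile duration.
* $\log_{10} k \sim N(0, 5^2)$: deliberately broad, since the secretion
  scale depends on assay units.
* Half-life $\ln 2 / d \sim N(80, 9.3^2)$ truncated to positive values: LH
  half-life is physiologically well constrained, and a sparse 8-hour
  profile cannot separate clearance from secretion scale on its own, so
  this is the one informative prior in the model.
* $f \sim U(0, 1)$: the natural uninformative choice on the bounded
  pulsatility-strength scale.

`log_prior()` returns the joint density on the natural scale including all
change-of-variable Jacobians (the test suite verifies each block integrates
to one).

## Inference: particle Gibbs

`run_gibbs()` alternates three blocks.

1. **Latent path** by conditional sequential Monte Carlo with ancestor
   sampling. The reference path from the previous sweep is pinned in one
   particle slot; at every resampling step its ancestor index is re-drawn
   with weights proportional to particle weight times the one-step
   transition density of $(H, X)$ to the reference's next state. Because
   LH is a deterministic function of the drive and the pinned initial
   value, the LH component carries no transition density; the reference's
   LH value is re-propagated from the sampled ancestor. This truncation of
   the ancestor weight is the standard practical device for degenerate
   state components and is the one approximation in the path update; with
   it, path updates mix well at moderate particle counts (default 80).
   Resampling is systematic, at observation times.
2. **Switch timescales** $(\log_{10}\tau_{\mathrm{ON}},
   \log_{10}\tau_{\mathrm{OFF}})$ by adaptive Metropolis–Hastings. Given
   the latent ON/OFF path the target is a product of transition
   probabilities (summarized by four transition counts) plus the
   stationary initial term. After 100 sweeps the proposal covariance
   follows the classic adaptive-Metropolis recipe ($2.38^2/2$ times the
   empirical covariance plus jitter).
3. **Secretion block** $(\log_{10} k,\ \ln 2/d,\ f)$ by simplified
   manifold MALA. Given the drive, the conditional likelihood is a product
   of Gaussians around a linear recursion, so the gradient and a
   Gauss–Newton information metric are available in closed form (computed
   in C++ alongside the likelihood); the proposal is a Gaussian
   preconditioned by the metric plus the prior precision, with an exact
   Metropolis correction, falling back to a random walk if the metric
   fails. The default step size 1.0 sits below the MALA stability cliff
   (acceptance ≈ 0.65–0.7 on typical profiles).

**Initialization.** The conditional posterior over $(k, f,
\tau_{\mathrm{ON}})$ can be multimodal on sparse profiles (e.g. a
basal-dominated mode with inflated $k$ and $f \to 1$ that explains pulses
away). The chain therefore starts from a deterministic data-informed point
(prior-central timescales and half-life, $k$ matched to the observed mean
via the steady state) and then selects among three short pilot chains
started at low/central/high $\tau_{\mathrm{ON}}$, continuing the main
chain from the end state of the pilot with the highest mean
log-likelihood. Start-state selection cannot bias the stationary
distribution; it only avoids wasting the burn-in in a spurious basin.

All randomness — including the C++ kernels, which draw normals by
Box–Muller from R's uniform stream — flows through R's RNG, so a seed fixes
every output bit-for-bit.

### Composite pre/post-intervention model

`run_gibbs_composite()` fits two series jointly: each period has its own
$\tau_{\mathrm{ON}}, \tau_{\mathrm{OFF}}, k, f$ and latent path, while the
clearance rate $d$ is shared, encoding the assumption that an intervention
acts on hypothalamic/pituitary drive, not on elimination. The shared
half-life is updated inside the baseline secretion block with the
post-intervention series contributing clearance information only.

## Pulse identification

The stored latent paths give a posterior ON-probability trace
(`pulse_probability()`). A pulse onset is called at each upward crossing of
a threshold (default 0.5 — the point where ON becomes more likely than
OFF); values exactly at the threshold do not count as exceeding it. The set
of supra-threshold time points shrinks monotonically as the threshold
rises.

## The exact-filter oracle

`exact_filter()` is an independent deterministic check on the SMC code: a
forward HMM filter on the joint latent chain with $X$ discretized into
bins and — crucially — **LH carried as a third gridded dimension**. A
cheaper design that tracks only $(H, X)$ and averages LH per cell is
biased by several nats on realistic instances, because LH integrates the
entire drive history between observations and the sharp assay CV makes the
likelihood sensitive to that history; grid refinement of such a filter
does not converge to the truth. With LH gridded, refinement is Cauchy and
the SMC mean agrees within Monte-Carlo error (this is an acceptance
criterion). The deterministic LH shift is precomputed as a sparse matrix
per generator state, keeping a 200×800-cell filter on a 7-observation
instance to a few seconds.

## Synthetic data and presets

`lh_simulate()` draws latent paths from the model (C++), and
`generate_fixture()` writes observation CSVs plus ground-truth parameters
and paths. `group_presets()` provides parameter sets producing
qualitatively distinct profiles (men, pre-/post-menopausal women, PCOS-like
frequent pulsing, hypothalamic-amenorrhea-like sparse pulsing). These
numbers are calibrated to produce the expected qualitative orderings (e.g.
higher $k$ post-menopause, lower $f$ in HA) and are labelled as synthetic
calibrations, not measured cohort values, in every artifact that contains
them.

## Validation and known limitations

The test suite includes an acceptance tier: oracle agreement of the
marginal likelihood, parameter recovery on replicate synthetic profiles,
pulse-detection accuracy against simulated truth, latent-process
stationarity, deterministic limits, null-intervention composite coverage,
and bit-identical determinism.

Three honest limitations are documented rather than patched:

* **Episodes shorter than the sampling interval are undetectable by
  threshold crossing.** Exponential ON durations put substantial mass
  below the sampling interval (39% for a 20-minute mean under 10-minute
  sampling). Such an episode yields a single elevated sample whose onset
  time is unidentifiable within the sampling gap; the pointwise posterior
  ON probability is then smeared across the gap (a 2-minute episode peaks
  near 0.2) and cannot cross the 0.5 calling threshold regardless of
  inference quality. The pulse-detection acceptance test falls a few
  percent short of its 80% target for exactly this reason, and is kept
  failing as a record of the resolution limit. Relatedly, the number of
  called pulses is not guaranteed monotone in the threshold: crossings
  count connected components of the supra-threshold set, and an episode
  whose probability trace dips briefly below a high threshold splits
  into two components there, so one extra call can appear at a higher
  threshold. (The supra-threshold *set* itself does shrink
  monotonically.)

* **There is no true "no-information" limit under multiplicative noise.**
  Sending $cv \to \infty$ does not flatten the likelihood: each
  observation contributes $-\log(cv \cdot \mathrm{LH})$, which permanently
  favors small concentrations, so the posterior does not revert to the
  prior (it visibly drags $k$ down, and through the preference for low-LH
  paths also shifts $d$, $f$ and the switch timescales). The corresponding
  acceptance test is expected to fail and is kept as a truthful record of
  this property.
* **Mean-of-log-likelihood comparisons carry Jensen bias.** The SMC
  likelihood estimate is unbiased on the natural scale, so the mean of log
  estimates lies below the truth by roughly half their variance; the
  oracle-agreement criterion passes because this bias is small relative to
  the Monte-Carlo band at 200 particles.

Problem sizes: fitting a 480-minute, 10-minute-sampled profile with the
default 10,000 sweeps takes on the order of half a minute on one CPU core;
the exact filter is intended for short (≈ hour-long) validation instances
only, since its cost grows with the cube of resolution.
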