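# Shared helpers for the test suite.

# canonical parameter set used throughout: 20/60 min switch timescales,
# 80-min half-life, moderate secretion, strong pulsatility
canon_params <- function(...) {
  p <- lh_params(tau_on = 20, tau_off = 60, k = 0.15, d = log(2) / 80,
                 f = 0.8)
  mod <- list(...)
  for (nm in names(mod)) p[[nm]] <- mod[[nm]]
  validate_params(p)
  p
}

# a small deterministic series for filter tests
tiny_series <- function(n_obs = 7, interval = 10, seed = 1,
                        params = canon_params(k = 1)) {
  lh_simulate(params, duration = (n_obs - 1) * interval,
              sample_interval = interval, seed = seed)$series
}

quiet_gibbs <- function(...) suppressWarnings(run_gibbs(...))
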