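test_that("onsets are upward threshold crossings", {
  p_on <- c(0.2, 0.6, 0.7, 0.4, 0.6, 0.1)
  times <- seq(0, 50, by = 10)
  expect_equal(identify_pulses(p_on, times, 0.5), c(10, 40))
  # trace starting above threshold: onset at the first grid point
  expect_equal(identify_pulses(c(0.8, 0.2, 0.9), c(0, 5, 10), 0.5),
               c(0, 10))
  # values exactly at the threshold do not count as exceeding it
  expect_equal(identify_pulses(rep(0.5, 4), 0:3, 0.5), numeric(0))
  expect_equal(identify_pulses(c(0.1, 0.2, 0.3), 0:2, 0.5), numeric(0))
  expect_error(identify_pulses(c(0.2, 1.4), 0:1, 0.5), "p_on")
  expect_error(identify_pulses(c(0.2, 0.4), 0:1, 0), "threshold")
})

test_that("raising the threshold shrinks the supra-threshold set", {
  set.seed(1)
  p_on <- pmin(pmax(stats::filter(runif(200), rep(1 / 5, 5),
                                  sides = 1)[-(1:4)], 0), 1)
  for (pair in list(c(0.3, 0.5), c(0.5, 0.7), c(0.7, 0.9))) {
    hi <- p_on > pair[2]
    lo <- p_on > pair[1]
    expect_true(all(lo[hi])) # every point above hi is above lo
  }
})

test_that("inter-pulse intervals and their edge cases", {
  iv <- interpulse_intervals(c(10, 70, 150))
  expect_equal(iv$intervals, c(60, 80))
  expect_equal(iv$mean, 70)
  expect_equal(iv$sd, sd(c(60, 80)))
  expect_true(is.na(interpulse_intervals(c(10))$mean))
  expect_length(interpulse_intervals(numeric(0))$intervals, 0)
  expect_true(is.na(interpulse_intervals(c(10, 70))$sd))
  expect_error(interpulse_intervals(c(70, 10)), "increasing")
})

test_that("pulse probability is the mean of stored paths", {
  sim <- lh_simulate(canon_params(), 60, 10, seed = 26)
  cfg <- gibbs_config(n_iterations = 40, burn_in = 10, thin = 2,
                      n_particles = 30, seed = 5, store_latent_every = 1)
  fit <- quiet_gibbs(sim$series, config = cfg)
  p_on <- pulse_probability(fit)
  expect_length(p_on, 61)
  expect_equal(p_on, colMeans(fit$latent$h))
  expect_true(all(p_on >= 0 & p_on <= 1))
  fit$latent$h <- fit$latent$h[0, , drop = FALSE]
  expect_error(pulse_probability(fit), "stored latent")
})

test_that("pulse calls delimit supra-threshold episodes", {
  sim <- lh_simulate(canon_params(), 60, 10, seed = 27)
  cfg <- gibbs_config(n_iterations = 40, burn_in = 10, thin = 2,
                      n_particles = 30, seed = 6, store_latent_every = 1)
  fit <- quiet_gibbs(sim$series, config = cfg)
  calls <- pulse_calls(fit, threshold = 0.5)
  expect_s3_class(calls, "lh_pulses")
  expect_equal(calls$onsets, calls$episodes$onset_min)
  if (nrow(calls$episodes)) {
    expect_true(all(calls$episodes$end_min >= calls$episodes$onset_min))
    expect_true(all(calls$episodes$max_p_on > 0.5))
  }
  expect_equal(calls$intervals, diff(calls$onsets))
})

test_that("posterior summaries match direct quantile computation", {
  sim <- lh_simulate(canon_params(), 60, 10, seed = 28)
  cfg <- gibbs_config(n_iterations = 60, burn_in = 10, thin = 2,
                      n_particles = 30, seed = 7)
  fit <- quiet_gibbs(sim$series, config = cfg)
  sm <- summarize_posterior(fit)
  expect_equal(sm$parameter, c("tau_on", "tau_off", "k", "d", "f"))
  i <- which(sm$parameter == "k")
  expect_equal(sm$median[i], unname(quantile(fit$draws$k, 0.5, type = 7)))
  expect_equal(sm$q05[i], unname(quantile(fit$draws$k, 0.05, type = 7)))
  expect_equal(sm$q95[i], unname(quantile(fit$draws$k, 0.95, type = 7)))
  expect_equal(sm$mean[i], mean(fit$draws$k))
  expect_equal(sm$mean_log10[i], mean(log10(fit$draws$k)))
})
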