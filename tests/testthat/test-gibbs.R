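test_that("configuration is validated", {
  expect_s3_class(gibbs_config(), "gibbs_config")
  expect_error(gibbs_config(n_particles = 1), "n_particles")
  expect_error(gibbs_config(n_iterations = 100, burn_in = 200), "burn")
  expect_error(gibbs_config(thin = 0), "thin")
})

test_that("bookkeeping: retained draws and stored paths have stated sizes", {
  sim <- lh_simulate(canon_params(), 120, 10, seed = 21)
  cfg <- gibbs_config(n_iterations = 61, burn_in = 11, thin = 10,
                      n_particles = 30, seed = 2, store_latent_every = 2)
  fit <- quiet_gibbs(sim$series, config = cfg)
  expect_s3_class(fit, "lh_posterior")
  expect_equal(nrow(fit$draws), 5) # (61 - 11) %/% 10
  expect_named(fit$draws, c("tau_on", "tau_off", "k", "d", "f", "loglik"))
  expect_equal(nrow(fit$latent$h), 2) # every 2nd retained draw
  expect_equal(ncol(fit$latent$h), 121)
  expect_true(all(fit$latent$h %in% 0:1))
  expect_true(all(fit$draws$tau_on >= 5 & fit$draws$tau_on <= 240))
  expect_true(all(fit$draws$f >= 0 & fit$draws$f <= 1))
})

test_that("a minimal chain still stores one latent path", {
  sim <- lh_simulate(canon_params(), 60, 10, seed = 22)
  cfg <- gibbs_config(n_iterations = 12, burn_in = 2, thin = 10,
                      n_particles = 20, seed = 3)
  fit <- quiet_gibbs(sim$series, config = cfg)
  expect_equal(nrow(fit$draws), 1)
  expect_equal(nrow(fit$latent$h), 1)
})

test_that("identical config and data give bit-identical posteriors", {
  sim <- lh_simulate(canon_params(), 120, 10, seed = 23)
  cfg <- gibbs_config(n_iterations = 80, burn_in = 20, thin = 5,
                      n_particles = 30, seed = 9)
  f1 <- quiet_gibbs(sim$series, config = cfg)
  f2 <- quiet_gibbs(sim$series, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$latent, f2$latent)
  cfg2 <- gibbs_config(n_iterations = 80, burn_in = 20, thin = 5,
                       n_particles = 30, seed = 10)
  f3 <- quiet_gibbs(sim$series, config = cfg2)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("composite fit shares clearance and keeps periods separate", {
  p <- canon_params()
  pre <- lh_simulate(p, 120, 10, seed = 24)$series
  post <- lh_simulate(p, 120, 10, seed = 25)$series
  cfg <- gibbs_config(n_iterations = 60, burn_in = 10, thin = 5,
                      n_particles = 30, seed = 4)
  fit <- suppressWarnings(run_gibbs_composite(pre, post, config = cfg))
  expect_s3_class(fit, "lh_posterior_composite")
  expect_true(all(c("tau_on_pre", "tau_off_pre", "k_pre", "f_pre",
                    "tau_on_post", "tau_off_post", "k_post", "f_post",
                    "d") %in% names(fit$draws)))
  # exactly one clearance column: shared by construction
  expect_equal(sum(grepl("^d", names(fit$draws))), 1)
  expect_equal(nrow(fit$draws), 10)
  # both periods' latent paths stored
  expect_true(all(c("h_pre", "h_post") %in% names(fit$latent)))
  expect_true(all(fit$latent$h_pre %in% 0:1))
  # reproducibility holds for the composite sampler too
  fit2 <- suppressWarnings(run_gibbs_composite(pre, post, config = cfg))
  expect_identical(fit$draws, fit2$draws)
})

test_that("acceptance-rate warning fires when rates are pathological", {
  expect_warning(lhpulse:::check_acceptance(c(switch = 0.01, secretion = 0.3)),
                 "acceptance")
  expect_silent(lhpulse:::check_acceptance(c(switch = 0.3, secretion = 0.3)))
})
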