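test_that("prior draws respect their supports", {
  set.seed(1)
  pr <- lh_priors()
  d <- sample_prior(pr, n = 500)
  expect_true(all(d$tau_on >= 5 & d$tau_on <= 240))
  expect_true(all(d$tau_off >= 5 & d$tau_off <= 240))
  expect_true(all(d$k > 0))
  expect_true(all(d$f >= 0 & d$f <= 1))
  expect_true(all(log(2) / d$d > 0))
  one <- sample_prior(pr, n = 1)
  expect_s3_class(one, "lh_params")
})

test_that("prior draws match the stated marginals", {
  set.seed(2)
  d <- sample_prior(lh_priors(), n = 4000)
  # log10 tau_on uniform on [log10 5, log10 240]
  expect_gt(ks.test(log10(d$tau_on), "punif", log10(5), log10(240))$p.value,
            0.001)
  # half-life ~ N(80, 9.3) (truncation at 0 is ~8.6 sd away, negligible)
  expect_gt(ks.test(log(2) / d$d, "pnorm", 80, 9.3)$p.value, 0.001)
  expect_gt(ks.test(d$f, "punif")$p.value, 0.001)
  expect_gt(ks.test(log10(d$k), "pnorm", 0, 5)$p.value, 0.001)
})

test_that("log prior density matches the generative marginals", {
  pr <- lh_priors()
  p <- canon_params()
  lp <- log_prior(p, pr)
  # independent blocks, each with its change-of-variables Jacobian
  manual <-
    -log(p$tau_on * log(10) * (log10(240) - log10(5))) -
    -log(1) - log(p$tau_off * log(10) * (log10(240) - log10(5))) +
    dnorm(log10(p$k), 0, 5, log = TRUE) - log(p$k * log(10)) +
    dnorm(log(2) / p$d, 80, 9.3, log = TRUE) -
    log(pnorm(0, 80, 9.3, lower.tail = FALSE)) +
    log(log(2) / p$d^2) + 0
  expect_equal(lp, manual, tolerance = 1e-12)
  expect_identical(log_prior(canon_params(tau_on = 239.9), pr),
                   log_prior(canon_params(tau_on = 239.9), pr))
  expect_identical(log_prior(modifyList(unclass(p), list(tau_on = 300)), pr),
                   -Inf)
  expect_identical(log_prior(modifyList(unclass(p), list(f = 1.1)), pr),
                   -Inf)
  expect_identical(log_prior(modifyList(unclass(p), list(d = -0.1)), pr),
                   -Inf)
})

test_that("log prior is a proper density on the natural scale", {
  pr <- lh_priors()
  base <- unclass(canon_params())
  at <- function(nm, v)
    exp(log_prior(modifyList(base, setNames(list(v), nm)), pr))
  # each univariate slice, renormalized by the other blocks, integrates to 1
  rest_tau <- at("tau_on", base$tau_on) *
    (base$tau_on * log(10) * (log10(240) - log10(5)))
  expect_equal(integrate(Vectorize(function(t) at("tau_on", t)), 5, 240,
                         rel.tol = 1e-9)$value / rest_tau, 1,
               tolerance = 1e-7)
  rest_f <- at("f", base$f) # f prior density is 1 on [0, 1]
  expect_equal(integrate(Vectorize(function(v) at("f", v)), 0, 1,
                         rel.tol = 1e-9)$value / rest_f, 1,
               tolerance = 1e-7)
  rest_k <- at("k", base$k) /
    (dnorm(log10(base$k), 0, 5) / (base$k * log(10)))
  # integrating from 1e-12 leaves out exactly pnorm(-12/5) of prior mass
  expect_equal(integrate(Vectorize(function(v) at("k", v)), 1e-12, Inf,
                         rel.tol = 1e-9)$value / rest_k, pnorm(12 / 5),
               tolerance = 1e-4)
})

test_that("working-scale secretion prior agrees with the natural one", {
  pr <- lh_priors()
  p1 <- canon_params()
  p2 <- canon_params(k = 0.4, d = log(2) / 70, f = 0.3)
  # differences must match once Jacobians between the two scales cancel:
  # d log-prior difference on working scale equals natural-scale difference
  # plus the Jacobian terms of the (log10 k, half-life) transformation
  w <- function(p) log_prior_working_sec(log10(p$k), log(2) / p$d, p$f, pr)
  jac <- function(p) -log(p$k * log(10)) + log(log(2) / p$d^2)
  expect_equal(w(p1) - w(p2),
               (log_prior(p1, pr) - jac(p1)) -
               (log_prior(p2, pr) - jac(p2)),
               tolerance = 1e-10)
  expect_identical(w(canon_params(f = 1)), w(canon_params(f = 1)))
  expect_identical(log_prior_working_sec(0, -5, 0.5, pr), -Inf)
})
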