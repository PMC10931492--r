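test_that("running covariance matches cov()", {
  set.seed(1)
  xs <- matrix(rnorm(60), 30, 2)
  st <- lhpulse:::adapt_init(2)
  for (i in 1:30) st <- lhpulse:::adapt_update(st, xs[i, ])
  expect_equal(st$n, 30L)
  expect_equal(st$mean, colMeans(xs))
  expect_equal(lhpulse:::adapt_cov(st), unname(cov(xs)), tolerance = 1e-12)
})

test_that("transition counts are exact", {
  h <- c(1, 1, 0, 0, 0, 1, 0, 1, 1)
  expect_equal(lhpulse:::transition_counts(h),
               c(n11 = 2, n10 = 2, n01 = 2, n00 = 2))
})

test_that("switch log posterior matches direct enumeration", {
  h <- c(1, 1, 0, 0, 1)
  p <- canon_params()
  pr <- lh_priors()
  lp <- lhpulse:::switch_logpost(c(log10(20), log10(60)),
                                 lhpulse:::transition_counts(h), h[1], 1, pr)
  direct <- log(20 / 80) +       # stationary start in ON
    log(1 - 1 / 20) +            # 1 -> 1
    log(1 / 20) +                # 1 -> 0
    log(1 - 1 / 60) +            # 0 -> 0
    log(1 / 60)                  # 0 -> 1
  expect_equal(lp, direct, tolerance = 1e-12)
  expect_identical(
    lhpulse:::switch_logpost(c(log10(300), log10(60)),
                             lhpulse:::transition_counts(h), h[1], 1, pr),
    -Inf)
})

test_that("switch update with no latent path samples the prior", {
  # latent = NULL makes the target the flat prior on log10 tau: a long
  # MH chain must reproduce the uniform distribution on [log10 5, log10 240]
  set.seed(42)
  p <- canon_params()
  st <- NULL
  out <- matrix(NA_real_, 3000, 2)
  for (i in seq_len(nrow(out))) {
    up <- update_switch_params(p, latent = NULL, adapt_state = st,
                               proposal_sd = 0.5)
    p$tau_on <- up$tau_on; p$tau_off <- up$tau_off
    st <- up$adapt_state
    out[i, ] <- c(log10(p$tau_on), log10(p$tau_off))
  }
  thin <- out[seq(500, nrow(out), by = 5), ]
  # MH rejections leave ties; the KS p-value is still a valid rough check
  ks <- function(x, ...) suppressWarnings(ks.test(x, ...))$p.value
  expect_gt(ks(thin[, 1], "punif", log10(5), log10(240)), 0.001)
  expect_gt(ks(thin[, 2], "punif", log10(5), log10(240)), 0.001)
})

test_that("switch update concentrates on the path-implied timescales", {
  # a long path simulated at known timescales should pull the sampler
  # toward them
  set.seed(7)
  truth <- canon_params()
  lat <- lh_simulate(truth, 6000, 10)$path
  p <- canon_params(tau_on = 60, tau_off = 20) # start far away
  st <- NULL
  keep <- matrix(NA_real_, 800, 2)
  for (i in seq_len(1200)) {
    up <- update_switch_params(p, latent = lat, adapt_state = st)
    p$tau_on <- up$tau_on; p$tau_off <- up$tau_off
    st <- up$adapt_state
    if (i > 400) keep[i - 400, ] <- c(p$tau_on, p$tau_off)
  }
  expect_lt(abs(median(keep[, 1]) - 20) / 20, 0.35)
  expect_lt(abs(median(keep[, 2]) - 60) / 60, 0.35)
})

test_that("secretion gradient matches finite differences", {
  set.seed(3)
  sim <- lh_simulate(canon_params(), 120, 10, seed = 3)
  g <- lhpulse:::series_grid(sim$series, 1)
  pr <- lh_priors()
  ctx <- list(list(y = sim$series$values, obs_idx = g$obs_idx,
                   h = as.integer(sim$path$h), b = sim$path$b,
                   lh0 = sim$series$values[1], cv = 0.041, dt = 1))
  w <- c(log10(0.15), 80, 0.8)
  res <- lhpulse:::sec_logpost_grad(w, 1:3, ctx, pr)
  eps <- 1e-6
  for (j in 1:3) {
    wp <- w; wp[j] <- wp[j] + eps
    wm <- w; wm[j] <- wm[j] - eps
    fd <- (lhpulse:::sec_logpost_grad(wp, 1:3, ctx, pr)$lp -
           lhpulse:::sec_logpost_grad(wm, 1:3, ctx, pr)$lp) / (2 * eps)
    expect_equal(res$grad[j], fd, tolerance = 1e-4)
  }
  # Gauss-Newton metric is symmetric positive definite
  expect_equal(res$G, t(res$G), tolerance = 1e-10)
  expect_true(all(eigen(res$G, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("free-coordinate masking pins the other coordinates", {
  set.seed(4)
  sim <- lh_simulate(canon_params(), 120, 10, seed = 4)
  g <- lhpulse:::series_grid(sim$series, 1)
  pr <- lh_priors()
  ctx <- list(list(y = sim$series$values, obs_idx = g$obs_idx,
                   h = as.integer(sim$path$h), b = sim$path$b,
                   lh0 = sim$series$values[1], cv = 0.041, dt = 1))
  w <- c(log10(0.15), 80, 0.8)
  full <- lhpulse:::sec_logpost_grad(w, 1:3, ctx, pr)
  sub <- lhpulse:::sec_logpost_grad(w, c(1, 3), ctx, pr)
  expect_equal(sub$lp, full$lp)
  expect_equal(sub$grad, full$grad[c(1, 3)])
  expect_equal(sub$G, full$G[c(1, 3), c(1, 3)])
})

test_that("a clearance-only context contributes no k or f information", {
  set.seed(5)
  sim <- lh_simulate(canon_params(), 120, 10, seed = 5)
  g <- lhpulse:::series_grid(sim$series, 1)
  pr <- lh_priors()
  base <- list(y = sim$series$values, obs_idx = g$obs_idx,
               h = as.integer(sim$path$h), b = sim$path$b,
               lh0 = sim$series$values[1], cv = 0.041, dt = 1)
  shared <- c(base, list(own = FALSE, k_fixed = 0.3, f_fixed = 0.5))
  w <- c(log10(0.15), 80, 0.8)
  res <- lhpulse:::sec_logpost_grad(w, 1:3, list(shared), pr)
  # only prior information in the k and f coordinates
  expect_equal(res$G[1, 1], 1e-8 + 1 / pr$log10_k_sd^2)
  expect_equal(res$G[3, 3], 1e-8 + 12 / diff(pr$f_bounds)^2)
  expect_gt(res$G[2, 2], 1 / pr$halflife_sd^2) # data inform the half-life
})

test_that("sMMALA preserves a known Gaussian target", {
  # target N(mu, sd^2) with exact gradient and metric: the chain mean and
  # variance must match
  mu <- 2; s2 <- 0.5^2
  lg <- function(w) list(lp = -0.5 * (w - mu)^2 / s2,
                         grad = -(w - mu) / s2,
                         G = matrix(1 / s2, 1, 1))
  set.seed(10)
  w <- 0; out <- numeric(4000)
  for (i in seq_along(out)) {
    st <- lhpulse:::smmala_step(w, lg, step = 1.2, rw_sd = 0.5)
    w <- st$w
    out[i] <- w
  }
  keep <- out[-(1:200)]
  expect_lt(abs(mean(keep) - mu), 0.05)
  expect_lt(abs(var(keep) - s2) / s2, 0.15)
})

test_that("sMMALA falls back to a random walk on a broken metric", {
  lg <- function(w) list(lp = -0.5 * sum(w^2), grad = -w,
                         G = matrix(NaN, 1, 1))
  set.seed(11)
  st <- lhpulse:::smmala_step(0.3, lg, step = 1, rw_sd = 0.1)
  expect_true(st$fallback)
  expect_true(is.finite(st$w))
})

test_that("prior-only secretion update targets the prior", {
  set.seed(12)
  p <- canon_params()
  out <- matrix(NA_real_, 4000, 3)
  for (i in seq_len(nrow(out))) {
    up <- suppressWarnings(
      update_secretion_params(p, latent = NULL, series = NULL, step = 1))
    p$k <- up$k; p$d <- up$d; p$f <- up$f
    out[i, ] <- c(log10(p$k), log(2) / p$d, p$f)
  }
  thin <- out[seq(500, 4000, by = 7), ]
  expect_gt(ks.test(thin[, 2], "pnorm", 80, 9.3)$p.value, 0.001)
  expect_gt(ks.test(thin[, 3], "punif")$p.value, 0.001)
  expect_gt(ks.test(thin[, 1], "pnorm", 0, 5)$p.value, 0.001)
})
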