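# Parameter-block updates used inside the Gibbs sweep.

# --- adaptive Metropolis-Hastings for (tau_on, tau_off) -----------------

adapt_init <- function(d = 2) {
  list(n = 0L, mean = numeric(d), m2 = matrix(0, d, d))
}

adapt_update <- function(state, x) {
  n <- state$n + 1L
  delta <- x - state$mean
  mean <- state$mean + delta / n
  m2 <- state$m2 + outer(delta, x - mean)
  list(n = n, mean = mean, m2 = m2)
}

adapt_cov <- function(state) state$m2 / max(state$n - 1L, 1L)

# Log posterior of (log10 tau_on, log10 tau_off) given an H path: product of
# telegraph transition probabilities plus the stationary initial-state term;
# the prior is flat on the log10 scale inside its bounds.
switch_logpost <- function(l10, counts, h1, dt, prior, include_init = TRUE) {
  tau_on <- 10^l10[1]; tau_off <- 10^l10[2]
  if (l10[1] < log10(prior$tau_on_bounds[1]) ||
      l10[1] > log10(prior$tau_on_bounds[2]) ||
      l10[2] < log10(prior$tau_off_bounds[1]) ||
      l10[2] > log10(prior$tau_off_bounds[2])) return(-Inf)
  if (dt / tau_on >= 1 || dt / tau_off >= 1) return(-Inf)
  if (is.null(counts)) return(0)
  ll <- counts["n11"] * log1p(-dt / tau_on) +
    counts["n10"] * log(dt / tau_on) +
    counts["n01"] * log(dt / tau_off) +
    counts["n00"] * log1p(-dt / tau_off)
  if (include_init)
    ll <- ll + log((if (h1 == 1) tau_on else tau_off) / (tau_on + tau_off))
  unname(ll)
}

transition_counts <- function(h) {
  a <- h[-length(h)]; b <- h[-1]
  c(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
    n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
}

#' Adaptive Metropolis-Hastings update of the switch timescales
#'
#' One MH step on `(log10 tau_on, log10 tau_off)` targeting the conditional
#' posterior given the current latent on/off path: the product of telegraph
#' transition probabilities along the path (plus the stationary initial-state
#' probability) times the flat-on-log10 prior. The proposal is Gaussian; once
#' enough draws have accumulated its covariance follows the classic
#' adaptive-Metropolis recipe, `2.38^2 / 2` times the empirical covariance of
#' past draws plus a small jitter.
#'
#' @param params Current [lh_params()].
#' @param latent Latent path (list with `h` on the `dt` grid), or `NULL` to
#'   target the prior alone (useful for sampler validation).
#' @param prior An [lh_priors()] object.
#' @param adapt_state Adaptation state from a previous call, or `NULL`.
#' @param adapt_start Number of updates before the adaptive covariance kicks
#'   in.
#' @param proposal_sd Standard deviation of the pre-adaptation proposal (per
#'   log10 coordinate).
#' @return List with `tau_on`, `tau_off`, `accept` (logical) and
#'   `adapt_state`.
#' @export
update_switch_params <- function(params, latent, prior = lh_priors(),
                                 adapt_state = NULL, adapt_start = 100,
                                 proposal_sd = 0.1) {
  if (is.null(adapt_state)) adapt_state <- adapt_init()
  counts <- NULL; h1 <- 1L
  if (!is.null(latent)) {
    counts <- transition_counts(latent$h)
    h1 <- latent$h[1]
  }
  cur <- c(log10(params$tau_on), log10(params$tau_off))
  lp_cur <- switch_logpost(cur, counts, h1, params$dt, prior)
  if (adapt_state$n >= adapt_start) {
    S <- 2.38^2 / 2 * (adapt_cov(adapt_state) + diag(1e-6, 2))
    prop <- cur + drop(rnorm(2) %*% chol(S))
  } else {
    prop <- cur + rnorm(2, sd = proposal_sd)
  }
  lp_prop <- switch_logpost(prop, counts, h1, params$dt, prior)
  accept <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur
  new <- if (accept) prop else cur
  adapt_state <- adapt_update(adapt_state, new)
  list(tau_on = 10^new[1], tau_off = 10^new[2], accept = accept,
       adapt_state = adapt_state)
}

# --- simplified manifold MALA for (k, d, f) -----------------------------

# Generic sMMALA step. logpost_grad(w) must return list(lp, grad, G) with G
# positive definite (the local information metric). The proposal is
# N(w + step^2/2 G^-1 grad, step^2 G^-1); the MH correction uses the exact
# proposal densities, so the target is preserved whatever metric is used.
# On numerical failure the step falls back to a symmetric random walk.
smmala_step <- function(w, logpost_grad, step, rw_sd) {
  cur <- logpost_grad(w)
  ok <- is.finite(cur$lp) && all(is.finite(cur$grad)) &&
    all(is.finite(cur$G))
  R <- if (ok) tryCatch(chol(cur$G), error = function(e) NULL) else NULL
  if (is.null(R)) {
    prop <- w + rnorm(length(w), sd = rw_sd)
    lp_prop <- logpost_grad(prop)$lp
    accept <- is.finite(lp_prop) && log(runif(1)) < lp_prop - cur$lp
    return(list(w = if (accept) prop else w, accept = accept,
                fallback = TRUE))
  }
  qdens <- function(x, mu, R) {
    z <- R %*% (x - mu)
    -0.5 * sum(z^2) / step^2 + sum(log(diag(R))) -
      length(x) * log(step)
  }
  mu <- w + (step^2 / 2) * drop(chol2inv(R) %*% cur$grad)
  prop <- mu + step * drop(backsolve(R, rnorm(length(w))))
  new <- logpost_grad(prop)
  if (!is.finite(new$lp)) {
    return(list(w = w, accept = FALSE, fallback = FALSE))
  }
  ok2 <- all(is.finite(new$grad)) && all(is.finite(new$G))
  R2 <- if (ok2) tryCatch(chol(new$G), error = function(e) NULL) else NULL
  if (is.null(R2)) {
    return(list(w = w, accept = FALSE, fallback = FALSE))
  }
  mu2 <- prop + (step^2 / 2) * drop(chol2inv(R2) %*% new$grad)
  la <- new$lp - cur$lp + qdens(w, mu2, R2) - qdens(prop, mu, R)
  accept <- log(runif(1)) < la
  list(w = if (accept) prop else w, accept = accept, fallback = FALSE)
}

# Conditional log posterior, gradient and Gauss-Newton metric for the
# secretion block. w3 = (log10 k, halflife, f) is the full working vector;
# `free` indexes the coordinates being updated (composite fits pin some).
# The data likelihood is the product of Gaussian observation densities
# around the LH path propagated deterministically from the latent drive.
# ctxs is a list of series contexts (y, obs_idx, h, b, lh0, cv, dt, and
# optionally k_fixed / f_fixed); a context with `own = FALSE` informs only
# the shared clearance.
sec_logpost_grad <- function(w3, free, ctxs, prior) {
  l10k <- w3[1]; hl <- w3[2]; f <- w3[3]
  lp0 <- log_prior_working_sec(l10k, hl, f, prior)
  grad <- numeric(3); G <- diag(1e-8, 3)
  fail <- function() list(lp = -Inf, grad = grad[free],
                          G = G[free, free, drop = FALSE])
  if (!is.finite(lp0)) return(fail())
  k <- 10^l10k; d <- log(2) / hl
  grad <- grad - c((l10k - prior$log10_k_mean) / prior$log10_k_sd^2,
                   (hl - prior$halflife_mean) / prior$halflife_sd^2, 0)
  diag(G) <- diag(G) + c(1 / prior$log10_k_sd^2, 1 / prior$halflife_sd^2,
                         12 / diff(prior$f_bounds)^2)
  lp <- lp0
  A <- c(k * log(10), -log(2) / hl^2, 1)
  for (cx in ctxs) {
    if (cx$dt * d >= 1) return(fail())
    own <- !isFALSE(cx$own)
    kk <- if (own) k else cx$k_fixed
    ff <- if (own) f else cx$f_fixed
    r <- cond_loglik_grad_cpp(cx$y, cx$obs_idx, cx$h, cx$b, cx$dt,
                              kk, d, ff, cx$cv, cx$lh0)
    if (!is.finite(r$loglik)) return(fail())
    lp <- lp + r$loglik
    AA <- if (own) A else c(0, A[2], 0)
    grad <- grad + AA * r$grad
    G <- G + outer(AA, AA) * r$gn
  }
  list(lp = lp, grad = grad[free], G = G[free, free, drop = FALSE])
}

#' Simplified manifold MALA update of the secretion block
#'
#' One sMMALA step on `(log10 k, half-life, f)` targeting their conditional
#' posterior given the latent drive and the data. Given the latent on/off and
#' basal paths, the LH concentration is a deterministic linear recursion, so
#' the conditional likelihood is a product of Gaussian observation densities;
#' the proposal uses its analytic gradient preconditioned by the Gauss-Newton
#' information metric plus the prior precision, with an exact MH correction.
#'
#' @param params Current [lh_params()].
#' @param latent Latent path (list with `h` and `b` on the `dt` grid), or
#'   `NULL` together with `series = NULL` to target the prior alone.
#' @param series The observed [lh_series()], or `NULL`.
#' @param prior An [lh_priors()] object.
#' @param step sMMALA step size.
#' @return List with `k`, `d`, `f`, `accept` and `fallback` (whether the
#'   random-walk fallback was used).
#' @export
update_secretion_params <- function(params, latent, series,
                                    prior = lh_priors(), step = 0.5) {
  ctxs <- list()
  if (!is.null(series)) {
    g <- series_grid(series, params$dt)
    ctxs <- list(list(y = series$values, obs_idx = g$obs_idx,
                      h = as.integer(latent$h), b = as.numeric(latent$b),
                      lh0 = series$values[1], cv = params$cv,
                      dt = params$dt))
  }
  w <- c(log10(params$k), log(2) / params$d, params$f)
  res <- smmala_step(
    w, function(ww) sec_logpost_grad(ww, free = 1:3, ctxs, prior),
    step = step, rw_sd = c(0.05, 2, 0.02))
  list(k = 10^res$w[1], d = log(2) / res$w[2], f = res$w[3],
       accept = res$accept, fallback = res$fallback)
}
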