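#' Prior specification for the LH model parameters
#'
#' Defaults follow the study design for 10-minute sampling over 480 minutes:
#' the switch timescales are uniform on the log10 scale between 5 and 240
#' minutes (below the sampling interval and half the profile duration,
#' respectively); `log10(k)` is a broad normal; the clearance rate is
#' parameterized through the half-life `log(2)/d`, normal around 80 minutes
#' (a physiological LH half-life) truncated to positive values; and the
#' pulsatility strength `f` is uniform on `[0, 1]`.
#'
#' @param tau_on_bounds,tau_off_bounds Bounds, minutes (uniform on log10).
#' @param log10_k_mean,log10_k_sd Normal prior for `log10(k)`.
#' @param halflife_mean,halflife_sd Normal prior for the half-life
#'   `log(2)/d`, minutes, truncated to `(0, Inf)`.
#' @param f_bounds Bounds for the uniform prior on `f`.
#' @return An object of class `lh_priors`.
#' @export
lh_priors <- function(tau_on_bounds = c(5, 240), tau_off_bounds = c(5, 240),
                      log10_k_mean = 0, log10_k_sd = 5,
                      halflife_mean = 80, halflife_sd = 9.3,
                      f_bounds = c(0, 1)) {
  stopifnot(length(tau_on_bounds) == 2, tau_on_bounds[1] > 0,
            diff(tau_on_bounds) > 0,
            length(tau_off_bounds) == 2, tau_off_bounds[1] > 0,
            diff(tau_off_bounds) > 0,
            log10_k_sd > 0, halflife_sd > 0, halflife_mean > 0,
            length(f_bounds) == 2, f_bounds[1] >= 0, f_bounds[2] <= 1,
            diff(f_bounds) > 0)
  structure(list(tau_on_bounds = tau_on_bounds,
                 tau_off_bounds = tau_off_bounds,
                 log10_k_mean = log10_k_mean, log10_k_sd = log10_k_sd,
                 halflife_mean = halflife_mean, halflife_sd = halflife_sd,
                 f_bounds = f_bounds),
            class = "lh_priors")
}

#' Draw model parameters from the prior
#'
#' @param prior An [lh_priors()] object.
#' @param n Number of draws.
#' @param cv,dt Fixed assay CV and step size attached to each draw.
#' @return For `n = 1` an [lh_params()] object; otherwise a data.frame with
#'   one row per draw.
#' @export
sample_prior <- function(prior = lh_priors(), n = 1, cv = 0.041, dt = 1) {
  tau_on <- 10^runif(n, log10(prior$tau_on_bounds[1]),
                     log10(prior$tau_on_bounds[2]))
  tau_off <- 10^runif(n, log10(prior$tau_off_bounds[1]),
                      log10(prior$tau_off_bounds[2]))
  k <- 10^rnorm(n, prior$log10_k_mean, prior$log10_k_sd)
  hl <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      hl[i] <- rnorm(1, prior$halflife_mean, prior$halflife_sd)
      if (hl[i] > 0 && log(2) / hl[i] * dt < 1) break
    }
  }
  f <- runif(n, prior$f_bounds[1], prior$f_bounds[2])
  if (n == 1L)
    return(lh_params(tau_on, tau_off, k, log(2) / hl, f, cv = cv, dt = dt))
  data.frame(tau_on = tau_on, tau_off = tau_off, k = k, d = log(2) / hl,
             f = f)
}

#' Log prior density of model parameters (natural scale)
#'
#' Returns the joint log prior density of `(tau_on, tau_off, k, d, f)` on
#' their natural scales, including the Jacobians of the log10 and half-life
#' parameterizations, so that each block integrates to one over its natural
#' support. `-Inf` outside the support.
#'
#' @param params An [lh_params()] object or a list with the five fields.
#' @param prior An [lh_priors()] object.
#' @return Scalar log-density.
#' @export
log_prior <- function(params, prior = lh_priors()) {
  lp <- 0
  b <- prior$tau_on_bounds
  if (params$tau_on < b[1] || params$tau_on > b[2]) return(-Inf)
  lp <- lp - log(params$tau_on * log(10) * diff(log10(b)))
  b <- prior$tau_off_bounds
  if (params$tau_off < b[1] || params$tau_off > b[2]) return(-Inf)
  lp <- lp - log(params$tau_off * log(10) * diff(log10(b)))
  if (params$k <= 0) return(-Inf)
  lp <- lp + dnorm(log10(params$k), prior$log10_k_mean, prior$log10_k_sd,
                   log = TRUE) - log(params$k * log(10))
  if (params$d <= 0) return(-Inf)
  hl <- log(2) / params$d
  z <- pnorm(0, prior$halflife_mean, prior$halflife_sd, lower.tail = FALSE)
  lp <- lp + dnorm(hl, prior$halflife_mean, prior$halflife_sd, log = TRUE) -
    log(z) + log(log(2) / params$d^2)
  b <- prior$f_bounds
  if (params$f < b[1] || params$f > b[2]) return(-Inf)
  lp <- lp - log(diff(b))
  lp
}

# log prior on the working scale used by the samplers:
# (log10 tau_on, log10 tau_off) flat inside bounds; (log10 k, halflife, f)
# normal x truncated-normal x uniform. Constants that cancel in MH ratios
# are kept for transparency.
log_prior_working_sec <- function(l10k, hl, f, prior) {
  if (hl <= 0 || f < prior$f_bounds[1] || f > prior$f_bounds[2]) return(-Inf)
  dnorm(l10k, prior$log10_k_mean, prior$log10_k_sd, log = TRUE) +
    dnorm(hl, prior$halflife_mean, prior$halflife_sd, log = TRUE) -
    log(diff(prior$f_bounds))
}
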