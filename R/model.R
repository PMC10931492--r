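#' Pulse-generator transition probability
#'
#' The hypothalamic pulse generator is a discretized two-state telegraph
#' process: over one step of length `dt` an ON state flips OFF with
#' probability `dt/tau_on` and an OFF state flips ON with probability
#' `dt/tau_off`, so mean dwell times are `tau_on` and `tau_off` minutes.
#'
#' @param h Current state(s), 0 (OFF) or 1 (ON).
#' @param params An [lh_params()] object.
#' @return Probability of being ON at the next grid point, same length as `h`.
#' @examples
#' p <- lh_params(10, 240, 0.2, log(2) / 80, 0.8)
#' transition_probability(1, p) # 1 - 1/10
#' transition_probability(0, p) # 1/240
#' @export
transition_probability <- function(h, params) {
  validate_params(params)
  if (!all(h %in% c(0, 1))) stop("h must be 0 or 1", call. = FALSE)
  ifelse(h == 1, 1 - params$dt / params$tau_on, params$dt / params$tau_off)
}

#' One step of the basal drive
#'
#' The basal hypothalamic signal is a mean-reverting pre-signal squashed
#' through a logistic: `x' = x - (dt/2) x + sqrt(dt) * noise` (an
#' Euler-Maruyama Ornstein-Uhlenbeck step whose continuum stationary law is
#' standard normal) and `b' = 1 / (1 + exp(-x'))`, bounded in (0, 1).
#'
#' @param x Current pre-signal value(s), finite.
#' @param params An [lh_params()] object.
#' @param noise Standard-normal draw(s); pass 0 for the deterministic part.
#' @return A list with `x` (next pre-signal) and `b` (next basal signal).
#' @examples
#' p <- lh_params(20, 60, 0.2, log(2) / 80, 0.8)
#' step_basal(0, p, 0) # x = 0, b = 0.5
#' @export
step_basal <- function(x, params, noise) {
  validate_params(params)
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  x_next <- x - (params$dt / 2) * x + sqrt(params$dt) * noise
  list(x = x_next, b = plogis(x_next))
}

#' One step of the LH concentration
#'
#' `lh' = lh + (k * (p * f + b * (1 - f)) - d * lh) * dt`: secretion driven
#' by the weighted pulsatile and basal signals, minus first-order clearance.
#'
#' @param lh Current LH concentration(s), IU/L, non-negative.
#' @param p Pulse-generator state(s), 0 or 1.
#' @param b Basal signal value(s) in `[0, 1]`.
#' @param params An [lh_params()] object.
#' @return Next LH concentration(s), IU/L.
#' @export
step_lh <- function(lh, p, b, params) {
  validate_params(params)
  if (any(lh < 0)) stop("lh must be >= 0", call. = FALSE)
  lh + (params$k * (p * params$f + b * (1 - params$f)) - params$d * lh) *
    params$dt
}

#' Apply multiplicative assay noise to a true LH value
#'
#' `lh_obs = lh * (1 + cv * noise)`. Values driven non-positive by large
#' noise draws are clipped to a tiny positive floor (1e-6 IU/L) with a
#' warning, since assay readings are positive.
#'
#' @param lh True LH concentration(s), IU/L, non-negative.
#' @param params An [lh_params()] object (uses `cv`).
#' @param noise Standard-normal draw(s).
#' @return Observed LH value(s), IU/L.
#' @export
lh_observe <- function(lh, params, noise) {
  validate_params(params)
  if (any(lh < 0)) stop("lh must be >= 0", call. = FALSE)
  obs <- lh * (1 + params$cv * noise)
  if (any(obs <= 0)) {
    warning("non-positive simulated observations clipped to 1e-6 IU/L",
            call. = FALSE)
    obs <- pmax(obs, 1e-6)
  }
  obs
}

#' Log-density of an observation given the true LH concentration
#'
#' The observation model is Gaussian with mean `lh` and standard deviation
#' `cv * lh`. For `lh <= 0` the density is degenerate and `-Inf` is returned
#' (a particle with zero likelihood), not an error.
#'
#' @param lh_obs Observed value(s), IU/L.
#' @param lh True concentration(s), IU/L.
#' @param params An [lh_params()] object (uses `cv`).
#' @return Log-density, vectorized; `-Inf` where `lh <= 0`.
#' @export
log_obs_density <- function(lh_obs, lh, params) {
  validate_params(params)
  n <- max(length(lh), length(lh_obs))
  out <- rep(-Inf, n)
  lh <- rep_len(lh, n); lh_obs <- rep_len(lh_obs, n)
  ok <- lh > 0
  out[ok] <- dnorm(lh_obs[ok], mean = lh[ok], sd = params$cv * lh[ok],
                   log = TRUE)
  out
}

#' Simulate a latent path and an observed LH series
#'
#' Simulates the pulse generator, basal drive and LH concentration on the
#' `dt` grid over `[0, duration]`, then samples observations every
#' `sample_interval` minutes through the multiplicative-noise observation
#' model. Initial conditions: the pulse generator starts from its stationary
#' law (`P(ON) = tau_on / (tau_on + tau_off)`), the basal pre-signal from
#' N(0, 1), and LH from its mean steady state `k * E[drive] / d`.
#'
#' @param params An [lh_params()] object.
#' @param duration Total simulated time, minutes.
#' @param sample_interval Observation spacing, minutes (a multiple of `dt`).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param subject_id,label Passed to the returned [lh_series()].
#' @return A list of class `lh_sim` with `path` (data.frame: `times`, `h`,
#'   `x`, `b`, `lh`) and `series` (an [lh_series()]).
#' @examples
#' sim <- lh_simulate(lh_params(20, 60, 0.15, log(2) / 80, 0.8),
#'                    duration = 480, sample_interval = 10, seed = 1)
#' length(sim$series$values) # 49
#' @export
lh_simulate <- function(params, duration = 480, sample_interval = 10,
                        seed = NULL, subject_id = "sim", label = "") {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  if (duration < sample_interval || sample_interval < dt)
    stop("need duration >= sample_interval >= dt", call. = FALSE)
  if (abs(sample_interval / dt - round(sample_interval / dt)) > 1e-8)
    stop("sample_interval must be a multiple of dt", call. = FALSE)
  n_steps <- as.integer(round(duration / dt)) + 1L
  pi_on <- params$tau_on / (params$tau_on + params$tau_off)
  h0 <- rbinom(1L, 1L, pi_on)
  x0 <- rnorm(1L)
  lat <- simulate_latent_cpp(n_steps, dt, params$tau_on, params$tau_off,
                             h0, x0)
  b <- plogis(lat$x)
  u <- params$f * lat$h + (1 - params$f) * b
  lh0 <- params$k * (params$f * pi_on + (1 - params$f) * 0.5) / params$d
  lh <- c(lh0, stats::filter(params$k * dt * u[-n_steps],
                             1 - params$d * dt, method = "recursive",
                             init = lh0))
  times <- dt * seq.int(0L, n_steps - 1L)
  obs_t <- seq(0, duration, by = sample_interval)
  obs_i <- as.integer(round(obs_t / dt)) + 1L
  y <- lh_observe(lh[obs_i], params, rnorm(length(obs_i)))
  structure(
    list(path = data.frame(times = times, h = lat$h, x = lat$x, b = b,
                           lh = as.numeric(lh)),
         series = lh_series(obs_t, y, subject_id = subject_id, label = label),
         params = params),
    class = "lh_sim")
}
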