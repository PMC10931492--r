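#' Model parameters for the LH state-space model
#'
#' Bundles the five inferable parameters of the LH model with the fixed assay
#' coefficient of variation and the integration step.
#'
#' @param tau_on Mean duration of the ON state of the pulse generator,
#'   minutes (> 0).
#' @param tau_off Mean duration of the OFF state, minutes (> 0).
#' @param k Maximum secretion rate, IU/L per minute (>= 0).
#' @param d Clearance rate, per minute (> 0); half-life is `log(2)/d`.
#' @param f Pulsatility strength in `[0, 1]`: weight of the pulsatile drive
#'   relative to the basal drive.
#' @param cv Assay coefficient of variation (> 0); the standard deviation of
#'   the multiplicative measurement noise. Default 0.041 (a typical
#'   intra-assay CV for automated LH immunoassays).
#' @param dt Integration step, minutes (> 0). Default 1.
#'
#' @return An object of class `lh_params`.
#' @examples
#' p <- lh_params(tau_on = 20, tau_off = 60, k = 0.15, d = log(2) / 80, f = 0.8)
#' p
#' @export
lh_params <- function(tau_on, tau_off, k, d, f, cv = 0.041, dt = 1) {
  p <- structure(list(tau_on = tau_on, tau_off = tau_off, k = k, d = d,
                      f = f, cv = cv, dt = dt), class = "lh_params")
  validate_params(p)
  p
}

#' Validate LH model parameters
#'
#' Checks domain constraints, including that the discretization is valid:
#' flip probabilities `dt/tau` must be below 1 and the Euler step must not
#' overshoot (`d * dt < 1`).
#'
#' @param p An `lh_params` object (or a list with the same fields).
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(p[[x]]) || length(p[[x]]) != 1L || !is.finite(p[[x]]))
      stop(sprintf("parameter '%s' must be a finite number", x), call. = FALSE)
  }
  for (nm in c("tau_on", "tau_off", "k", "d", "f", "cv", "dt")) num1(nm)
  if (p$tau_on <= 0) stop("tau_on must be > 0", call. = FALSE)
  if (p$tau_off <= 0) stop("tau_off must be > 0", call. = FALSE)
  if (p$k < 0) stop("k must be >= 0", call. = FALSE)
  if (p$d <= 0) stop("d must be > 0", call. = FALSE)
  if (p$f < 0 || p$f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (p$cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (p$dt / p$tau_on >= 1 || p$dt / p$tau_off >= 1)
    stop("dt/tau_on and dt/tau_off must be < 1 (valid flip probabilities)",
         call. = FALSE)
  if (p$d * p$dt >= 1)
    stop("d * dt must be < 1 (Euler step would overshoot)", call. = FALSE)
  invisible(p)
}

#' @export
print.lh_params <- function(x, ...) {
  cat("LH model parameters\n")
  cat(sprintf("  tau_on  %8.3f min    tau_off %8.3f min\n", x$tau_on, x$tau_off))
  cat(sprintf("  k       %8.4f IU/L/min   d %8.5f /min (half-life %.1f min)\n",
              x$k, x$d, log(2) / x$d))
  cat(sprintf("  f       %8.3f        cv %6.3f    dt %g min\n", x$f, x$cv, x$dt))
  invisible(x)
}

#' Observed LH time series
#'
#' @param times Observation times in minutes, strictly increasing.
#' @param values Measured LH concentrations in IU/L, strictly positive.
#' @param subject_id Free-text subject identifier.
#' @param label Free-text label (e.g. group or visit).
#'
#' @return An object of class `lh_series`.
#' @examples
#' lh_series(seq(0, 60, 10), c(5.1, 5.4, 7.9, 6.5, 5.8, 5.2, 5.0))
#' @export
lh_series <- function(times, values, subject_id = "", label = "") {
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("at least 2 observations are required", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("times and values must not contain NA", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values <= 0))
    stop("LH values must be strictly positive", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 subject_id = subject_id, label = label),
            class = "lh_series")
}

#' @export
print.lh_series <- function(x, ...) {
  cat(sprintf("LH series%s: %d observations, %g-%g min, median %.2f IU/L\n",
              if (nzchar(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              length(x$times), min(x$times), max(x$times), median(x$values)))
  invisible(x)
}

# Map observation times onto the dt grid anchored at the first observation.
# Times off the grid are snapped to the nearest grid point with a warning.
series_grid <- function(series, dt) {
  rel <- series$times - series$times[1]
  idx <- round(rel / dt)
  if (max(abs(rel - idx * dt)) > 1e-8) {
    warning("observation times snapped to the dt grid", call. = FALSE)
  }
  if (anyDuplicated(idx))
    stop("two observations snap to the same grid point; decrease dt",
         call. = FALSE)
  list(obs_idx = as.integer(idx),             # 0-based grid indices
       n_grid = as.integer(idx[length(idx)] + 1L),
       times = series$times[1] + dt * seq.int(0L, idx[length(idx)]))
}
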