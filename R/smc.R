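#' Particle filter for the latent hypothalamic path
#'
#' Without a reference path this is a bootstrap particle filter: it returns
#' an unbiased estimate of the marginal likelihood of the observations and
#' one latent trajectory drawn from the final particle weights. With a
#' reference path it runs conditional sequential Monte Carlo: the reference
#' trajectory survives every resampling step (pinned in one particle slot),
#' and with `ancestor_sampling = TRUE` its ancestor index is re-drawn at each
#' resampling step with weights proportional to particle weight times the
#' one-step transition density to the reference's next state.
#'
#' Conventions: the first observation pins the initial LH concentration
#' (`lh0` defaults to it) and is not weighted; particles are resampled
#' systematically after every weighted observation.
#'
#' @param series An [lh_series()].
#' @param params An [lh_params()] object.
#' @param n_particles Number of particles (>= 1).
#' @param ref_path Optional reference path: a list/data.frame with `h` and
#'   `x` on the full `dt` grid of the series.
#' @param ancestor_sampling Logical; re-draw the reference's ancestry
#'   (conditional runs only).
#' @param lh0 Initial LH concentration; defaults to the first observation.
#' @return A list of class `lh_path_draw` with `times`, `h`, `x`, `b`, `lh`
#'   on the `dt` grid and `loglik`, the marginal log-likelihood estimate.
#' @export
particle_filter <- function(series, params, n_particles = 100,
                            ref_path = NULL, ancestor_sampling = TRUE,
                            lh0 = series$values[1]) {
  validate_params(params)
  stopifnot(inherits(series, "lh_series"), n_particles >= 1)
  g <- series_grid(series, params$dt)
  ref_h <- NULL; ref_x <- NULL
  if (!is.null(ref_path)) {
    if (length(ref_path$h) != g$n_grid || length(ref_path$x) != g$n_grid)
      stop("ref_path grid does not match the series grid", call. = FALSE)
    ref_h <- as.integer(ref_path$h)
    ref_x <- as.numeric(ref_path$x)
  }
  res <- csmc_cpp(series$values, g$obs_idx, g$n_grid, params$dt,
                  params$tau_on, params$tau_off, params$k, params$d,
                  params$f, params$cv, lh0, as.integer(n_particles),
                  ref_h, ref_x, isTRUE(ancestor_sampling))
  structure(list(times = g$times, h = res$h, x = res$x, b = plogis(res$x),
                 lh = res$lh, loglik = res$loglik),
            class = "lh_path_draw")
}
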