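#' Posterior pulse-probability trace
#'
#' Elementwise mean of the stored binary on/off latent paths: the posterior
#' probability that the hypothalamic pulse generator is ON at each grid
#' point.
#'
#' @param samples An `lh_posterior` object (from [run_gibbs()]).
#' @return Numeric vector in `[0, 1]` on the latent grid
#'   (`samples$latent$times`).
#' @export
pulse_probability <- function(samples) {
  h <- samples$latent$h
  if (is.null(h) || nrow(h) < 1L)
    stop("no stored latent paths in the posterior object", call. = FALSE)
  colMeans(h)
}

#' Identify pulse onsets by threshold crossing
#'
#' A pulse onset is marked at each upward crossing of the threshold:
#' `p_on[i-1] <= threshold < p_on[i]` (plus the first grid point if the
#' trace starts above threshold). Values exactly at the threshold count as
#' not exceeding it, so one onset is called per contiguous supra-threshold
#' episode and a trace pinned at the threshold yields no calls.
#'
#' @param p_on Pulse-probability trace in `[0, 1]`.
#' @param times Grid times (minutes) matching `p_on`.
#' @param threshold Scalar in (0, 1); default 0.5, the point above which ON
#'   is more likely than OFF.
#' @return Numeric vector of onset times (minutes), possibly empty.
#' @examples
#' identify_pulses(c(0.2, 0.6, 0.7, 0.4, 0.6, 0.1), seq(0, 50, 10))
#' @export
identify_pulses <- function(p_on, times = seq_along(p_on) - 1,
                            threshold = 0.5) {
  stopifnot(length(p_on) == length(times), threshold > 0, threshold < 1,
            all(p_on >= 0 & p_on <= 1))
  above <- p_on > threshold
  onset <- above & !c(FALSE, above[-length(above)])
  times[onset]
}

#' Inter-pulse intervals
#'
#' @param onsets Sorted pulse-onset times, minutes.
#' @return List with `intervals` (successive differences, empty when fewer
#'   than 2 onsets), `mean` and `sd` (NA when undefined).
#' @export
interpulse_intervals <- function(onsets) {
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing", call. = FALSE)
  iv <- diff(onsets)
  list(intervals = iv,
       mean = if (length(iv)) mean(iv) else NA_real_,
       sd = if (length(iv) > 1) sd(iv) else NA_real_)
}

#' Pulse calls from a fitted posterior
#'
#' Combines [pulse_probability()], [identify_pulses()] and
#' [interpulse_intervals()] and delimits each supra-threshold episode.
#'
#' @param samples An `lh_posterior` object.
#' @param threshold Calling threshold, default 0.5.
#' @return An object of class `lh_pulses`: `times`, `p_on`, `threshold`,
#'   `onsets`, `intervals`, and `episodes` (data.frame `onset_min`,
#'   `end_min`, `max_p_on`, one row per supra-threshold episode).
#' @export
pulse_calls <- function(samples, threshold = 0.5) {
  p_on <- pulse_probability(samples)
  times <- samples$latent$times
  onsets <- identify_pulses(p_on, times, threshold)
  above <- p_on > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- which(r$values)
  episodes <- data.frame(
    onset_min = times[starts[ep]],
    end_min = times[ends[ep]],
    max_p_on = vapply(ep, function(j)
      max(p_on[starts[j]:ends[j]]), numeric(1)))
  structure(list(times = times, p_on = p_on, threshold = threshold,
                 onsets = onsets,
                 intervals = interpulse_intervals(onsets)$intervals,
                 episodes = episodes),
            class = "lh_pulses")
}

#' @export
print.lh_pulses <- function(x, ...) {
  cat(sprintf("%d pulse(s) called at threshold %.2f", length(x$onsets),
              x$threshold))
  if (length(x$onsets))
    cat(": onsets at", paste(x$onsets, collapse = ", "), "min")
  cat("\n")
  if (length(x$intervals))
    cat(sprintf("  mean inter-pulse interval %.1f min\n", mean(x$intervals)))
  invisible(x)
}

#' Posterior parameter summaries
#'
#' Mean, sd, median and 5/95% quantiles (linear interpolation, R type 7)
#' for each model parameter, on the natural and log10 scales.
#'
#' @param samples An `lh_posterior` or `lh_posterior_composite` object.
#' @return data.frame with one row per parameter.
#' @export
summarize_posterior <- function(samples) {
  d <- samples$draws
  pars <- setdiff(names(d), c("loglik", "loglik_pre", "loglik_post"))
  if (nrow(d) < 2L) stop("need at least 2 retained draws", call. = FALSE)
  one <- function(nm) {
    x <- d[[nm]]
    q <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
    lx <- log10(x)
    lq <- suppressWarnings(quantile(lx, c(0.05, 0.5, 0.95), names = FALSE,
                                    type = 7))
    data.frame(parameter = nm, mean = mean(x), sd = sd(x), q05 = q[1],
               median = q[2], q95 = q[3], mean_log10 = mean(lx),
               q05_log10 = lq[1], median_log10 = lq[2], q95_log10 = lq[3])
  }
  do.call(rbind, lapply(pars, one))
}
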