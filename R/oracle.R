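#' Exact forward filter on a discretized latent grid
#'
#' An independent, deterministic validation oracle for the particle filter:
#' the standard HMM forward algorithm on the joint latent chain of the
#' on/off state (2 values), the basal pre-signal discretized into
#' `n_x_bins` uniform bins on `x_range`, and the LH concentration
#' discretized into `n_lh_bins` uniform bins. Between-bin transitions for
#' the pre-signal come from the Gaussian increment of the basal recursion
#' (row-normalized); the LH concentration moves deterministically given the
#' cell's drive, with its mass split linearly between the two enclosing LH
#' bins; emissions are the Gaussian observation densities. The filtered
#' distribution is renormalized at every observation. Conventions match
#' [particle_filter()]: the first observation pins the initial LH value and
#' is not weighted beyond its constant density term.
#'
#' The LH concentration must be carried in the state grid (not merely
#' averaged per pre-signal cell) because it integrates the whole latent
#' history between observations; with a sharp assay CV the likelihood is
#' sensitive to that history.
#'
#' Intended for short series (around a dozen observations); cost grows with
#' `n_x_bins^2 * n_lh_bins` per grid step.
#'
#' @param series An [lh_series()].
#' @param params An [lh_params()] object.
#' @param n_x_bins Number of pre-signal bins (>= 10).
#' @param n_lh_bins Number of LH bins (>= 50).
#' @param x_range Pre-signal bin range; must cover `[-5, 5]` (five
#'   stationary standard deviations).
#' @param lh0 Initial LH concentration; defaults to the first observation.
#' @return An object of class `lh_grid_filter`: `loglik`, `filtered_p_on`
#'   (filtered probability that the generator is ON at each observation
#'   time), `n_x_bins`, `n_lh_bins`, `x_range`.
#' @export
exact_filter <- function(series, params, n_x_bins = 200, n_lh_bins = 800,
                         x_range = c(-5, 5), lh0 = series$values[1]) {
  validate_params(params)
  stopifnot(inherits(series, "lh_series"))
  if (n_x_bins < 10)
    stop("n_x_bins too small for a meaningful grid", call. = FALSE)
  if (n_lh_bins < 50)
    stop("n_lh_bins too small for a meaningful grid", call. = FALSE)
  if (x_range[1] > -5 || x_range[2] < 5)
    stop("x_range must cover [-5, 5] (five stationary sds of the basal ",
         "pre-signal)", call. = FALSE)
  dt <- params$dt
  g <- series_grid(series, dt)
  y <- series$values
  n_steps <- g$n_grid - 1L

  edges <- seq(x_range[1], x_range[2], length.out = n_x_bins + 1)
  xc <- (edges[-1] + edges[-(n_x_bins + 1)]) / 2
  bc <- plogis(xc)
  a <- 1 - dt / 2; s <- sqrt(dt)
  Tx <- t(vapply(xc, function(x0) {
    p <- diff(pnorm(edges, mean = a * x0, sd = s))
    p / sum(p)
  }, numeric(n_x_bins)))
  pi_on <- params$tau_on / (params$tau_on + params$tau_off)
  # Ph[from + 1, to + 1], states OFF = 0, ON = 1
  Ph <- matrix(c(1 - dt / params$tau_off, dt / params$tau_off,
                 dt / params$tau_on, 1 - dt / params$tau_on),
               2, 2, byrow = TRUE)

  # LH support: decay-only lower bound, full-drive upper bound
  alh <- 1 - params$d * dt
  lh_lo <- min(lh0 * alh^n_steps, lh0) * 0.999
  lh_hi <- max(lh0, params$k / params$d) * 1.001
  lc <- seq(lh_lo, lh_hi, length.out = n_lh_bins)
  wbin <- lc[2] - lc[1]

  # P[[h + 1]]: n_lh_bins x n_x_bins mass array for each generator state
  p0x <- diff(pnorm(edges)); p0x <- p0x / sum(p0x)
  i0 <- findInterval(lh0, lc, all.inside = TRUE)
  fr0 <- (lh0 - lc[i0]) / wbin
  lh_init <- numeric(n_lh_bins)
  lh_init[i0] <- 1 - fr0
  lh_init[min(i0 + 1L, n_lh_bins)] <- lh_init[min(i0 + 1L, n_lh_bins)] + fr0
  P <- list(outer(lh_init, (1 - pi_on) * p0x),
            outer(lh_init, pi_on * p0x))

  # deterministic LH move: lh' = alh*lh + k*u(h, b)*dt, with mass split
  # linearly between the two enclosing bins. The map is time-invariant, so
  # the target indices and split fractions are precomputed per state.
  base_pos <- (alh * lc - lh_lo) / wbin + 1 # before adding the drive offset
  n_cells <- n_lh_bins * n_x_bins
  col_off <- rep((seq_len(n_x_bins) - 1L) * n_lh_bins, each = n_lh_bins)
  shift_plan <- function(u_per_x) {
    pos <- outer(base_pos, params$k * u_per_x * dt / wbin, `+`)
    i <- pmin(pmax(floor(pos), 1), n_lh_bins - 1)
    fr <- as.vector(pmin(pmax(pos - i, 0), 1))
    src <- seq_len(n_cells)
    Matrix::sparseMatrix(
      i = c(as.vector(i) + col_off, as.vector(i) + 1 + col_off),
      j = c(src, src), x = c(1 - fr, fr), dims = c(n_cells, n_cells))
  }
  shift_lh <- function(M, plan)
    matrix(as.vector(plan %*% as.vector(M)), n_lh_bins, n_x_bins)

  loglik <- 0
  filtered <- numeric(length(y))
  j <- 1L
  if (g$obs_idx[1] == 0L) {
    loglik <- loglik + dnorm(y[1], lh0, params$cv * lh0, log = TRUE)
    filtered[1] <- sum(P[[2]])
    j <- 2L
  }

  plan_off <- shift_plan((1 - params$f) * bc)
  plan_on <- shift_plan(params$f + (1 - params$f) * bc)
  emis <- matrix(0, n_lh_bins, n_x_bins)
  for (t in seq_len(n_steps)) {
    S_off <- shift_lh(P[[1]], plan_off)
    S_on <- shift_lh(P[[2]], plan_on)
    S_off <- S_off %*% Tx
    S_on <- S_on %*% Tx
    P <- list(Ph[1, 1] * S_off + Ph[2, 1] * S_on,
              Ph[1, 2] * S_off + Ph[2, 2] * S_on)
    if (j <= length(y) && g$obs_idx[j] == t) {
      emis[] <- dnorm(y[j], mean = lc, sd = params$cv * lc)
      m <- sum(P[[1]] * emis) + sum(P[[2]] * emis)
      if (m <= 0)
        stop("forward filter lost all mass at observation ", j,
             call. = FALSE)
      loglik <- loglik + log(m)
      P <- list(P[[1]] * emis / m, P[[2]] * emis / m)
      filtered[j] <- sum(P[[2]])
      j <- j + 1L
    }
  }
  structure(list(loglik = loglik, filtered_p_on = filtered,
                 n_x_bins = n_x_bins, n_lh_bins = n_lh_bins,
                 x_range = x_range),
            class = "lh_grid_filter")
}

# sum `w` into `n` accumulator cells indexed by `i`
tapply_add <- function(i, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, i)
  out[as.integer(rownames(agg))] <- agg
  out
}
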