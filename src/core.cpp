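#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time model, shared conventions:
//   grid t = 0, dt, 2*dt, ...  (n_grid points)
//   H flips with prob dt/tau_on (from ON) or dt/tau_off (from OFF)
//   X_{t+dt} = X_t - (dt/2) X_t + sqrt(dt) eps,  B = logistic(X)
//   LH_{t+dt} = LH_t + (k (f H_t + (1-f) B_t) - d LH_t) dt
//   y_j ~ N(LH, (cv LH)^2) at observation grid indices; the first
//   observation pins LH_0 and is not weighted.
// All randomness uses R's RNG so set.seed() governs everything.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Box-Muller normals driven by R's uniform stream: statistically exact,
// deterministic given the R seed, and considerably cheaper than inversion
// in the filter's hot loop.
struct NormalGen {
  bool has_spare = false;
  double spare = 0.0;
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif_rand(), u2 = unif_rand();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

static inline double log_obs_dens(double y, double lh, double cv) {
  if (lh <= 0.0) return R_NegInf;
  double sd = cv * lh;
  double z = (y - lh) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672742; // log(sqrt(2pi))
}

// systematic resampling of n indices from normalized weights
static void systematic_resample(const std::vector<double>& w, int n,
                                std::vector<int>& idx, double u0) {
  int m = (int)w.size();
  double step = 1.0 / n;
  double u = u0 * step;
  double c = w[0];
  int i = 0;
  for (int j = 0; j < n; ++j) {
    while (u > c && i < m - 1) { ++i; c += w[i]; }
    idx[j] = i;
    u += step;
  }
}

// Simulate the latent (H, X) chain; lh/b are computed in R.
// [[Rcpp::export]]
List simulate_latent_cpp(int n_steps, double dt, double tau_on, double tau_off,
                         int h0, double x0) {
  IntegerVector h(n_steps);
  NumericVector x(n_steps);
  NormalGen ngen;
  double p_off_on = dt / tau_off, p_on_off = dt / tau_on;
  double a = 1.0 - dt / 2.0, s = std::sqrt(dt);
  h[0] = h0; x[0] = x0;
  for (int t = 1; t < n_steps; ++t) {
    double u = R::runif(0.0, 1.0);
    if (h[t - 1] == 1) h[t] = (u < p_on_off) ? 0 : 1;
    else               h[t] = (u < p_off_on) ? 1 : 0;
    x[t] = a * x[t - 1] + s * ngen();
  }
  return List::create(_["h"] = h, _["x"] = x);
}

// Log-likelihood of observations given a fixed latent drive (H, B), with
// analytic gradient and Gauss-Newton information w.r.t. (k, d, f) on the
// natural scale.  LH is propagated deterministically from lh0.
// [[Rcpp::export]]
List cond_loglik_grad_cpp(NumericVector y, IntegerVector obs_idx,
                          IntegerVector H, NumericVector B, double dt,
                          double k, double d, double f, double cv,
                          double lh0) {
  int n_grid = H.size();
  int n_obs = y.size();
  double a = 1.0 - d * dt;
  double lh = lh0, Sk = 0.0, Sd = 0.0, Sf = 0.0;
  double ll = 0.0;
  NumericVector grad(3);
  NumericMatrix gn(3, 3);
  NumericVector lh_path(n_grid);
  lh_path[0] = lh0;
  int j = 0;
  if (obs_idx[0] == 0) j = 1; // first observation pins lh0, not weighted
  for (int t = 1; t < n_grid; ++t) {
    double u = f * H[t - 1] + (1.0 - f) * B[t - 1];
    double lh_new = a * lh + k * u * dt;
    Sd = a * Sd - lh * dt;          // d LH / d d
    Sk = a * Sk + u * dt;           // d LH / d k
    Sf = a * Sf + k * (H[t - 1] - B[t - 1]) * dt;
    lh = lh_new;
    lh_path[t] = lh;
    if (j < n_obs && obs_idx[j] == t) {
      double lo = log_obs_dens(y[j], lh, cv);
      if (!R_finite(lo)) {
        return List::create(_["loglik"] = R_NegInf, _["grad"] = grad,
                            _["gn"] = gn, _["lh"] = lh_path);
      }
      ll += lo;
      double sd2 = cv * cv * lh * lh;
      double r = y[j] - lh;
      // full derivative of log N(y; lh, (cv lh)^2) w.r.t. lh
      double dldlh = -1.0 / lh + r / sd2 + r * r / (sd2 * lh);
      double g[3] = {Sk, Sd, Sf};
      for (int p = 0; p < 3; ++p) {
        grad[p] += dldlh * g[p];
        for (int q = 0; q < 3; ++q) gn(p, q) += g[p] * g[q] / sd2;
      }
      ++j;
    }
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad, _["gn"] = gn,
                      _["lh"] = lh_path);
}

// Particle filter for the latent path.  Unconditional (ref_h = NULL): a
// bootstrap filter returning an unbiased marginal-likelihood estimate and a
// path drawn from the final weights.  Conditional: the reference trajectory
// is pinned in slot 0 at every step; with ancestor_sampling its ancestry is
// re-drawn at every resampling step with weights proportional to particle
// weight times the one-step (H, X) transition density to the reference's
// next state (the deterministic LH component carries no density; the
// reference's LH is re-propagated from the sampled ancestor).
// [[Rcpp::export]]
List csmc_cpp(NumericVector y, IntegerVector obs_idx, int n_grid, double dt,
              double tau_on, double tau_off, double k, double d, double f,
              double cv, double lh0, int n_particles,
              Nullable<IntegerVector> ref_h_, Nullable<NumericVector> ref_x_,
              bool ancestor_sampling) {
  int N = n_particles;
  int n_obs = y.size();
  bool conditional = ref_h_.isNotNull();
  IntegerVector ref_h;
  NumericVector ref_x;
  if (conditional) { ref_h = ref_h_.get(); ref_x = ref_x_.get(); }

  double p_off_on = dt / tau_off, p_on_off = dt / tau_on;
  double ax = 1.0 - dt / 2.0, sx = std::sqrt(dt);
  double alh = 1.0 - d * dt;
  double pi_on = tau_on / (tau_on + tau_off);

  // full state history per grid point and slot, plus ancestor bookkeeping
  IntegerMatrix Hh(n_grid, N);
  NumericMatrix Xh(n_grid, N), Lh(n_grid, N);
  IntegerMatrix Anc(n_obs, N); // Anc(j, i): ancestor of slot i across obs j

  std::vector<double> h(N), x(N), lh(N), logw(N), w(N), aw(N);
  std::vector<int> idx(N);
  NormalGen ngen;

  for (int i = 0; i < N; ++i) {
    h[i] = (R::unif_rand() < pi_on) ? 1.0 : 0.0;
    x[i] = ngen();
    lh[i] = lh0;
  }
  if (conditional) { h[0] = ref_h[0]; x[0] = ref_x[0]; }
  for (int i = 0; i < N; ++i) { Hh(0, i) = (int)h[i]; Xh(0, i) = x[i]; Lh(0, i) = lh[i]; }

  double loglik = 0.0;
  int j0 = 0;
  if (obs_idx[0] == 0) {
    // the first observation pins lh0; its (constant) density is still part
    // of the data likelihood
    loglik += log_obs_dens(y[0], lh0, cv);
    j0 = 1;
  }

  for (int j = j0; j < n_obs; ++j) {
    int t_from = (j == j0) ? obs_idx[0] : obs_idx[j - 1];
    int t_to = obs_idx[j];
    // propagate
    for (int t = t_from; t < t_to; ++t) {
      for (int i = 0; i < N; ++i) {
        if (conditional && i == 0) {
          double u = f * ref_h[t] + (1.0 - f) * logistic(ref_x[t]);
          lh[0] = alh * lh[0] + k * u * dt;
          h[0] = ref_h[t + 1];
          x[0] = ref_x[t + 1];
        } else {
          double b = logistic(x[i]);
          double drive = f * h[i] + (1.0 - f) * b;
          lh[i] = alh * lh[i] + k * drive * dt;
          double u = R::unif_rand();
          if (h[i] == 1.0) h[i] = (u < p_on_off) ? 0.0 : 1.0;
          else             h[i] = (u < p_off_on) ? 1.0 : 0.0;
          x[i] = ax * x[i] + sx * ngen();
        }
        Hh(t + 1, i) = (int)h[i]; Xh(t + 1, i) = x[i]; Lh(t + 1, i) = lh[i];
      }
    }
    // weight
    double mx = R_NegInf;
    for (int i = 0; i < N; ++i) {
      logw[i] = log_obs_dens(y[j], lh[i], cv);
      if (logw[i] > mx) mx = logw[i];
    }
    if (!R_finite(mx))
      stop("degenerate particle filter: all weights zero at observation %d", j + 1);
    double sw = 0.0;
    for (int i = 0; i < N; ++i) { w[i] = std::exp(logw[i] - mx); sw += w[i]; }
    loglik += mx + std::log(sw / N);
    for (int i = 0; i < N; ++i) w[i] /= sw;

    if (j < n_obs - 1) {
      // resample (slots 1..N-1; slot 0 stays the reference when conditional)
      int t_next = t_to + 1; // first grid step of the next segment
      if (conditional) {
        int a0 = 0;
        if (ancestor_sampling && N > 1) {
          double amx = R_NegInf;
          for (int i = 0; i < N; ++i) {
            double lt;
            if (ref_h[t_next] == 1)
              lt = (h[i] == 1.0) ? std::log(1.0 - p_on_off) : std::log(p_off_on);
            else
              lt = (h[i] == 1.0) ? std::log(p_on_off) : std::log(1.0 - p_off_on);
            lt += R::dnorm(ref_x[t_next], ax * x[i], sx, 1);
            aw[i] = logw[i] - mx + lt;
            if (aw[i] > amx) amx = aw[i];
          }
          if (R_finite(amx)) {
            double s = 0.0;
            for (int i = 0; i < N; ++i) { aw[i] = std::exp(aw[i] - amx); s += aw[i]; }
            double u = R::unif_rand() * s, c = 0.0;
            for (int i = 0; i < N; ++i) { c += aw[i]; if (u <= c) { a0 = i; break; } }
          }
        }
        if (N > 1) systematic_resample(w, N - 1, idx, R::unif_rand());
        Anc(j, 0) = a0;
        std::vector<double> nh(N), nx(N), nlh(N);
        // slot 0 continues along the reference; its LH restarts from the
        // sampled ancestor's concentration
        nh[0] = ref_h[t_to]; nx[0] = ref_x[t_to]; nlh[0] = lh[a0];
        for (int i = 1; i < N; ++i) {
          int s = idx[i - 1];
          Anc(j, i) = s;
          nh[i] = h[s]; nx[i] = x[s]; nlh[i] = lh[s];
        }
        h = nh; x = nx; lh = nlh;
      } else {
        systematic_resample(w, N, idx, R::unif_rand());
        std::vector<double> nh(N), nx(N), nlh(N);
        for (int i = 0; i < N; ++i) {
          int s = idx[i];
          Anc(j, i) = s;
          nh[i] = h[s]; nx[i] = x[s]; nlh[i] = lh[s];
        }
        h = nh; x = nx; lh = nlh;
      }
    }
  }

  // draw the returned trajectory from the final weights
  int cur = 0;
  {
    double u = R::unif_rand(), c = 0.0;
    for (int i = 0; i < N; ++i) { c += w[i]; if (u <= c) { cur = i; break; } }
  }
  IntegerVector ph(n_grid);
  NumericVector px(n_grid), plh(n_grid);
  for (int j = n_obs - 1; j >= j0; --j) {
    int t_lo = (j == j0) ? obs_idx[0] : obs_idx[j - 1];
    for (int t = obs_idx[j]; t > t_lo; --t) {
      ph[t] = Hh(t, cur); px[t] = Xh(t, cur); plh[t] = Lh(t, cur);
    }
    if (j > j0) cur = Anc(j - 1, cur);
  }
  ph[0] = Hh(0, cur); px[0] = Xh(0, cur); plh[0] = Lh(0, cur);

  return List::create(_["h"] = ph, _["x"] = px, _["lh"] = plh,
                      _["loglik"] = loglik);
}
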