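#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of the three-state site-exposure chain.
// States: 1 wrapped, 2 transiently unwrapped (unbound), 3 unwrapped + bound.
// Allowed edges: 1<->2 (k12, k21), 2<->3 (k23*[TF], k32).
// Uses R's RNG so paths are reproducible under set.seed().
// [[Rcpp::export]]
List gillespie_path_cpp(double k12, double k21, double k23c, double k32,
                        double duration, int start_state) {
  std::vector<double> times;
  std::vector<int> states;
  times.reserve(256);
  states.reserve(256);
  double t = 0.0;
  int s = start_state;
  bool absorbed = false;
  times.push_back(0.0);
  states.push_back(s);
  while (true) {
    double r1 = 0.0, r2 = 0.0;
    int to1 = 0, to2 = 0;
    if (s == 1) {
      r1 = k12; to1 = 2;
    } else if (s == 2) {
      r1 = k21; to1 = 1;
      r2 = k23c; to2 = 3;
    } else {
      r1 = k32; to1 = 2;
    }
    double rtot = r1 + r2;
    if (rtot <= 0.0) { absorbed = true; break; }
    t += R::rexp(1.0) / rtot;
    if (t >= duration) break;
    s = (r2 > 0.0 && unif_rand() * rtot > r1) ? to2 : to1;
    times.push_back(t);
    states.push_back(s);
  }
  return List::create(_["entry_time"] = times,
                      _["state"] = states,
                      _["absorbed"] = absorbed);
}

// Occupancy-time-weighted average of state emission levels within each
// camera frame (noiseless; Gaussian noise is added by the caller).
// [[Rcpp::export]]
NumericVector render_frames_cpp(NumericVector entry, IntegerVector state,
                                double duration, double frame_time,
                                NumericVector e_levels) {
  int n_frames = (int)std::floor(duration / frame_time + 1e-9);
  NumericVector out(n_frames);
  int nseg = entry.size();
  for (int i = 0; i < nseg; ++i) {
    double t0 = entry[i];
    double t1 = (i + 1 < nseg) ? entry[i + 1] : duration;
    if (t1 > duration) t1 = duration;
    if (t1 <= t0) continue;
    double e = e_levels[state[i] - 1];
    int f0 = (int)std::floor(t0 / frame_time);
    int f1 = (int)std::ceil(t1 / frame_time - 1e-12);
    if (f0 < 0) f0 = 0;
    if (f1 > n_frames) f1 = n_frames;
    for (int f = f0; f < f1; ++f) {
      double lo = f * frame_time, hi = lo + frame_time;
      double a = t0 > lo ? t0 : lo;
      double b = t1 < hi ? t1 : hi;
      if (b > a) out[f] += e * (b - a);
    }
  }
  for (int f = 0; f < n_frames; ++f) out[f] /= frame_time;
  return out;
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727; // log(sqrt(2*pi))
}

// Maximum-likelihood EM (Baum-Welch) for a two-state Gaussian-emission HMM,
// followed by Viterbi decoding of the most probable path under the fitted
// parameters. Scaled forward-backward recursions; sds floored to avoid
// variance collapse. Returns degenerate = true when one state's expected
// occupancy empties so the caller can restart or fall back.
// [[Rcpp::export]]
List hmm_em_cpp(NumericVector y, NumericVector mu0, NumericVector sd0,
                NumericMatrix A0, NumericVector pi0,
                double tol, int max_iter, double sd_floor) {
  const int T = y.size(), K = 2;
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  double A[2][2] = {{A0(0, 0), A0(0, 1)}, {A0(1, 0), A0(1, 1)}};
  std::vector<double> pi(pi0.begin(), pi0.end());

  std::vector<double> alpha(T * K), beta(T * K), gamma(T * K), c(T), b(T * K);
  std::vector<double> ll_trace;
  double ll_prev = R_NegInf;
  bool degenerate = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        b[t * K + k] = std::exp(dnorm_log(y[t], mu[k], sd[k]));
    // forward (scaled)
    double ll = 0.0;
    for (int k = 0; k < K; ++k) alpha[k] = pi[k] * b[k];
    c[0] = alpha[0] + alpha[1];
    if (c[0] <= 0) { degenerate = true; break; }
    alpha[0] /= c[0]; alpha[1] /= c[0];
    ll += std::log(c[0]);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double s = alpha[(t - 1) * K] * A[0][k] + alpha[(t - 1) * K + 1] * A[1][k];
        alpha[t * K + k] = s * b[t * K + k];
      }
      c[t] = alpha[t * K] + alpha[t * K + 1];
      if (c[t] <= 0) { degenerate = true; break; }
      alpha[t * K] /= c[t]; alpha[t * K + 1] /= c[t];
      ll += std::log(c[t]);
    }
    if (degenerate) break;
    ll_trace.push_back(ll);
    // backward (scaled)
    beta[(T - 1) * K] = 1.0; beta[(T - 1) * K + 1] = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += A[k][j] * b[(t + 1) * K + j] * beta[(t + 1) * K + j];
        beta[t * K + k] = s / c[t + 1];
      }
    // gamma and xi accumulators
    double gsum[2] = {0, 0}, gy[2] = {0, 0};
    double xi[2][2] = {{0, 0}, {0, 0}};
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double g = alpha[t * K + k] * beta[t * K + k];
        gamma[t * K + k] = g;
        gsum[k] += g;
        gy[k] += g * y[t];
      }
    for (int t = 0; t < T - 1; ++t)
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < K; ++j)
          xi[k][j] += alpha[t * K + k] * A[k][j] * b[(t + 1) * K + j] *
                      beta[(t + 1) * K + j] / c[t + 1];
    if (gsum[0] < 1e-6 || gsum[1] < 1e-6) { degenerate = true; break; }
    // M-step
    for (int k = 0; k < K; ++k) {
      mu[k] = gy[k] / gsum[k];
      double sv = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = y[t] - mu[k];
        sv += gamma[t * K + k] * d * d;
      }
      sd[k] = std::sqrt(sv / gsum[k]);
      if (sd[k] < sd_floor) sd[k] = sd_floor;
      double rs = xi[k][0] + xi[k][1];
      if (rs > 0) { A[k][0] = xi[k][0] / rs; A[k][1] = xi[k][1] / rs; }
      pi[k] = gamma[k];
    }
    if (iter > 0 && std::fabs(ll - ll_prev) < tol) { ll_prev = ll; ++iter; break; }
    ll_prev = ll;
  }

  // Viterbi under final parameters (log space)
  IntegerVector path(T);
  if (!degenerate) {
    std::vector<double> d0(T), d1(T);
    std::vector<int> bp(T * K);
    double lA[2][2];
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j)
        lA[k][j] = A[k][j] > 0 ? std::log(A[k][j]) : -1e300;
    d0[0] = (pi[0] > 0 ? std::log(pi[0]) : -1e300) + dnorm_log(y[0], mu[0], sd[0]);
    d1[0] = (pi[1] > 0 ? std::log(pi[1]) : -1e300) + dnorm_log(y[0], mu[1], sd[1]);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double v0 = d0[t - 1] + lA[0][k];
        double v1 = d1[t - 1] + lA[1][k];
        int arg = v1 > v0 ? 1 : 0;
        double v = (arg ? v1 : v0) + dnorm_log(y[t], mu[k], sd[k]);
        if (k == 0) d0[t] = v; else d1[t] = v;
        bp[t * K + k] = arg;
      }
    }
    int cur = d1[T - 1] > d0[T - 1] ? 1 : 0;
    path[T - 1] = cur + 1;
    for (int t = T - 1; t > 0; --t) {
      cur = bp[t * K + cur];
      path[t - 1] = cur + 1;
    }
  }

  NumericMatrix Aout(2, 2);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j) Aout(k, j) = A[k][j];
  return List::create(
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sd"] = NumericVector(sd.begin(), sd.end()),
      _["trans"] = Aout,
      _["pi"] = NumericVector(pi.begin(), pi.end()),
      _["loglik"] = wrap(ll_trace),
      _["iterations"] = iter,
      _["degenerate"] = degenerate,
      _["path"] = path);
}
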