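#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Order-2 switching MAR filter: x_t = A1[s_t] x_{t-1} + A2[s_t] x_{t-2} + e_t
// A1, A2 are 2 x 2 x K arrays (one slice per state label), labels are
// 0-based per-sample state indices, noise is the pre-drawn innovation matrix
// (n x 2) so that all randomness stays under R's RNG.
// [[Rcpp::export]]
NumericMatrix mar_filter_cpp(NumericVector A1, NumericVector A2,
                             IntegerVector labels, NumericMatrix noise) {
  const int n = labels.size();
  if (noise.nrow() != n || noise.ncol() != 2)
    stop("noise must be n x 2");
  IntegerVector dim = A1.attr("dim");
  const int k = dim[2];
  NumericMatrix x(n, 2);
  double x1a = 0.0, x1b = 0.0; // x_{t-1}
  double x2a = 0.0, x2b = 0.0; // x_{t-2}
  for (int t = 0; t < n; ++t) {
    const int s = labels[t];
    if (s < 0 || s >= k) stop("state label out of range");
    const double *a1 = &A1[4 * s];
    const double *a2 = &A2[4 * s];
    // column-major 2x2: [0]=A(1,1) [1]=A(2,1) [2]=A(1,2) [3]=A(2,2)
    double xa = a1[0] * x1a + a1[2] * x1b + a2[0] * x2a + a2[2] * x2b +
                noise(t, 0);
    double xb = a1[1] * x1a + a1[3] * x1b + a2[1] * x2a + a2[3] * x2b +
                noise(t, 1);
    x(t, 0) = xa;
    x(t, 1) = xb;
    x2a = x1a; x2b = x1b;
    x1a = xa;  x1b = xb;
  }
  return x;
}

static inline double jr_sigmoid(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// Jansen-Rit network integrated with the stochastic Heun scheme.
//
// State per node: y0..y5 (three PSPs and their derivatives); output is the
// pyramidal membrane potential y1 - y2. Coupling into node i at step t is
// sum_j W_ij(segment) * S(out_j(t - d_ij)), with S() precomputed into a ring
// buffer at store time. The white-noise drive enters the excitatory input
// (y4 equation) additively with amplitude He*a*drive_sd; its Wiener
// increment is applied once per step (predictor and corrector share it).
// Output is block-averaged over `decim` steps (FIR anti-alias) after
// discarding `burn_steps`.
// [[Rcpp::export]]
NumericMatrix nmm_simulate_cpp(int n_nodes, int n_steps, double dt,
                               List params, NumericVector coupling,
                               IntegerVector seg_ends,
                               IntegerMatrix delay_steps,
                               NumericVector init_state, double init_sig,
                               int decim, int burn_steps) {
  const double He = params["He"], Hi = params["Hi"];
  const double a = params["a"], b = params["b"];
  const double C1 = params["C1"], C2 = params["C2"];
  const double C3 = params["C3"], C4 = params["C4"];
  const double e0 = params["e0"], v0 = params["v0"], r = params["r"];
  const double p_mean = params["drive_mean"], p_sd = params["drive_sd"];
  const int N = n_nodes;
  const int n_seg = seg_ends.size();
  IntegerVector cdim = coupling.attr("dim");
  if (cdim[0] != N || cdim[1] != N || cdim[2] != n_seg)
    stop("coupling array must be N x N x n_segments");
  if (init_state.size() != 6) stop("init_state must have length 6");

  int max_delay = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
  const int buflen = max_delay + 1;

  // ring buffer of S(output) per node, seeded with the fixed-point value
  std::vector<double> sigbuf((size_t)N * buflen, init_sig);
  std::vector<double> y((size_t)N * 6);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < 6; ++s) y[(size_t)i * 6 + s] = init_state[s];

  const double g = He * a * p_sd;       // noise amplitude in the y4 equation
  const double sqdt = std::sqrt(dt);
  const int n_out = (n_steps - burn_steps) / decim;
  NumericMatrix out(n_out, N);
  std::vector<double> acc(N, 0.0);
  std::vector<double> coup(N), f1(6), yp(6), f2(6), dW(N);

  int seg = 0;
  int acc_count = 0, out_row = 0;
  for (int t = 0; t < n_steps; ++t) {
    while (t >= seg_ends[seg] && seg < n_seg - 1) ++seg;
    const double *W = &coupling[(size_t)seg * N * N];
    const int tmod = t % buflen;
    // delayed coupling input, frozen over the step
    for (int i = 0; i < N; ++i) {
      double ci = 0.0;
      for (int j = 0; j < N; ++j) {
        const double w = W[i + (size_t)N * j];
        if (w != 0.0) {
          int idx = t - delay_steps(i, j);
          int m = idx >= 0 ? idx % buflen : tmod; // pre-history: fixed point
          if (idx < 0) {
            ci += w * init_sig;
          } else {
            ci += w * sigbuf[(size_t)j * buflen + m];
          }
        }
      }
      coup[i] = ci;
    }
    for (int i = 0; i < N; ++i) dW[i] = sqdt * R::rnorm(0.0, 1.0);

    for (int i = 0; i < N; ++i) {
      double *yi = &y[(size_t)i * 6];
      const double ci = coup[i];
      // drift at current state
      f1[0] = yi[3];
      f1[1] = yi[4];
      f1[2] = yi[5];
      f1[3] = He * a * jr_sigmoid(yi[1] - yi[2], e0, v0, r) -
              2.0 * a * yi[3] - a * a * yi[0];
      f1[4] = He * a * (p_mean + C2 * jr_sigmoid(C1 * yi[0], e0, v0, r) + ci) -
              2.0 * a * yi[4] - a * a * yi[1];
      f1[5] = Hi * b * C4 * jr_sigmoid(C3 * yi[0], e0, v0, r) -
              2.0 * b * yi[5] - b * b * yi[2];
      // predictor (with the shared noise increment)
      for (int s = 0; s < 6; ++s) yp[s] = yi[s] + dt * f1[s];
      yp[4] += g * dW[i];
      // drift at predictor
      f2[0] = yp[3];
      f2[1] = yp[4];
      f2[2] = yp[5];
      f2[3] = He * a * jr_sigmoid(yp[1] - yp[2], e0, v0, r) -
              2.0 * a * yp[3] - a * a * yp[0];
      f2[4] = He * a * (p_mean + C2 * jr_sigmoid(C1 * yp[0], e0, v0, r) + ci) -
              2.0 * a * yp[4] - a * a * yp[1];
      f2[5] = Hi * b * C4 * jr_sigmoid(C3 * yp[0], e0, v0, r) -
              2.0 * b * yp[5] - b * b * yp[2];
      // corrector
      for (int s = 0; s < 6; ++s) yi[s] += 0.5 * dt * (f1[s] + f2[s]);
      yi[4] += g * dW[i];
      const double outv = yi[1] - yi[2];
      if (!std::isfinite(outv) || std::fabs(outv) > 1e6)
        stop("integration diverged at step %d (node %d)", t, i + 1);
      sigbuf[(size_t)i * buflen + ((t + 1) % buflen)] =
          jr_sigmoid(outv, e0, v0, r);
      if (t >= burn_steps) acc[i] += outv;
    }
    if (t >= burn_steps) {
      if (++acc_count == decim) {
        if (out_row < n_out) {
          for (int i = 0; i < N; ++i) out(out_row, i) = acc[i] / decim;
          ++out_row;
        }
        std::fill(acc.begin(), acc.end(), 0.0);
        acc_count = 0;
      }
    }
  }
  return out;
}
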