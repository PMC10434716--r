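#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Truncated, integral-normalized Gaussian kernel: sum(k) * spacing == amp.
// Support is +/- 3 widths, at least one tap each side.
static std::vector<double> make_kernel(double amp, double width, double spacing) {
  int half = std::max(1, (int)std::ceil(3.0 * width / spacing));
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    double d = i * spacing;
    double g = std::exp(-0.5 * d * d / (width * width));
    k[i + half] = g;
    s += g * spacing;
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] *= amp / s;
  return k;
}

// Zero-padded (open boundary) convolution, out[i] = sum_j k[j] * x[i - half + j] * spacing
static void convolve(const std::vector<double>& x, const std::vector<double>& k,
                     double spacing, std::vector<double>& out) {
  int n = x.size();
  int half = ((int)k.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    int j0 = std::max(0, i - half), j1 = std::min(n - 1, i + half);
    for (int j = j0; j <= j1; ++j) acc += k[j - i + half] * x[j];
    out[i] = acc * spacing;
  }
}

// Scatter form of the same convolution, skipping negligible sources. The
// field is at rest (rate ~ exp(-beta*|h_u|) ~ 0) over most of the grid, so
// looping over active sources only is much cheaper; the truncation error is
// bounded by n * max(k) * 1e-12.
static void convolve_sparse(const std::vector<double>& x, const std::vector<double>& k,
                            double spacing, std::vector<double>& out) {
  int n = x.size();
  int half = ((int)k.size() - 1) / 2;
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    double xv = x[j];
    if (xv <= 1e-12) continue;
    int i0 = std::max(0, j - half), i1 = std::min(n - 1, j + half);
    for (int i = i0; i <= i1; ++i) out[i] += k[j - i + half] * xv;
  }
  for (int i = 0; i < n; ++i) out[i] *= spacing;
}

static inline double sigm(double x, double beta) {
  double z = beta * x;
  if (z < -28.0) return 0.0;   // below double-precision relevance
  if (z > 28.0) return 1.0;
  return 1.0 / (1.0 + std::exp(-z));
}

static void check_finite(const std::vector<double>& x, const char* name) {
  for (size_t i = 0; i < x.size(); ++i)
    if (!std::isfinite(x[i]))
      stop("integration diverged: non-finite value in field '%s'", name);
}

struct Params {
  double tau_u, tau_v, h_u, h_v, beta;
  double w_uu_amp, w_uu_width, w_uv_amp, w_uv_width, w_vu_amp, w_vu_width;
  double trace_build_tau, trace_decay_tau, trace_gain, trace_spread, trace_sat;
  double adapt_tau, adapt_decay_tau, adapt_gain, adapt_spread;
  double noise_slow_tau, noise_slow_amp, noise_fast_amp;
  double input_width, dt;
  int n_points; double spacing;
};

static Params read_params(const List& p) {
  Params q;
  q.tau_u = p["tau_u"]; q.tau_v = p["tau_v"];
  q.h_u = p["h_u"]; q.h_v = p["h_v"]; q.beta = p["beta"];
  q.w_uu_amp = p["w_uu_amp"]; q.w_uu_width = p["w_uu_width"];
  q.w_uv_amp = p["w_uv_amp"]; q.w_uv_width = p["w_uv_width"];
  q.w_vu_amp = p["w_vu_amp"]; q.w_vu_width = p["w_vu_width"];
  q.trace_build_tau = p["trace_build_tau"]; q.trace_decay_tau = p["trace_decay_tau"];
  q.trace_gain = p["trace_gain"]; q.trace_spread = p["trace_spread"];
  q.trace_sat = p["trace_sat"];
  q.adapt_tau = p["adapt_tau"]; q.adapt_decay_tau = p["adapt_decay_tau"];
  q.adapt_gain = p["adapt_gain"]; q.adapt_spread = p["adapt_spread"];
  q.noise_slow_tau = p["noise_slow_tau"]; q.noise_slow_amp = p["noise_slow_amp"];
  q.noise_fast_amp = p["noise_fast_amp"];
  q.input_width = p["input_width"]; q.dt = p["dt"];
  q.n_points = p["n_points"]; q.spacing = p["spacing"];
  return q;
}

// Stimulus input field: sum of Gaussian bumps with peak amplitude amp and
// SD = input_width / 2 (input_width is the full width of the line segment).
static std::vector<double> build_input(const NumericVector& centers,
                                       const NumericVector& amps,
                                       const Params& q) {
  std::vector<double> S(q.n_points, 0.0);
  double x0 = -0.5 * (q.n_points - 1) * q.spacing;
  double sd = q.input_width / 2.0;
  for (int k = 0; k < centers.size(); ++k) {
    for (int i = 0; i < q.n_points; ++i) {
      double d = x0 + i * q.spacing - centers[k];
      S[i] += amps[k] * std::exp(-0.5 * d * d / (sd * sd));
    }
  }
  return S;
}

// [[Rcpp::export]]
List nf_run(NumericVector durations,        // per-frame durations (ms)
            List frame_centers,             // per-frame input centers (field units)
            List frame_amps,                // per-frame input amplitudes
            List params,
            double n0,                      // initial slow-noise offset
            NumericVector judge_center,     // per-frame readout center (NA = not judged)
            double judge_halfwidth,
            double record_stride,           // ms; <= 0 disables the record
            NumericVector init_u,           // length 0 = resting init
            NumericVector init_v,
            NumericVector init_m,
            NumericVector init_a) {
  Params q = read_params(params);
  int n = q.n_points, n_frames = durations.size();
  double sp = q.spacing, dt = q.dt;

  std::vector<double> k_uu = make_kernel(q.w_uu_amp, q.w_uu_width, sp);
  std::vector<double> k_uv = make_kernel(q.w_uv_amp, q.w_uv_width, sp);
  std::vector<double> k_vu = make_kernel(q.w_vu_amp, q.w_vu_width, sp);
  std::vector<double> k_ts = make_kernel(1.0, q.trace_spread, sp);
  std::vector<double> k_as = make_kernel(1.0, q.adapt_spread, sp);

  std::vector<double> u(n, q.h_u + n0), v(n, q.h_v), m(n, 0.0), a(n, 0.0);
  if (init_u.size() == n) for (int i = 0; i < n; ++i) u[i] = init_u[i];
  if (init_v.size() == n) for (int i = 0; i < n; ++i) v[i] = init_v[i];
  if (init_m.size() == n) for (int i = 0; i < n; ++i) m[i] = init_m[i];
  if (init_a.size() == n) for (int i = 0; i < n; ++i) a[i] = init_a[i];
  double nn = n0, t = 0.0;

  std::vector<double> fu(n), fv(n), exc(n), inh(n), dv(n), ms(n), as(n);
  double x0 = -0.5 * (n - 1) * sp;

  // record bookkeeping
  bool record = record_stride > 0;
  int total_steps = 0;
  std::vector<int> steps_per_frame(n_frames);
  for (int f = 0; f < n_frames; ++f) {
    steps_per_frame[f] = std::max(1, (int)std::lround(durations[f] / dt));
    total_steps += steps_per_frame[f];
  }
  int rec_every = record ? std::max(1, (int)std::lround(record_stride / dt)) : 0;
  int n_rec = record ? (total_steps + rec_every - 1) / rec_every + 1 : 0;
  NumericMatrix rec_u = record ? NumericMatrix(n_rec, n) : NumericMatrix(0, 0);
  NumericVector rec_t(record ? n_rec : 0);
  IntegerVector rec_f(record ? n_rec : 0);
  int rec_i = 0;

  NumericVector frac_supra(n_frames, NA_REAL);
  double ou_decay = 1.0 - dt / q.noise_slow_tau;
  double ou_sd = q.noise_slow_amp * std::sqrt(2.0 * dt / q.noise_slow_tau);
  double fast_sd = q.noise_fast_amp * std::sqrt(dt);
  double sqdt = dt; (void)sqdt;
  int global_step = 0;

  if (record) { // initial sample
    for (int i = 0; i < n; ++i) rec_u(rec_i, i) = u[i];
    rec_t[rec_i] = 0.0; rec_f[rec_i] = 0; ++rec_i;
  }

  for (int f = 0; f < n_frames; ++f) {
    NumericVector ctr = frame_centers[f], amp = frame_amps[f];
    std::vector<double> S = build_input(ctr, amp, q);
    bool any_input = false;
    for (int i = 0; i < n; ++i) if (S[i] != 0.0) { any_input = true; break; }

    // readout window for this frame
    int j0 = -1, j1 = -1;
    bool judged = !NumericVector::is_na(judge_center[f]);
    if (judged) {
      j0 = std::max(0, (int)std::floor((judge_center[f] - judge_halfwidth - x0) / sp));
      j1 = std::min(n - 1, (int)std::ceil((judge_center[f] + judge_halfwidth - x0) / sp));
    }
    int supra_steps = 0;

    for (int s = 0; s < steps_per_frame[f]; ++s, ++global_step) {
      for (int i = 0; i < n; ++i) fu[i] = sigm(u[i], q.beta);
      for (int i = 0; i < n; ++i) fv[i] = sigm(v[i], q.beta);
      convolve_sparse(fu, k_uu, sp, exc);
      convolve_sparse(fv, k_uv, sp, inh);
      convolve_sparse(fu, k_vu, sp, dv);

      double m_max = 0.0, a_max = 0.0;
      for (int i = 0; i < n; ++i) { if (m[i] > m_max) m_max = m[i]; if (a[i] > a_max) a_max = a[i]; }
      if (m_max > 1e-12) convolve_sparse(m, k_ts, sp, ms); else std::fill(ms.begin(), ms.end(), 0.0);
      if (a_max > 1e-12) convolve_sparse(a, k_as, sp, as); else std::fill(as.begin(), as.end(), 0.0);

      for (int i = 0; i < n; ++i) {
        double S_eff = 0.0;
        if (any_input) {
          S_eff = S[i] * (1.0 - q.adapt_gain * as[i]);
          if (S_eff < 0.0) S_eff = 0.0;
        }
        double boost = q.trace_gain * (ms[i] < q.trace_sat ? ms[i] : q.trace_sat);
        double du = (-u[i] + q.h_u + nn + boost + S_eff + exc[i] - inh[i]) / q.tau_u;
        double dvv = (-v[i] + q.h_v + dv[i]) / q.tau_v;
        bool supra = u[i] > 0.0;
        double u_new = u[i] + dt * du;
        if (q.noise_fast_amp > 0.0) u_new += fast_sd * norm_rand();
        v[i] += dt * dvv;
        // memory trace: builds toward f(u) where above threshold, decays elsewhere
        if (supra) m[i] += dt * (fu[i] - m[i]) / q.trace_build_tau;
        else       m[i] += dt * (0.0  - m[i]) / q.trace_decay_tau;
        if (m[i] < 0.0) m[i] = 0.0;
        // adaptation: builds toward 1 where above threshold, decays elsewhere
        if (supra) a[i] += dt * (1.0 - a[i]) / q.adapt_tau;
        else       a[i] += dt * (0.0 - a[i]) / q.adapt_decay_tau;
        if (a[i] < 0.0) a[i] = 0.0; else if (a[i] > 1.0) a[i] = 1.0;
        u[i] = u_new;
      }
      if (q.noise_slow_amp > 0.0) nn = nn * ou_decay + ou_sd * norm_rand();
      else nn = nn * ou_decay;
      t += dt;

      if (judged) {
        double umax = -1e300;
        for (int i = j0; i <= j1; ++i) if (u[i] > umax) umax = u[i];
        if (umax > 0.0) ++supra_steps;
      }
      if (record && ((global_step + 1) % rec_every == 0 || global_step + 1 == total_steps)) {
        if (rec_i < n_rec) {
          for (int i = 0; i < n; ++i) rec_u(rec_i, i) = u[i];
          rec_t[rec_i] = t; rec_f[rec_i] = f + 1; ++rec_i;
        }
      }
      if ((global_step & 255) == 0) {
        check_finite(u, "u"); check_finite(v, "v");
      }
    }
    check_finite(u, "u"); check_finite(v, "v"); check_finite(m, "m"); check_finite(a, "a");
    if (judged) frac_supra[f] = (double)supra_steps / steps_per_frame[f];
  }

  List out = List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["m"] = NumericVector(m.begin(), m.end()),
    _["a"] = NumericVector(a.begin(), a.end()),
    _["n_offset"] = nn,
    _["t"] = t,
    _["frac_supra"] = frac_supra);
  if (record) {
    out["times"] = rec_t[Range(0, rec_i - 1)];
    out["frame_index"] = rec_f[Range(0, rec_i - 1)];
    out["u_trace"] = rec_u(Range(0, rec_i - 1), _);
  }
  return out;
}

// Deterministic relaxation to a stationary state (noise, trace, adaptation off).
// [[Rcpp::export]]
List nf_relax(NumericVector centers, NumericVector amps, List params,
              NumericVector init_u, NumericVector init_v,
              double tol, int max_steps) {
  Params q = read_params(params);
  int n = q.n_points; double sp = q.spacing, dt = q.dt;
  std::vector<double> k_uu = make_kernel(q.w_uu_amp, q.w_uu_width, sp);
  std::vector<double> k_uv = make_kernel(q.w_uv_amp, q.w_uv_width, sp);
  std::vector<double> k_vu = make_kernel(q.w_vu_amp, q.w_vu_width, sp);
  std::vector<double> S = build_input(centers, amps, q);
  std::vector<double> u(n, q.h_u), v(n, q.h_v);
  if (init_u.size() == n) for (int i = 0; i < n; ++i) u[i] = init_u[i];
  if (init_v.size() == n) for (int i = 0; i < n; ++i) v[i] = init_v[i];
  std::vector<double> fu(n), fv(n), exc(n), inh(n), dv(n);
  bool converged = false;
  int step = 0;
  for (; step < max_steps; ++step) {
    for (int i = 0; i < n; ++i) fu[i] = sigm(u[i], q.beta);
    for (int i = 0; i < n; ++i) fv[i] = sigm(v[i], q.beta);
    convolve(fu, k_uu, sp, exc);
    convolve(fv, k_uv, sp, inh);
    convolve(fu, k_vu, sp, dv);
    double max_du = 0.0;
    for (int i = 0; i < n; ++i) {
      double du = (-u[i] + q.h_u + S[i] + exc[i] - inh[i]) / q.tau_u;
      double dvv = (-v[i] + q.h_v + dv[i]) / q.tau_v;
      u[i] += dt * du; v[i] += dt * dvv;
      double ad = std::fabs(du) * dt;
      if (ad > max_du) max_du = ad;
      ad = std::fabs(dvv) * dt;
      if (ad > max_du) max_du = ad;
    }
    if ((step & 255) == 0) { check_finite(u, "u"); check_finite(v, "v"); }
    if (max_du < tol) { converged = true; break; }
  }
  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["converged"] = converged,
    _["steps"] = step);
}
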