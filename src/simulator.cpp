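#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Deterministic, self-contained RNG (xoshiro256++ seeded via splitmix64)
// so that simulations are reproducible from a single integer seed and
// independent of R's global RNG state. Normal deviates via the Marsaglia
// polar method.
namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_norm = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_norm;
  double spare;
  inline double norm() {
    if (have_norm) { have_norm = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_norm = true;
    return u * f;
  }
};

inline double wrap(double z, double L) {
  z -= L * std::floor(z / L);
  if (z >= L) z -= L;
  return z;
}

// squared distance from point c to segment p0 + t*(p1-p0), t in [0,1]
inline double seg_dist2(double cx, double cy, double p0x, double p0y,
                        double ux, double uy, double len) {
  double t = (cx * ux + cy * uy) / (len * len);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dx = cx - t * ux * 1.0, dy = cy - t * uy * 1.0;
  (void)p0x; (void)p0y;
  return dx * dx + dy * dy;
}

}  // namespace

// Grow axons as biased random walks and establish directed connections
// where an axon crosses a dendritic disk (one Bernoulli trial per ordered
// pair, at the first crossing).
// [[Rcpp::export]]
Rcpp::List cpp_build_network(Rcpp::NumericVector x, Rcpp::NumericVector y,
                             Rcpp::NumericVector dend_r,
                             Rcpp::NumericVector axon_len,
                             double seg_len, double angle_sd,
                             double p_conn, double Lx, double Ly,
                             bool periodic, bool keep_geometry,
                             double seed) {
  const int n = x.size();
  Rng rng((uint64_t)seed);
  double rmax = 1.0;
  for (int i = 0; i < n; ++i) if (dend_r[i] > rmax) rmax = dend_r[i];

  // uniform grid over the plating square for disk lookup
  double cell = std::max(rmax, 50.0);
  int ncx = std::max(1, (int)std::floor(Lx / cell));
  int ncy = std::max(1, (int)std::floor(Ly / cell));
  double csx = Lx / ncx, csy = Ly / ncy;
  std::vector<std::vector<int>> cells((size_t)ncx * ncy);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)(wrap(x[i], Lx) / csx));
    int cy = std::min(ncy - 1, (int)(wrap(y[i], Ly) / csy));
    cells[(size_t)cy * ncx + cx].push_back(i);
  }
  int reach_x = (int)std::ceil((rmax + seg_len) / csx) + 1;
  int reach_y = (int)std::ceil((rmax + seg_len) / csy) + 1;

  std::vector<int> stamp(n, -1);
  std::vector<int> from, to;
  Rcpp::List geom(keep_geometry ? n : 0);

  for (int i = 0; i < n; ++i) {
    double px = x[i], py = y[i];
    double theta = rng.unif() * 2.0 * M_PI;
    double remaining = axon_len[i];
    std::vector<int> cand;
    std::vector<double> verts;
    if (keep_geometry) { verts.push_back(px); verts.push_back(py); }
    while (remaining > 1e-9) {
      double L = std::min(seg_len, remaining);
      remaining -= L;
      double ux = L * std::cos(theta), uy = L * std::sin(theta);
      double qx = px + ux, qy = py + uy;
      if (keep_geometry) { verts.push_back(qx); verts.push_back(qy); }
      // candidate disks: cells around the wrapped segment start
      double wx = wrap(px, Lx), wy = wrap(py, Ly);
      int cx0 = std::min(ncx - 1, (int)(wx / csx));
      int cy0 = std::min(ncy - 1, (int)(wy / csy));
      for (int dy = -reach_y; dy <= reach_y; ++dy) {
        int cy = cy0 + dy;
        if (periodic) cy = ((cy % ncy) + ncy) % ncy;
        else if (cy < 0 || cy >= ncy) continue;
        for (int dx = -reach_x; dx <= reach_x; ++dx) {
          int cx = cx0 + dx;
          if (periodic) cx = ((cx % ncx) + ncx) % ncx;
          else if (cx < 0 || cx >= ncx) continue;
          const std::vector<int>& bucket = cells[(size_t)cy * ncx + cx];
          for (size_t bi = 0; bi < bucket.size(); ++bi) {
            int j = bucket[bi];
            if (j == i || stamp[j] == i) continue;
            // displacement of disk centre relative to segment start
            double cxr = x[j] - px, cyr = y[j] - py;
            if (periodic) {
              cxr = x[j] - wx; cyr = y[j] - wy;
              if (cxr > 0.5 * Lx) cxr -= Lx;
              if (cxr < -0.5 * Lx) cxr += Lx;
              if (cyr > 0.5 * Ly) cyr -= Ly;
              if (cyr < -0.5 * Ly) cyr += Ly;
            }
            double d2 = seg_dist2(cxr, cyr, 0, 0, ux, uy, L);
            if (d2 <= dend_r[j] * dend_r[j]) {
              stamp[j] = i;
              cand.push_back(j);
            }
          }
        }
      }
      px = qx; py = qy;
      theta += angle_sd * rng.norm();
    }
    for (size_t c = 0; c < cand.size(); ++c) {
      if (rng.unif() < p_conn) {
        from.push_back(i + 1);
        to.push_back(cand[c] + 1);
      }
    }
    if (keep_geometry) {
      Rcpp::NumericMatrix m(verts.size() / 2, 2);
      for (size_t vtx = 0; vtx < verts.size() / 2; ++vtx) {
        m(vtx, 0) = verts[2 * vtx];
        m(vtx, 1) = verts[2 * vtx + 1];
      }
      geom[i] = m;
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("from") = Rcpp::IntegerVector(from.begin(), from.end()),
    Rcpp::Named("to") = Rcpp::IntegerVector(to.begin(), to.end()));
  if (keep_geometry) out["axons"] = geom;
  return out;
}

// Forward-Euler integration of the quadratic integrate-and-fire network
// with adaptation, exponential synaptic currents scaled by short-term
// depression, Poisson miniature currents and white membrane noise.
// Times in ms, potentials/currents in mV. Spikes are returned for all
// neurons (1-based ids, times in ms).
// [[Rcpp::export]]
Rcpp::List cpp_simulate_culture(
    int n, Rcpp::IntegerVector adj_ptr, Rcpp::IntegerVector adj_tgt,
    Rcpp::NumericVector v_r, Rcpp::NumericVector v_c,
    Rcpp::NumericVector d_jump, Rcpp::NumericVector g_out,
    Rcpp::LogicalVector is_inh, Rcpp::NumericVector beta_syn,
    Rcpp::NumericVector tau_D,
    double C, double k, double v_t, double v_p, double b, double tau_a,
    double g_s, double lambda_mini, double g_m, double tau_m,
    double tau_e, double tau_i,
    double duration_ms, double dt, double seed, double v_guard,
    double I_ext, int record_neuron) {
  if (n < 1 || dt <= 0 || duration_ms <= 0)
    Rcpp::stop("invalid simulation size or time step");
  Rng rng((uint64_t)seed);
  std::vector<double> v(n), u(n, 0.0), Ie(n, 0.0), Ii(n, 0.0), Im(n, 0.0),
      D(n, 1.0);
  std::vector<double> recov(n);
  for (int i = 0; i < n; ++i) {
    v[i] = v_r[i];
    recov[i] = dt / tau_D[i];
  }
  const double fe = std::exp(-dt / tau_e);
  const double fi = std::exp(-dt / tau_i);
  const double fm = std::exp(-dt / tau_m);
  const double dtC = dt / C;
  const double dt_tau_a = dt / tau_a;
  const double p_mini = lambda_mini * dt;
  // Euler-Maruyama: eta = g_s * sqrt(2/dt) * xi contributes dt/C * eta
  const double noise_amp = dtC * g_s * std::sqrt(2.0 / dt);
  const long n_steps = (long)std::ceil(duration_ms / dt);
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 20);
  spike_t.reserve(1 << 20);
  std::vector<int> fired;
  fired.reserve(256);
  const bool record = record_neuron >= 1 && record_neuron <= n;
  std::vector<double> rec_v, rec_u, rec_D;
  if (record) {
    rec_v.reserve(n_steps);
    rec_u.reserve(n_steps);
    rec_D.reserve(n_steps);
  }

  for (long step = 0; step < n_steps; ++step) {
    double t_now = (step + 1) * dt;
    fired.clear();
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double dv = dtC * (k * (vi - v_r[i]) * (vi - v_t) - u[i] +
                         Ie[i] + Ii[i] + Im[i] + I_ext) +
                  noise_amp * rng.norm();
      u[i] += dt_tau_a * (b * (vi - v_r[i]) - u[i]);
      vi += dv;
      Ie[i] *= fe;
      Ii[i] *= fi;
      Im[i] *= fm;
      D[i] += recov[i] * (1.0 - D[i]);
      if (rng.unif() < p_mini) Im[i] += g_m;
      if (vi >= v_p) {
        vi = v_c[i];
        u[i] += d_jump[i];
        fired.push_back(i);
      } else if (vi < -v_guard || vi != vi) {
        Rcpp::stop("integration diverged at neuron %d, t = %.3f ms",
                   i + 1, t_now);
      }
      v[i] = vi;
    }
    for (size_t f = 0; f < fired.size(); ++f) {
      int i = fired[f];
      spike_id.push_back(i + 1);
      spike_t.push_back(t_now);
      double w = g_out[i] * D[i];
      if (w != 0.0) {
        if (is_inh[i]) {
          for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e)
            Ii[adj_tgt[e] - 1] += w;
        } else {
          for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e)
            Ie[adj_tgt[e] - 1] += w;
        }
      }
      D[i] *= beta_syn[i];
    }
    if (record) {
      int ri = record_neuron - 1;
      rec_v.push_back(v[ri]);
      rec_u.push_back(u[ri]);
      rec_D.push_back(D[ri]);
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("neuron") = Rcpp::IntegerVector(spike_id.begin(),
                                                spike_id.end()),
    Rcpp::Named("time_ms") = Rcpp::NumericVector(spike_t.begin(),
                                                 spike_t.end()));
  if (record) {
    out["state"] = Rcpp::List::create(
      Rcpp::Named("v") = Rcpp::NumericVector(rec_v.begin(), rec_v.end()),
      Rcpp::Named("u") = Rcpp::NumericVector(rec_u.begin(), rec_u.end()),
      Rcpp::Named("D") = Rcpp::NumericVector(rec_D.begin(), rec_D.end()));
  }
  return out;
}
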