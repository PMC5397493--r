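// Euler-Maruyama integrator for the depressing ring network.
//
// The recurrent drive (1/N) sum_j W_ij U x_j m_j with
// W_ij = J0 + J1 cos(2(theta_i - theta_j)) is evaluated in O(N) per step via
// the identity cos(2(ti-tj)) = cos2ti*cos2tj + sin2ti*sin2tj, so one step
// needs only three population sums. This is exact, not an approximation.
//
// Two RNG streams: network noise uses R's RNG (seeded by set.seed() on the
// R side, so runs are reproducible with the usual mechanism); Poisson spike
// sampling for the sparse readout uses a self-contained splitmix64 stream
// with its own seed, so the network trajectory is invariant to readout
// configuration.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SpikeRng {
  uint64_t s;
  explicit SpikeRng(double seed) : s(static_cast<uint64_t>(seed)) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // Knuth's method; spike means m*dt are well below 1 in practice
  int pois(double lambda) {
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

inline double softplus(double y) {
  return y > 0.0 ? y + std::log1p(std::exp(-y)) : std::log1p(std::exp(y));
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(int N, double J0, double J1, double tau, double tau_rec,
                  double tau_n, double sigma, double U, double I0, double dt,
                  NumericVector m0, NumericVector x0, NumericVector n0,
                  int n_steps, int record_stride, int burn_in_steps,
                  NumericVector stim_onset, NumericVector stim_theta,
                  double stim_C, double stim_T,
                  List readout_idx, double tau_rd, double spike_seed,
                  bool record_trace) {
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> In(n0.begin(), n0.end());

  std::vector<double> c2(N), s2(N);
  for (int i = 0; i < N; ++i) {
    double th = 2.0 * M_PI * i / N;  // 2*theta_i with theta_i = i*pi/N
    c2[i] = std::cos(th);
    s2[i] = std::sin(th);
  }

  const int n_ev = stim_onset.size();
  int kptr = 0;
  double ev_c = 0.0, ev_s = 0.0;  // cos(2*theta_k), sin(2*theta_k)
  int ev_cached = -1;

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix m_rec(N, n_rec), x_rec(N, n_rec);
  NumericVector t_rec(n_rec);
  int rec_i = 0;

  NumericVector er_re, er_im;
  if (record_trace) {
    er_re = NumericVector(n_steps);
    er_im = NumericVector(n_steps);
  }

  const int n_sets = readout_idx.size();
  std::vector<std::vector<int>> sets(n_sets);
  std::vector<NumericVector> r_re(n_sets), r_im(n_sets);
  std::vector<double> Rre(n_sets, 0.0), Rim(n_sets, 0.0);
  for (int r = 0; r < n_sets; ++r) {
    IntegerVector iv = readout_idx[r];
    sets[r].assign(iv.begin(), iv.end());  // 0-based
    r_re[r] = NumericVector(n_steps);
    r_im[r] = NumericVector(n_steps);
  }
  SpikeRng srng(spike_seed);

  const double noise_decay = dt / tau_n;
  const double noise_amp = sigma * std::sqrt(2.0 * dt / tau_n);
  const double rd_decay = (n_sets > 0) ? dt / tau_rd : 0.0;

  double mean_acc = 0.0;
  long mean_n = 0;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    if (s % record_stride == 0) {
      t_rec[rec_i] = t;
      for (int i = 0; i < N; ++i) {
        m_rec(i, rec_i) = m[i];
        x_rec(i, rec_i) = x[i];
      }
      ++rec_i;
    }

    // population sums for recurrent drive and exact PV
    double Sm = 0.0, Sc = 0.0, Ss = 0.0, Smm = 0.0, Scm = 0.0, Ssm = 0.0;
    for (int i = 0; i < N; ++i) {
      double xm = x[i] * m[i];
      Sm += xm;
      Sc += c2[i] * xm;
      Ss += s2[i] * xm;
      Smm += m[i];
      Scm += c2[i] * m[i];
      Ssm += s2[i] * m[i];
    }
    if (record_trace) {
      er_re[s] = Scm / N;
      er_im[s] = -Ssm / N;
    }
    if (s >= burn_in_steps) {
      mean_acc += Smm / N;
      ++mean_n;
    }

    // active stimulus window [t_k, t_k + T)
    bool active = false;
    while (kptr < n_ev && t >= stim_onset[kptr] + stim_T) ++kptr;
    if (kptr < n_ev && t >= stim_onset[kptr]) {
      active = true;
      if (ev_cached != kptr) {
        ev_c = std::cos(2.0 * stim_theta[kptr]);
        ev_s = std::sin(2.0 * stim_theta[kptr]);
        ev_cached = kptr;
      }
    }

    // sparse readouts: Poisson counts enter as unit-area impulses counts/dt
    for (int r = 0; r < n_sets; ++r) {
      double acc_re = 0.0, acc_im = 0.0;
      const std::vector<int>& idx = sets[r];
      for (size_t j = 0; j < idx.size(); ++j) {
        int u = idx[j];
        int k = srng.pois(m[u] * dt);
        if (k > 0) {
          acc_re += c2[u] * k;
          acc_im -= s2[u] * k;
        }
      }
      double nr = static_cast<double>(idx.size());
      double newRe = Rre[r] * (1.0 - rd_decay) + acc_re / (tau_rd * nr);
      double newIm = Rim[r] * (1.0 - rd_decay) + acc_im / (tau_rd * nr);
      r_re[r][s] = Rre[r];
      r_im[r][s] = Rim[r];
      Rre[r] = newRe;
      Rim[r] = newIm;
    }

    const double uJ0Sm = U * J0 * Sm / N;
    const double uJ1c = U * J1 * Sc / N;
    const double uJ1s = U * J1 * Ss / N;

    for (int i = 0; i < N; ++i) {
      double inp = active ? stim_C * (ev_c * c2[i] + ev_s * s2[i]) : 0.0;
      double y = uJ0Sm + uJ1c * c2[i] + uJ1s * s2[i] + inp + In[i] + I0;
      double m_new = m[i] + (dt / tau) * (softplus(y) - m[i]);
      double x_new = x[i] + dt * ((1.0 - x[i]) / tau_rec - U * x[i] * m[i]);
      if (!(m_new > 0.0) || !(x_new > 0.0) || x_new > 1.0 + 1e-12) {
        stop("state invariant violated at t = %f (unit %d: m = %g, x = %g); "
             "dt is likely too large for these parameters",
             t + dt, i + 1, m_new, x_new);
      }
      m[i] = m_new;
      x[i] = x_new;
      In[i] += -noise_decay * In[i] + noise_amp * R::rnorm(0.0, 1.0);
    }
  }

  // state after the final step
  if (n_steps % record_stride == 0 && rec_i < n_rec) {
    t_rec[rec_i] = n_steps * dt;
    for (int i = 0; i < N; ++i) {
      m_rec(i, rec_i) = m[i];
      x_rec(i, rec_i) = x[i];
    }
    ++rec_i;
  }

  List R_list(n_sets);
  for (int r = 0; r < n_sets; ++r)
    R_list[r] = List::create(_["re"] = r_re[r], _["im"] = r_im[r]);

  return List::create(
      _["t_rec"] = t_rec[Range(0, rec_i - 1)],
      _["m_rec"] = m_rec(_, Range(0, rec_i - 1)),
      _["x_rec"] = x_rec(_, Range(0, rec_i - 1)),
      _["er_re"] = er_re, _["er_im"] = er_im,
      _["readout"] = R_list,
      _["mean_rate"] = mean_n > 0 ? mean_acc / mean_n : NA_REAL,
      _["final_m"] = NumericVector(m.begin(), m.end()),
      _["final_x"] = NumericVector(x.begin(), x.end()),
      _["final_noise"] = NumericVector(In.begin(), In.end()));
}
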