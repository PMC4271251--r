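#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the coupled FitzHugh-Nagumo network with
// delayed dual-exponential chemical synapses.
//
// Gating per presynaptic neuron i:
//   s_i(t) = sum_k [exp(-(t-t_k-tau)/tau_d) - exp(-(t-t_k-tau)/tau_r)]
// maintained incrementally as s_i = D_i - R_i with two exponential
// accumulators; a spike detected at t_k matures (enters the accumulators)
// at the first step boundary >= t_k + tau, with an exact decay correction
// for the sub-step offset, so the maturation error is below one step.
//
// Adjacency is passed in CSR form (0-based): neighbours of node i are
// nbr[off[i] .. off[i+1]-1].

struct PendingSpike {
  double t_on;  // t_spike + tau
  int node;
};

// [[Rcpp::export]]
List sim_core(IntegerVector nbr, IntegerVector off,
              NumericVector f, NumericVector gmax,
              double eps, double a, double b, double d,
              double u_syn, double tau, double tau_d, double tau_r,
              double u_th, double debounce,
              double A, double B, double omega, double T0, int target,
              NumericVector u0, NumericVector v0,
              double dt, double t_end, double settle,
              int record_stride, bool record_states, double blowup) {
  const int N = f.size();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> Dacc(N, 0.0), Racc(N, 0.0);
  std::vector<std::vector<double> > spikes(N);
  std::vector<double> last_spike(N, -1e18);
  std::deque<PendingSpike> queue;  // FIFO: constant delay keeps it sorted

  const long nsettle = (long)std::llround(settle / dt);
  const long nsteps  = (long)std::llround(t_end / dt) + nsettle;
  const double decay_d = std::exp(-dt / tau_d);
  const double decay_r = std::exp(-dt / tau_r);
  // gating evaluation factors at the RK4 stage offsets 0, dt/2, dt
  const double half_d = std::exp(-0.5 * dt / tau_d);
  const double half_r = std::exp(-0.5 * dt / tau_r);

  std::vector<double> k1u(N), k1v(N), k2u(N), k2v(N), k3u(N), k3v(N),
      k4u(N), k4v(N), uu(N), vv(N);

  // trajectory recording
  std::vector<double> rec_t;
  std::vector<double> rec_u, rec_v;  // column-major blocks of length N
  long nrec_est = record_states ? (long)(std::llround(t_end / dt) / record_stride + 2) : 0;
  if (record_states) {
    rec_t.reserve(nrec_est);
    rec_u.reserve(nrec_est * N);
    rec_v.reserve(nrec_est * N);
  }

  bool blew_up = false;
  double blow_t = NA_REAL;
  int blow_node = NA_INTEGER;

  for (long step = 0; step < nsteps && !blew_up; ++step) {
    const double t = (step - nsettle) * dt;

    // mature pending spikes whose onset lies at or before the current time
    while (!queue.empty() && queue.front().t_on <= t) {
      const PendingSpike ev = queue.front();
      queue.pop_front();
      const double lag = t - ev.t_on;  // in [0, dt)
      Dacc[ev.node] += std::exp(-lag / tau_d);
      Racc[ev.node] += std::exp(-lag / tau_r);
    }

    // one derivative evaluation; fd/fr give the gating decay from t to the
    // stage time, stim is the external current at the stage time
    // (stimulus active only for stage_t in [0, T0))
    auto deriv = [&](const std::vector<double>& U, const std::vector<double>& V,
                     double fd, double fr, double stage_t,
                     std::vector<double>& dU, std::vector<double>& dV) {
      double stim = 0.0;
      if (stage_t >= 0.0 && stage_t < T0)
        stim = A * std::sin(omega * stage_t) + B;
      for (int i = 0; i < N; ++i) {
        double Isum = 0.0;
        for (int p = off[i]; p < off[i + 1]; ++p) {
          const int j = nbr[p];
          const double s = Dacc[j] * fd - Racc[j] * fr;
          Isum += (f[j] + gmax[j] * s) * (u_syn - U[i]);
        }
        if (i == target) Isum += stim;
        dU[i] = (U[i] - U[i] * U[i] * U[i] / 3.0 - V[i] + Isum) / eps;
        dV[i] = a * U[i] + b * V[i] + d;
      }
    };

    deriv(u, v, 1.0, 1.0, t, k1u, k1v);
    for (int i = 0; i < N; ++i) { uu[i] = u[i] + 0.5 * dt * k1u[i]; vv[i] = v[i] + 0.5 * dt * k1v[i]; }
    deriv(uu, vv, half_d, half_r, t + 0.5 * dt, k2u, k2v);
    for (int i = 0; i < N; ++i) { uu[i] = u[i] + 0.5 * dt * k2u[i]; vv[i] = v[i] + 0.5 * dt * k2v[i]; }
    deriv(uu, vv, half_d, half_r, t + 0.5 * dt, k3u, k3v);
    for (int i = 0; i < N; ++i) { uu[i] = u[i] + dt * k3u[i]; vv[i] = v[i] + dt * k3v[i]; }
    deriv(uu, vv, decay_d, decay_r, t + dt, k4u, k4v);

    for (int i = 0; i < N; ++i) {
      const double unew = u[i] + dt / 6.0 * (k1u[i] + 2.0 * k2u[i] + 2.0 * k3u[i] + k4u[i]);
      const double vnew = v[i] + dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      // upward threshold crossing with linear interpolation
      if (u[i] < u_th && unew >= u_th) {
        const double tc = t + dt * (u_th - u[i]) / (unew - u[i]);
        if (tc - last_spike[i] >= debounce) {
          last_spike[i] = tc;
          if (tc >= 0.0) spikes[i].push_back(tc);
          queue.push_back({tc + tau, i});
        }
      }
      u[i] = unew;
      v[i] = vnew;
      if (std::fabs(unew) > blowup && !blew_up) {
        blew_up = true;
        blow_t = t + dt;
        blow_node = i + 1;
      }
    }

    for (int i = 0; i < N; ++i) {
      Dacc[i] *= decay_d;
      Racc[i] *= decay_r;
    }

    if (record_states && step >= nsettle && ((step - nsettle) % record_stride == 0)) {
      rec_t.push_back(t + dt);
      for (int i = 0; i < N; ++i) rec_u.push_back(u[i]);
      for (int i = 0; i < N; ++i) rec_v.push_back(v[i]);
    }

    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  List spk(N);
  for (int i = 0; i < N; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  List out = List::create(
      _["spikes"] = spk,
      _["u_final"] = NumericVector(u.begin(), u.end()),
      _["v_final"] = NumericVector(v.begin(), v.end()),
      _["blew_up"] = blew_up,
      _["blow_t"] = blow_t,
      _["blow_node"] = blow_node);
  if (record_states) {
    const int nr = (int)rec_t.size();
    NumericMatrix U(nr, N), V(nr, N);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < N; ++i) {
        U(r, i) = rec_u[(size_t)r * N + i];
        V(r, i) = rec_v[(size_t)r * N + i];
      }
    out["times"] = NumericVector(rec_t.begin(), rec_t.end());
    out["u"] = U;
    out["v"] = V;
  }
  return out;
}
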