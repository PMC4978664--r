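#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 method-of-lines integrator for the delayed
// reaction-diffusion logistic system with feedback control on [0, l*pi],
// node-centered grid with mirror-ghost Neumann boundaries. The delayed
// population field is read from a ring buffer of the last k_delay + 1
// stored states, so the delay lookup at whole steps is an exact buffer
// index; half-step stage values use linear interpolation between adjacent
// buffer slots.

static inline void laplacian(const std::vector<double>& f, std::vector<double>& out,
                             int M, double ih2) {
  out[0] = 2.0 * (f[1] - f[0]) * ih2;
  for (int i = 1; i < M - 1; ++i)
    out[i] = (f[i - 1] - 2.0 * f[i] + f[i + 1]) * ih2;
  out[M - 1] = 2.0 * (f[M - 2] - f[M - 1]) * ih2;
}

struct Params {
  double d1, d2, r, K, a1, a2, c, b, a;
};

static inline void rhs(const Params& p, int M, double ih2,
                       const std::vector<double>& N, const std::vector<double>& u,
                       const std::vector<double>& Nlag,
                       std::vector<double>& lapN, std::vector<double>& lapu,
                       std::vector<double>& dN, std::vector<double>& du) {
  laplacian(N, lapN, M, ih2);
  laplacian(u, lapu, M, ih2);
  for (int i = 0; i < M; ++i) {
    dN[i] = p.d1 * lapN[i] +
      p.r * N[i] * (1.0 - (p.a1 * N[i] + p.a2 * Nlag[i]) / p.K - p.c * u[i]);
    du[i] = p.d2 * lapu[i] + p.b * Nlag[i] - p.a * u[i];
  }
}

// [[Rcpp::export]]
List rdlf_integrate(NumericVector par, int M, double h, double dt,
                    int n_steps, int k_delay, int save_every,
                    NumericMatrix histN, NumericVector N0, NumericVector u0,
                    double cap) {
  Params p;
  p.d1 = par["d1"]; p.d2 = par["d2"]; p.r = par["r"]; p.K = par["K"];
  p.a1 = par["a1"]; p.a2 = par["a2"]; p.c = par["c"]; p.b = par["b"];
  p.a = par["a"];
  const double ih2 = 1.0 / (h * h);
  const int nslot = k_delay + 1;
  const bool delayed = k_delay > 0;

  // ring buffer of N fields at the last nslot step times
  std::vector<double> buf((size_t)nslot * M);
  if (delayed) {
    const bool const_hist = histN.ncol() == 1;
    for (int s = 0; s < nslot; ++s) {
      const int col = const_hist ? 0 : s;
      for (int i = 0; i < M; ++i) buf[(size_t)s * M + i] = histN(i, col);
    }
    for (int i = 0; i < M; ++i) buf[(size_t)k_delay * M + i] = N0[i];
  }

  std::vector<double> N(N0.begin(), N0.end()), u(u0.begin(), u0.end());
  std::vector<double> Ntmp(M), utmp(M), Nlag0(M), NlagH(M), Nlag1(M);
  std::vector<double> lapN(M), lapu(M);
  std::vector<double> k1N(M), k1u(M), k2N(M), k2u(M), k3N(M), k3u(M), k4N(M), k4u(M);

  const int n_save = n_steps / save_every + 1;
  NumericMatrix Nout(M, n_save), uout(M, n_save);
  NumericVector tout(n_save);
  for (int i = 0; i < M; ++i) { Nout(i, 0) = N[i]; uout(i, 0) = u[i]; }
  tout[0] = 0.0;
  int isave = 1, status = 0, stop_step = n_steps;

  for (int k = 0; k < n_steps; ++k) {
    if (delayed) {
      const int s0 = k % nslot;             // slot holding N(t_k - tau)
      const int s1 = (k + 1) % nslot;       // slot holding N(t_k - tau + dt)
      for (int i = 0; i < M; ++i) {
        const double a0 = buf[(size_t)s0 * M + i];
        const double a1v = buf[(size_t)s1 * M + i];
        Nlag0[i] = a0;
        NlagH[i] = 0.5 * (a0 + a1v);
        Nlag1[i] = a1v;
      }
    }

    rhs(p, M, ih2, N, u, delayed ? Nlag0 : N, lapN, lapu, k1N, k1u);
    for (int i = 0; i < M; ++i) {
      Ntmp[i] = N[i] + 0.5 * dt * k1N[i];
      utmp[i] = u[i] + 0.5 * dt * k1u[i];
    }
    rhs(p, M, ih2, Ntmp, utmp, delayed ? NlagH : Ntmp, lapN, lapu, k2N, k2u);
    for (int i = 0; i < M; ++i) {
      Ntmp[i] = N[i] + 0.5 * dt * k2N[i];
      utmp[i] = u[i] + 0.5 * dt * k2u[i];
    }
    rhs(p, M, ih2, Ntmp, utmp, delayed ? NlagH : Ntmp, lapN, lapu, k3N, k3u);
    for (int i = 0; i < M; ++i) {
      Ntmp[i] = N[i] + dt * k3N[i];
      utmp[i] = u[i] + dt * k3u[i];
    }
    rhs(p, M, ih2, Ntmp, utmp, delayed ? Nlag1 : Ntmp, lapN, lapu, k4N, k4u);
    for (int i = 0; i < M; ++i) {
      N[i] += dt / 6.0 * (k1N[i] + 2.0 * k2N[i] + 2.0 * k3N[i] + k4N[i]);
      u[i] += dt / 6.0 * (k1u[i] + 2.0 * k2u[i] + 2.0 * k3u[i] + k4u[i]);
    }

    if (delayed) {
      // slot of t_{k-kd} is no longer needed; t_{k+1} lands exactly there
      // because (k + 1 + k_delay) mod nslot == k mod nslot
      const int snew = k % nslot;
      for (int i = 0; i < M; ++i) buf[(size_t)snew * M + i] = N[i];
    }

    bool bad = false;
    for (int i = 0; i < M; ++i) {
      if (!std::isfinite(N[i]) || !std::isfinite(u[i])) { status = 2; bad = true; break; }
      if (N[i] > cap || u[i] > cap) { status = 1; bad = true; break; }
    }
    if (bad) { stop_step = k + 1; break; }

    if ((k + 1) % save_every == 0) {
      for (int i = 0; i < M; ++i) { Nout(i, isave) = N[i]; uout(i, isave) = u[i]; }
      tout[isave] = (k + 1) * dt;
      ++isave;
    }
  }

  return List::create(_["t"] = tout, _["N"] = Nout, _["u"] = uout,
                      _["status"] = status, _["stop_step"] = stop_step,
                      _["n_saved"] = isave);
}
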