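// Time-stepped ALIF network simulation and hand-derived BPTT adjoints.
//
// State convention (per unit): membrane potential v, adaptation trace a.
// At step t (1-based in R, 0-based here):
//   v[t] = Em + alpha*(v[t-1]-Em) + Wrec^T z[t-1] + Win^T x[t] - z[t-1]*(vth-Em)
//   A[t] = vth + beta*a[t],  a[t] = rho*a[t-1] + z[t-1]   (adaptation trace
//          entering the threshold at t)
//   z[t] = H(v[t]-A[t]), forced 0 for t_refrac steps after a spike
// The readout is y[t] = Wout^T z[t] with no nonlinearity.
//
// Gradients: the Heaviside derivative is replaced by the pseudo-derivative
//   psi = (gamma/v_eff) * max(0, 1 - |v-A|/v_eff),  psi = 0 in refractory.
// Reverse-mode adjoints (lv = dE/dv, la = dE/da, lz = dE/dz):
//   lz[t] = Wout*dY[t] + rate-loss term + Wrec*lv[t+1] - (vth-Em)*lv[t+1]
//           + la[t+1]
//   lv[t] = psi[t]*lz[t] + alpha*lv[t+1]
//   la[t] = -beta*psi[t]*lz[t] + rho*la[t+1]
// Weight gradients reduce to three GEMMs over the stored trajectories.
//
// `soft = true` replaces the hard spike by the continuous pseudo-spike
// whose exact derivative is psi (refractoriness disabled); this makes the
// whole graph differentiable so the adjoint code can be checked against
// central finite differences.
//
// Inner loops run over raw column memory: trials are thousands of steps
// and the per-step work is tiny, so allocation-free code matters more
// than BLAS here. Spikes are binary and sparse, so recurrent input is
// accumulated over the spiking units only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Pars {
  double Em, vth, alpha, rho, beta, gamma_pd, v_eff, reset;
  int t_refrac;
  bool leak_to_rest;
};

Pars parse_pars(const List& p) {
  Pars q;
  q.Em = as<double>(p["E_m"]);
  q.vth = as<double>(p["v_th"]);
  q.alpha = as<double>(p["alpha"]);
  q.rho = as<double>(p["rho"]);
  q.beta = as<double>(p["beta"]);
  q.gamma_pd = as<double>(p["gamma_pd"]);
  q.v_eff = as<double>(p["v_eff"]);
  q.reset = q.vth - q.Em;
  q.t_refrac = as<int>(p["t_refrac"]);
  q.leak_to_rest = as<bool>(p["leak_to_rest"]);
  return q;
}

inline double soft_spike(double u, double gamma_pd, double v_eff) {
  // antiderivative of the pseudo-derivative; ranges 0 -> gamma_pd
  if (u <= -v_eff) return 0.0;
  if (u >= v_eff) return gamma_pd;
  double g = gamma_pd / v_eff;
  if (u <= 0.0) return g * (u + u * u / (2.0 * v_eff) + v_eff / 2.0);
  return gamma_pd / 2.0 + g * (u - u * u / (2.0 * v_eff));
}

// Shared forward pass; fills Z, PSI, Y (and V, A when requested).
void forward_pass(const arma::mat& WinT,   // N x C
                  const arma::mat& WrecT,  // N x N, col j = outgoing of j
                  const arma::mat& Wout,   // N x K
                  const arma::mat& x,      // C x T
                  const arma::vec& v_init, const Pars& q, bool soft,
                  arma::mat& Z, arma::mat& PSI, arma::mat& Y,
                  arma::mat* Vout, arma::mat* Aout) {
  const arma::uword N = WrecT.n_rows, T = x.n_cols, C = x.n_rows;
  const arma::uword K = Wout.n_cols;
  arma::vec v = v_init, a(N, arma::fill::zeros), zprev(N, arma::fill::zeros);
  arma::vec I(N);
  arma::ivec refrac(N, arma::fill::zeros);
  double* vp = v.memptr();
  double* ap = a.memptr();
  double* zp = zprev.memptr();
  double* Ip = I.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    I.zeros();
    if (soft) {
      for (arma::uword j = 0; j < N; ++j) {
        if (zp[j] != 0.0) {
          const double zj = zp[j];
          const double* col = WrecT.colptr(j);
          for (arma::uword i = 0; i < N; ++i) Ip[i] += zj * col[i];
        }
      }
    } else {
      for (arma::uword j = 0; j < N; ++j) {
        if (zp[j] != 0.0) {
          const double* col = WrecT.colptr(j);
          for (arma::uword i = 0; i < N; ++i) Ip[i] += col[i];
        }
      }
    }
    const double* xc = x.colptr(t);
    for (arma::uword c = 0; c < C; ++c) {
      if (xc[c] != 0.0) {
        const double xcv = xc[c];
        const double* col = WinT.colptr(c);
        for (arma::uword i = 0; i < N; ++i) Ip[i] += xcv * col[i];
      }
    }
    double* Zc = Z.colptr(t);
    double* Pc = PSI.colptr(t);
    for (arma::uword i = 0; i < N; ++i) {
      double vi = q.leak_to_rest
                      ? q.Em + q.alpha * (vp[i] - q.Em) + Ip[i] -
                            zp[i] * q.reset
                      : q.alpha * vp[i] + Ip[i] - zp[i] * q.reset;
      double a_thr = q.rho * ap[i] + zp[i];
      double A = q.vth + q.beta * a_thr;
      double u = vi - A;
      double zi;
      if (!soft && refrac[i] > 0) {
        zi = 0.0;
        Pc[i] = 0.0;
        refrac[i] -= 1;
      } else {
        if (soft) {
          zi = soft_spike(u, q.gamma_pd, q.v_eff);
        } else {
          zi = (u > 0.0) ? 1.0 : 0.0;
          if (zi == 1.0) refrac[i] = q.t_refrac;
        }
        double h = 1.0 - std::abs(u) / q.v_eff;
        Pc[i] = (h > 0.0) ? (q.gamma_pd / q.v_eff) * h : 0.0;
      }
      vp[i] = vi;
      ap[i] = a_thr;
      Zc[i] = zi;
      if (Vout) (*Vout)(i, t) = vi;
      if (Aout) (*Aout)(i, t) = A;
    }
    std::memcpy(zp, Zc, N * sizeof(double));
  }
  Y = Wout.t() * Z;
  (void)K;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(const arma::mat& Win, const arma::mat& Wrec,
                  const arma::mat& Wout, const arma::mat& x,
                  const arma::vec& v_init, List pars, bool soft = false,
                  bool record_state = false) {
  Pars q = parse_pars(pars);
  const arma::uword N = Wrec.n_rows, T = x.n_cols;
  arma::mat WrecT = Wrec.t(), WinT = Win.t();
  arma::mat Z(N, T), PSI(N, T), Y;
  arma::mat V, A;
  if (record_state) { V.set_size(N, T); A.set_size(N, T); }
  forward_pass(WinT, WrecT, Wout, x, v_init, q, soft, Z, PSI, Y,
               record_state ? &V : nullptr, record_state ? &A : nullptr);
  List out = List::create(_["z"] = Z, _["y"] = Y,
                          _["rate"] = arma::accu(Z) / (double)(N * T));
  if (record_state) { out["v"] = V; out["A"] = A; }
  return out;
}

// [[Rcpp::export(name = ".cpp_bptt")]]
List cpp_bptt(const arma::mat& Win, const arma::mat& Wrec,
              const arma::mat& Wout, const arma::mat& x,
              const arma::vec& v_init, const arma::mat& target, List pars,
              double w_task, double w_rate, double lambda_rate,
              double rate_target, bool soft = false) {
  Pars q = parse_pars(pars);
  const arma::uword N = Wrec.n_rows, T = x.n_cols, K = Wout.n_cols;
  arma::mat WrecT = Wrec.t(), WinT = Win.t();
  arma::mat Z(N, T), PSI(N, T), Y;
  forward_pass(WinT, WrecT, Wout, x, v_init, q, soft, Z, PSI, Y, nullptr,
               nullptr);

  double E_task = arma::accu(arma::square(Y - target)) / (double)(K * T);
  double rbar = arma::accu(Z) / (double)(N * T);
  double E_rate = (rbar - rate_target) * (rbar - rate_target);
  double loss = w_task * E_task + w_rate * lambda_rate * E_rate;

  arma::mat dY = (2.0 * w_task / (double)(K * T)) * (Y - target);  // K x T
  const double rate_coef =
      w_rate * lambda_rate * 2.0 * (rbar - rate_target) / (double)(N * T);

  arma::mat LV(N, T);
  arma::vec lz(N), lv_next(N, arma::fill::zeros),
      la_next(N, arma::fill::zeros);
  double* lzp = lz.memptr();
  double* lvn = lv_next.memptr();
  double* lan = la_next.memptr();
  for (arma::uword tt = T; tt-- > 0;) {
    // direct term: readout and rate loss
    const double* dYc = dY.colptr(tt);
    for (arma::uword i = 0; i < N; ++i) {
      double s = rate_coef;
      for (arma::uword k = 0; k < K; ++k) s += Wout(i, k) * dYc[k];
      lzp[i] = s;
    }
    if (tt + 1 < T) {
      // z[t] feeds v[t+1] through the recurrent weights and the reset,
      // and a[t+1] through the adaptation increment
      for (arma::uword i = 0; i < N; ++i) {
        const double* row = WrecT.colptr(i);  // WrecT col i = Wrec row i
        double s = 0.0;
        for (arma::uword jj = 0; jj < N; ++jj) s += row[jj] * lvn[jj];
        lzp[i] += s - q.reset * lvn[i] + lan[i];
      }
    }
    const double* Pc = PSI.colptr(tt);
    double* LVc = LV.colptr(tt);
    for (arma::uword i = 0; i < N; ++i) {
      double pl = Pc[i] * lzp[i];
      double lv = pl + q.alpha * lvn[i];
      double la = -q.beta * pl + q.rho * lan[i];
      LVc[i] = lv;
      lvn[i] = lv;
      lan[i] = la;
    }
  }

  arma::mat dWrec(N, N, arma::fill::zeros);
  if (T > 1)
    dWrec = Z.cols(0, T - 2) * LV.cols(1, T - 1).t();
  arma::mat dWin = x * LV.t();   // C x N
  arma::mat dWout = Z * dY.t();  // N x K

  return List::create(
      _["E_task"] = E_task, _["E_rate"] = E_rate, _["loss"] = loss,
      _["rate"] = rbar, _["dW_in"] = dWin, _["dW_rec"] = dWrec,
      _["dW_out"] = dWout, _["y"] = Y, _["spike_count"] = arma::accu(Z));
}
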