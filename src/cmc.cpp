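// Fixed-step RK4 integration of the canonical-microcircuit network with
// conduction delays resolved by linear interpolation into the state
// history on the integration grid.  Mirrors the reference R integrator.
//
// Hot path: allocation-free inner loops (the integrator is called a few
// hundred times per model fit through finite-difference Jacobians).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// state columns: v_ss, i_ss, v_sp, i_sp, v_ii, i_ii, v_dp, i_dp
// gi columns:    ss_ss, sp_ss, ii_ss, ii_ii, ss_ii, dp_ii, sp_sp, ss_sp,
//                ii_dp, dp_dp  (sp_sp already includes exp(G) scaling)

static inline double sig(double v, double slope, double smax) {
  return smax * (1.0 / (1.0 + std::exp(-slope * v)) - 0.5);
}

struct CmcSys {
  const mat &AFss, &AFdp, &ABsp, &ABii, &gi;
  const vec &C, &tau;
  double slope, smax;
  int n;

  // dx <- f(Y; delayed Yi, Ye, input u_t); all buffers n x 8 / n x 4
  void deriv(const mat& Y, const mat& Yi, const mat& Ye, double u_t,
             mat& Si, mat& Se, mat& dx) const {
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < 4; ++p) {
        Si(i, p) = sig(Yi(i, 2 * p), slope, smax);
        Se(i, p) = sig(Ye(i, 2 * p), slope, smax);
      }
    for (int i = 0; i < n; ++i) {
      double fwd_ss = 0.0, fwd_dp = 0.0, bwd_sp = 0.0, bwd_ii = 0.0;
      for (int j = 0; j < n; ++j) {
        fwd_ss += AFss(i, j) * Se(j, 1);
        fwd_dp += AFdp(i, j) * Se(j, 1);
        bwd_sp += ABsp(i, j) * Se(j, 3);
        bwd_ii += ABii(i, j) * Se(j, 3);
      }
      double U[4];
      U[0] = gi(i, 0) * Si(i, 0) + gi(i, 1) * Si(i, 1) + gi(i, 2) * Si(i, 2) +
             fwd_ss + C(i) * u_t;
      U[1] = gi(i, 6) * Si(i, 1) + gi(i, 7) * Si(i, 0) + bwd_sp;
      U[2] = gi(i, 3) * Si(i, 2) + gi(i, 4) * Si(i, 0) + gi(i, 5) * Si(i, 3) +
             bwd_ii;
      U[3] = gi(i, 8) * Si(i, 2) + gi(i, 9) * Si(i, 3) + fwd_dp;
      for (int p = 0; p < 4; ++p) {
        dx(i, 2 * p) = Y(i, 2 * p + 1);
        dx(i, 2 * p + 1) =
          (U[p] - 2.0 * Y(i, 2 * p + 1) - Y(i, 2 * p) / tau(p)) / tau(p);
      }
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cmc_integrate_cpp(const arma::mat& AFss, const arma::mat& AFdp,
                             const arma::mat& ABsp, const arma::mat& ABii,
                             const arma::mat& gi, const arma::vec& C,
                             const arma::vec& tau, double slope, double smax,
                             const arma::vec& u, double h, double d_intr,
                             double d_extr, int n_steps, bool full_state,
                             double bound) {
  const int n = AFss.n_rows;
  CmcSys sys{AFss, AFdp, ABsp, ABii, gi, C, tau, slope, smax, n};

  // history of states on the grid; column k = flattened n x 8 state
  mat hist(n * 8, n_steps + 1, fill::zeros);
  mat vsp(n_steps + 1, n, fill::zeros);
  bool diverged = false;
  double maxnorm = 0.0;

  mat Y(n, 8, fill::zeros), Ys(n, 8), Yi(n, 8), Ye(n, 8);
  mat Si(n, 4), Se(n, 4);
  mat k1(n, 8), k2(n, 8), k3(n, 8), k4(n, 8);

  auto delayed = [&](double k_frac, mat& out) {
    if (k_frac <= 0.0) { out.zeros(); return; }
    int lo = (int)std::floor(k_frac);
    double w = k_frac - lo;
    const double* a = hist.colptr(lo);
    if (w == 0.0) {
      std::copy(a, a + n * 8, out.memptr());
    } else {
      const double* b = hist.colptr(lo + 1);
      double* o = out.memptr();
      for (int q = 0; q < n * 8; ++q) o[q] = (1.0 - w) * a[q] + w * b[q];
    }
  };

  const double cc[4] = {0.0, 0.5, 0.5, 1.0};
  for (int k = 0; k < n_steps; ++k) {
    for (int s = 0; s < 4; ++s) {
      if (s == 0) Ys = Y;
      else if (s == 1) Ys = Y + (h * 0.5) * k1;
      else if (s == 2) Ys = Y + (h * 0.5) * k2;
      else Ys = Y + h * k3;
      delayed(k + cc[s] - d_intr, Yi);
      delayed(k + cc[s] - d_extr, Ye);
      double u_t = u((uword)(2 * k + (int)(2 * cc[s])));
      mat& dst = (s == 0) ? k1 : (s == 1) ? k2 : (s == 2) ? k3 : k4;
      sys.deriv(Ys, Yi, Ye, u_t, Si, Se, dst);
    }
    Y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    double m = abs(Y).max();
    if (m > maxnorm) maxnorm = m;
    if (!Y.is_finite() || maxnorm > bound) { diverged = true; break; }
    std::copy(Y.memptr(), Y.memptr() + n * 8, hist.colptr(k + 1));
    vsp.row(k + 1) = Y.col(2).t();
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("vsp") = vsp,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("maxnorm") = maxnorm);
  if (full_state) {
    // (n_steps+1) x n x 8 array matching the R engine's layout
    cube X(n_steps + 1, n, 8);
    for (int k = 0; k <= n_steps; ++k)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 8; ++j)
          X(k, i, j) = hist(i + n * j, k);
    out["X"] = X;
  } else {
    out["X"] = R_NilValue;
  }
  return out;
}
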