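#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled extinction/data ODEs of the binary-state speciation-extinction
// model. y = (E0, E1, D0, D1); pars = (la0, la1, mu0, mu1, q01, q10).
static inline void bisse_rhs(const double *y, double *dy, const double *p) {
  const double la0 = p[0], la1 = p[1], mu0 = p[2], mu1 = p[3],
               q01 = p[4], q10 = p[5];
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = mu0 - (la0 + mu0 + q01) * E0 + q01 * E1 + la0 * E0 * E0;
  dy[1] = mu1 - (la1 + mu1 + q10) * E1 + q10 * E0 + la1 * E1 * E1;
  dy[2] = -(la0 + mu0 + q01) * D0 + q01 * D1 + 2.0 * la0 * E0 * D0;
  dy[3] = -(la1 + mu1 + q10) * D1 + q10 * D0 + 2.0 * la1 * E1 * D1;
}

// Cash-Karp embedded Runge-Kutta 4(5) step for the 4-dim system.
static inline void rkck_step(const double *y, const double *dydx, double h,
                             double *yout, double *yerr, const double *p) {
  static const double b21 = 0.2,
    b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
    b41 = 0.3, b42 = -0.9, b43 = 1.2,
    b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0,
    b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
    b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
    c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
    c6 = 512.0 / 1771.0,
    dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
    dc6 = c6 - 0.25;
  double ak2[4], ak3[4], ak4[4], ak5[4], ak6[4], ytemp[4];
  for (int i = 0; i < 4; ++i) ytemp[i] = y[i] + b21 * h * dydx[i];
  bisse_rhs(ytemp, ak2, p);
  for (int i = 0; i < 4; ++i)
    ytemp[i] = y[i] + h * (b31 * dydx[i] + b32 * ak2[i]);
  bisse_rhs(ytemp, ak3, p);
  for (int i = 0; i < 4; ++i)
    ytemp[i] = y[i] + h * (b41 * dydx[i] + b42 * ak2[i] + b43 * ak3[i]);
  bisse_rhs(ytemp, ak4, p);
  for (int i = 0; i < 4; ++i)
    ytemp[i] = y[i] + h * (b51 * dydx[i] + b52 * ak2[i] + b53 * ak3[i] +
                           b54 * ak4[i]);
  bisse_rhs(ytemp, ak5, p);
  for (int i = 0; i < 4; ++i)
    ytemp[i] = y[i] + h * (b61 * dydx[i] + b62 * ak2[i] + b63 * ak3[i] +
                           b64 * ak4[i] + b65 * ak5[i]);
  bisse_rhs(ytemp, ak6, p);
  for (int i = 0; i < 4; ++i) {
    yout[i] = y[i] + h * (c1 * dydx[i] + c3 * ak3[i] + c4 * ak4[i] +
                          c6 * ak6[i]);
    yerr[i] = h * (dc1 * dydx[i] + dc3 * ak3[i] + dc4 * ak4[i] +
                   dc5 * ak5[i] + dc6 * ak6[i]);
  }
}

// Integrate the system over a branch of length len with adaptive stepping
// (abs/rel tolerance `tol`). Returns false on numerical failure.
static bool integrate_branch(double *y, double len, const double *p,
                             double tol) {
  if (len <= 0.0) return true;
  double t = 0.0;
  double rate = 0.0;
  for (int i = 0; i < 6; ++i) rate = std::max(rate, p[i]);
  double h = std::min(len, rate > 0 ? 0.1 / rate : len);
  double dydx[4], ytmp[4], yerr[4];
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) return false;
    if (t + h > len) h = len - t;
    bisse_rhs(y, dydx, p);
    rkck_step(y, dydx, h, ytmp, yerr, p);
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      double sc = tol + tol * std::fabs(y[i]);
      errmax = std::max(errmax, std::fabs(yerr[i]) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ytmp[i];
      // clamp E into [0,1] and D to >= 0 against roundoff
      for (int i = 0; i < 2; ++i)
        y[i] = std::min(1.0, std::max(0.0, y[i]));
      for (int i = 2; i < 4; ++i) y[i] = std::max(0.0, y[i]);
      h *= std::min(5.0, 0.9 * std::pow(errmax > 1e-12 ? errmax : 1e-12,
                                        -0.2));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[2]) ||
        !std::isfinite(y[3]) || h < 1e-14 * len)
      return false;
  }
  return true;
}

// [[Rcpp::export]]
double bisse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                        int n_tip, IntegerVector tip_state,
                        NumericVector pars, int root_type,
                        NumericVector root_p, bool condition_survival,
                        double tol) {
  const int n_node = edge.nrow() + 1;      // total nodes in the tree
  const double *p = REAL(pars);
  std::vector<double> E0(n_node + 1, 0.0), E1(n_node + 1, 0.0);
  std::vector<double> D0(n_node + 1, 0.0), D1(n_node + 1, 0.0);
  std::vector<int> seen(n_node + 1, 0);
  double logcomp = 0.0;

  for (int i = 1; i <= n_tip; ++i) {
    int s = tip_state[i - 1];
    if (s == 0) { D0[i] = 1.0; }
    else if (s == 1) { D1[i] = 1.0; }
    else { D0[i] = 1.0; D1[i] = 1.0; }   // unknown state
  }

  int root = -1;
  for (int k = 0; k < edge.nrow(); ++k) {       // edges in postorder
    const int par = edge(k, 0), ch = edge(k, 1);
    double y[4] = { E0[ch], E1[ch], D0[ch], D1[ch] };
    if (!integrate_branch(y, edge_length[k], p, tol))
      return R_NegInf;
    if (seen[par] == 0) {
      E0[par] = y[0]; E1[par] = y[1];
      D0[par] = y[2]; D1[par] = y[3];
    } else {
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
      D0[par] = D0[par] * y[2] * p[0];
      D1[par] = D1[par] * y[3] * p[1];
    }
    seen[par] += 1;
    double s = D0[par] + D1[par];
    if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
    D0[par] /= s; D1[par] /= s;
    logcomp += std::log(s);
    root = par;
  }
  // identify the root: the node that never appears as a child
  std::vector<bool> is_child(n_node + 1, false);
  for (int k = 0; k < edge.nrow(); ++k) is_child[edge(k, 1)] = true;
  for (int v = n_tip + 1; v <= n_node; ++v)
    if (seen[v] > 0 && !is_child[v]) { root = v; break; }

  double d0 = D0[root], d1 = D1[root];
  double w0, w1;
  if (root_type == 0) {            // weighted by conditional likelihood
    double s = d0 + d1;
    w0 = d0 / s; w1 = d1 / s;
  } else if (root_type == 1) {     // equal weights
    w0 = 0.5; w1 = 0.5;
  } else {                         // user-supplied
    w0 = root_p[0]; w1 = root_p[1];
  }
  double lik = w0 * d0 + w1 * d1;
  if (condition_survival) {
    double e0 = E0[root], e1 = E1[root];
    double cond = w0 * p[0] * (1 - e0) * (1 - e0) +
                  w1 * p[1] * (1 - e1) * (1 - e1);
    if (cond <= 0.0) return R_NegInf;
    lik /= cond;
  }
  if (lik <= 0.0 || !std::isfinite(lik)) return R_NegInf;
  return std::log(lik) + logcomp;
}
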