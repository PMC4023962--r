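// Binary-state speciation-extinction (BiSSE) ODE core.
//
// State vector y = (E0, E1, D0, D1): E_i is the probability that a lineage
// in state i at age t leaves no sampled descendants at the present; D_i is
// the likelihood density of the observed subtree given a lineage in state i.
// Integration runs backward in time (present -> root) over each branch:
//
//   E_i' = mu_i - (lambda_i + mu_i + q_ij) E_i + q_ij E_j + lambda_i E_i^2
//   D_i' = -(lambda_i + mu_i + q_ij) D_i + q_ij D_j + 2 lambda_i E_i D_i
//
// integrated with an adaptive Dormand-Prince 5(4) scheme.  D is
// renormalized whenever it underflows, with the scaling accumulated as a
// log factor so the final log-likelihood is exact.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct BisseParams {
  double l0, l1, m0, m1, q01, q10;
};

inline void derivs(const BisseParams& p, const double* y, double* dy) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.m0 - (p.l0 + p.m0 + p.q01) * E0 + p.q01 * E1 + p.l0 * E0 * E0;
  dy[1] = p.m1 - (p.l1 + p.m1 + p.q10) * E1 + p.q10 * E0 + p.l1 * E1 * E1;
  dy[2] = -(p.l0 + p.m0 + p.q01) * D0 + p.q01 * D1 + 2.0 * p.l0 * E0 * D0;
  dy[3] = -(p.l1 + p.m1 + p.q10) * D1 + p.q10 * D0 + 2.0 * p.l1 * E1 * D1;
}

// Dormand-Prince 5(4) tableau
const double A21 = 1.0 / 5.0;
const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
             A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
             A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
             A65 = -5103.0 / 18656.0;
const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
             B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
const double E1c = 71.0 / 57600.0, E3c = -71.0 / 16695.0, E4c = 71.0 / 1920.0,
             E5c = -17253.0 / 339200.0, E6c = 22.0 / 525.0, E7c = -1.0 / 40.0;

// integrate y over duration `len`; returns accumulated log scaling of D
double integrate_branch(const BisseParams& p, double* y, double len,
                        double rtol, double atol) {
  if (len <= 0.0) return 0.0;
  double logfac = 0.0;
  double t = 0.0;
  // cap the step by the kinetic scale: beyond h ~ 1/rate the embedded
  // error estimate is untrustworthy even when it reads small
  const double rate_scale = p.l0 + p.l1 + p.m0 + p.m1 + p.q01 + p.q10;
  const double hmax = (rate_scale > 0.0) ? 1.0 / rate_scale : len;
  double h = len / 10.0;
  if (h > hmax) h = hmax;
  if (h <= 0.0) h = len;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4], y5[4];
  derivs(p, y, k1);  // FSAL
  long steps = 0;
  const long max_steps = 10000000L;
  while (t < len) {
    if (++steps > max_steps)
      stop("BiSSE ODE integration failed: step limit reached");
    if (h > len - t) h = len - t;
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * A21 * k1[i];
    derivs(p, yt, k2);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    derivs(p, yt, k3);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    derivs(p, yt, k4);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                          A54 * k4[i]);
    derivs(p, yt, k5);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                          A64 * k4[i] + A65 * k5[i]);
    derivs(p, yt, k6);
    for (int i = 0; i < 4; ++i)
      y5[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                          B5 * k5[i] + B6 * k6[i]);
    derivs(p, y5, k7);
    double err = 0.0;
    for (int i = 0; i < 4; ++i) {
      double e = h * (E1c * k1[i] + E3c * k3[i] + E4c * k4[i] +
                      E5c * k5[i] + E6c * k6[i] + E7c * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / 4.0);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      // clamp tiny numerical excursions of the probabilities E
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
      }
      double m = std::max(y[2], y[3]);
      if (m > 0.0 && (m < 1e-50 || m > 1e50)) {
        y[2] /= m; y[3] /= m;
        logfac += std::log(m);
        derivs(p, y, k1);
      }
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h > hmax) h = hmax;
    if (!(h > 0.0) || !std::isfinite(h))
      stop("BiSSE ODE integration failed: step size underflow");
  }
  return logfac;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".bisse_branch_cpp")]]
List bisse_branch_cpp(NumericVector y, NumericVector pars, double len,
                      double rtol = 1e-8, double atol = 1e-10) {
  if (y.size() != 4) stop("state vector must have length 4");
  if (pars.size() != 6) stop("parameter vector must have length 6");
  BisseParams p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  double yy[4] = {y[0], y[1], y[2], y[3]};
  double logfac = integrate_branch(p, yy, len, rtol, atol);
  return List::create(_["y"] = NumericVector::create(yy[0], yy[1], yy[2],
                                                     yy[3]),
                      _["logfac"] = logfac);
}

// Post-order likelihood pass.  `edge` must be in ape postorder; node ids
// are 1-based as in a phylo object (tips 1..ntip, root ntip+1).  `tip_init`
// is an ntip x 4 matrix of (E0, E1, D0, D1) initial conditions and
// `tip_logfac` the per-tip log scaling already accumulated (e.g. by an
// unresolved-clade initializer).  Tips flagged in `skip_branch` carry
// values already propagated to their parent end, so their pendant branch is
// not integrated again.  At each internal node the children are combined as
// D_i <- lambda_i * D_i(left) * D_i(right); the root combination also
// includes the lambda factor.
//' @noRd
// [[Rcpp::export(name = ".bisse_postorder_cpp")]]
List bisse_postorder_cpp(int ntip, int nnode, IntegerMatrix edge,
                         NumericVector edge_len, NumericMatrix tip_init,
                         NumericVector tip_logfac, LogicalVector skip_branch,
                         NumericVector pars, double rtol = 1e-8,
                         double atol = 1e-10) {
  if (pars.size() != 6) stop("parameter vector must have length 6");
  BisseParams p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  const int ntot = ntip + nnode;
  std::vector<double> E0(ntot, 0.0), E1(ntot, 0.0), D0(ntot, 1.0),
      D1(ntot, 1.0), lf(ntot, 0.0);
  std::vector<char> visited(ntot, 0);
  const int ne = edge.nrow();
  for (int k = 0; k < ne; ++k) {
    const int par = edge(k, 0) - 1;
    const int ch = edge(k, 1) - 1;
    double y[4];
    double logfac;
    if (ch < ntip) {
      y[0] = tip_init(ch, 0); y[1] = tip_init(ch, 1);
      y[2] = tip_init(ch, 2); y[3] = tip_init(ch, 3);
      logfac = tip_logfac[ch];
      if (!skip_branch[ch])
        logfac += integrate_branch(p, y, edge_len[k], rtol, atol);
    } else {
      // internal child: apply the speciation factor at the node, then
      // integrate its subtending branch
      y[0] = E0[ch]; y[1] = E1[ch];
      y[2] = p.l0 * D0[ch]; y[3] = p.l1 * D1[ch];
      logfac = lf[ch];
      logfac += integrate_branch(p, y, edge_len[k], rtol, atol);
    }
    double m = std::max(y[2], y[3]);
    if (!(m > 0.0))
      stop("all-zero state likelihoods on a branch: numerical failure or "
           "impossible data");
    y[2] /= m; y[3] /= m;
    logfac += std::log(m);
    if (!visited[par]) {
      E0[par] = y[0]; E1[par] = y[1];
      D0[par] = y[2]; D1[par] = y[3];
      lf[par] = logfac;
      visited[par] = 1;
    } else {
      D0[par] *= y[2]; D1[par] *= y[3];
      lf[par] += logfac;
      // E along sibling branches agrees analytically; keep the first copy
    }
  }
  const int root = ntip;  // 0-based index of node ntip+1
  double d0 = p.l0 * D0[root], d1 = p.l1 * D1[root];
  return List::create(_["E"] = NumericVector::create(E0[root], E1[root]),
                      _["D"] = NumericVector::create(d0, d1),
                      _["logfac"] = lf[root]);
}
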