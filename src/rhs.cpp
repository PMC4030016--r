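#include <Rcpp.h>
using namespace Rcpp;

// Reaction-network right-hand side.
//
// State amounts are clamped at zero before rate evaluation so that a tiny
// integrator undershoot cannot inject mass through a negative concentration.
// Law codes: 1 = mass action, 2 = Michaelis-Menten (first reactant is the
// substrate; remaining reactants enter mass-action style), 3 = Hill.
// Modifier factors (per modifier, role +1 activator / -1 inhibitor, with the
// reaction's hill exponent n and half-effect constant Km):
//   activator:  strength * A^n / (Km^n + A^n)
//   inhibitor:  1 / (1 + (strength * I / Km)^n)
// Km >> operating level makes a coupling effectively linear (share-
// preserving); Km near the operating level makes it saturable.
// All CSR pointer vectors are 0-based.

// [[Rcpp::export(name = ".network_rhs_cpp")]]
NumericVector network_rhs_cpp(NumericVector y,
                              IntegerVector law,
                              NumericVector k,
                              NumericVector Km,
                              NumericVector hn,
                              NumericVector scale,
                              IntegerVector ra_ptr, IntegerVector ra_idx, NumericVector ra_st,
                              IntegerVector pr_ptr, IntegerVector pr_idx, NumericVector pr_st,
                              IntegerVector mo_ptr, IntegerVector mo_idx,
                              IntegerVector mo_role, NumericVector mo_str,
                              NumericVector syn, NumericVector deg) {
  const int n = y.size();
  const int m = law.size();
  NumericVector dy(n);
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) {
    const double v = y[i];
    x[i] = (v > 0.0) ? v : 0.0;
    dy[i] = syn[i] - deg[i] * x[i];
  }
  for (int r = 0; r < m; ++r) {
    double rate = k[r] * scale[r];
    if (rate <= 0.0) continue;
    const int rlo = ra_ptr[r], rhi = ra_ptr[r + 1];
    if (law[r] == 1) {
      for (int j = rlo; j < rhi; ++j) {
        const double s = x[ra_idx[j]];
        const double st = ra_st[j];
        rate *= (st == 1.0) ? s : std::pow(s, st);
      }
    } else if (rlo < rhi) {
      const double s = x[ra_idx[rlo]];
      if (law[r] == 2) {
        rate *= s / (Km[r] + s);
      } else {
        const double sn = std::pow(s, hn[r]);
        rate *= sn / (std::pow(Km[r], hn[r]) + sn);
      }
      for (int j = rlo + 1; j < rhi; ++j) {
        const double s2 = x[ra_idx[j]];
        const double st = ra_st[j];
        rate *= (st == 1.0) ? s2 : std::pow(s2, st);
      }
    }
    for (int j = mo_ptr[r]; j < mo_ptr[r + 1]; ++j) {
      const double a = x[mo_idx[j]];
      const double nH = hn[r];
      if (mo_role[j] == 1) {
        const double an = (nH == 1.0) ? a : std::pow(a, nH);
        const double kn = (nH == 1.0) ? Km[r] : std::pow(Km[r], nH);
        rate *= mo_str[j] * an / (kn + an);
      } else {
        const double t = mo_str[j] * a / Km[r];
        const double tn = (nH == 1.0) ? t : std::pow(t, nH);
        rate *= 1.0 / (1.0 + tn);
      }
      if (rate <= 0.0) break;
    }
    if (rate <= 0.0) continue;
    for (int j = rlo; j < rhi; ++j) dy[ra_idx[j]] -= ra_st[j] * rate;
    for (int j = pr_ptr[r]; j < pr_ptr[r + 1]; ++j) dy[pr_idx[j]] += pr_st[j] * rate;
  }
  return dy;
}
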