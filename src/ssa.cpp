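#include <Rcpp.h>
using namespace Rcpp;

// Direct-method SSA kernel for the fixed nine-reaction p53-Mdm2 network.
// Species order: mdm2_mrna, mdm2, p53_mrna, p53. Uses R's RNG, so a prior
// set.seed() in R fixes the trajectory. Records the piecewise-constant
// state at the supplied time grid.
// [[Rcpp::export(name = ".ssa_mech_cpp")]]
NumericMatrix ssa_mech_cpp(NumericVector par, double omega,
                           NumericVector init, double t_end,
                           NumericVector record_times, double max_events) {
  const double b1 = par[0], b2 = par[1], b3 = par[2], b4 = par[3];
  const double a1 = par[4], a2 = par[5], a3 = par[6], a4 = par[7];
  const double n = par[8], K1 = par[9] * omega, K2 = par[10] * omega;
  const double g = par[11];
  double x1 = init[0], x2 = init[1], x3 = init[2], x4 = init[3];
  const int nr = record_times.size();
  NumericMatrix out(nr, 4);
  int gi = 0;
  double t = 0, ev = 0;
  const double K1n = pow(K1, n);
  double a[9];
  for (;;) {
    const double Pn = pow(x4, n);
    a[0] = omega * b1 * Pn / (K1n + Pn);
    a[1] = a1 * x1;
    a[2] = b2 * x1;
    a[3] = a2 * x2;
    a[4] = omega * b3;
    a[5] = a3 * x3;
    a[6] = b4 * x3;
    a[7] = a4 * x4;
    a[8] = g * x4 / (K2 + x4) * x2;
    double a0 = 0;
    for (int i = 0; i < 9; i++) a0 += a[i];
    const double t_next = (a0 <= 0) ? R_PosInf : t + R::exp_rand() / a0;
    const double horizon = (t_next < t_end ? t_next : t_end);
    while (gi < nr && record_times[gi] < horizon + 1e-15) {
      out(gi, 0) = x1; out(gi, 1) = x2; out(gi, 2) = x3; out(gi, 3) = x4;
      gi++;
    }
    if (t_next > t_end || ev >= max_events) break;
    t = t_next;
    const double u = unif_rand() * a0;
    double c = 0;
    int j = 0;
    for (; j < 8; j++) { c += a[j]; if (u < c) break; }
    switch (j) {
      case 0: x1++; break;
      case 1: x1--; break;
      case 2: x2++; break;
      case 3: x2--; break;
      case 4: x3++; break;
      case 5: x3--; break;
      case 6: x4++; break;
      case 7: x4--; break;
      default: x4--; break;  // j == 8: MM removal
    }
    ev++;
  }
  while (gi < nr) {
    out(gi, 0) = x1; out(gi, 1) = x2; out(gi, 2) = x3; out(gi, 3) = x4;
    gi++;
  }
  return out;
}
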