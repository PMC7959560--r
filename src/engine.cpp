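#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a trial sequence under the hybrid
// model-free/model-based learner, canonical 9-parameter encoding:
// (alpha_pain, alpha_nopain, beta1, beta2, lambda,
//  rho_self, rho_other, omega_self, omega_other).
// Trial matrix columns: choice1, state2, choice2 (1-based), outcome (0/1),
// recipient (1 self / 2 other), block. Mirrors the R reference path
// exactly; q-values start at 0.5, prev-choice resets at block changes.
// [[Rcpp::export]]
double nll_canonical_cpp(IntegerMatrix trials, NumericVector par,
                         double p_common, bool reset_values) {
  const double ap = par[0], an = par[1], b1 = par[2], b2 = par[3],
               lam = par[4];
  const double rho[2] = {par[5], par[6]};
  const double omg[2] = {par[7], par[8]};
  double q2[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  double q1[2] = {0.5, 0.5};
  int prev = -1, cur_block = INT_MIN;
  double ll = 0.0;
  const int n = trials.nrow();
  for (int i = 0; i < n; ++i) {
    const int c1 = trials(i, 0) - 1, s2 = trials(i, 1) - 1,
              c2 = trials(i, 2) - 1, out = trials(i, 3),
              rec = trials(i, 4) - 1, blk = trials(i, 5);
    if (blk != cur_block) {
      cur_block = blk;
      prev = -1;
      if (reset_values) {
        q2[0][0] = q2[0][1] = q2[1][0] = q2[1][1] = 0.5;
        q1[0] = q1[1] = 0.5;
      }
    }
    const double m0 = std::max(q2[0][0], q2[0][1]);
    const double m1 = std::max(q2[1][0], q2[1][1]);
    const double qmb0 = p_common * m0 + (1.0 - p_common) * m1;
    const double qmb1 = (1.0 - p_common) * m0 + p_common * m1;
    const double w = omg[rec], r = rho[rec];
    double l0 = b1 * (w * qmb0 + (1.0 - w) * q1[0]) + (prev == 0 ? r : 0.0);
    double l1 = b1 * (w * qmb1 + (1.0 - w) * q1[1]) + (prev == 1 ? r : 0.0);
    double mx = std::max(l0, l1);
    ll += (c1 == 0 ? l0 : l1) - mx -
          std::log(std::exp(l0 - mx) + std::exp(l1 - mx));
    const double s0 = b2 * q2[s2][0], s1 = b2 * q2[s2][1];
    mx = std::max(s0, s1);
    ll += (c2 == 0 ? s0 : s1) - mx -
          std::log(std::exp(s0 - mx) + std::exp(s1 - mx));
    const double astar = (out == 1) ? an : ap;
    const double q2_old = q2[s2][c2];
    q2[s2][c2] = q2_old + astar * (out - q2_old);
    q1[c1] += astar * (q2_old - q1[c1]) + astar * lam * (out - q2_old);
    prev = c1;
  }
  return -ll;
}
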