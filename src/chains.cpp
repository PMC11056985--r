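#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state Markov chain per hydrogen bond, discretized with the exact
// exponential transition probabilities 1 - exp(-k*dt) so that dwell
// statistics are unbiased at coarse frame intervals. Cooperativity
// multiplies k_form when at least one neighbouring bond was formed at the
// previous frame. Uses R's RNG stream: set.seed() on the R side makes runs
// bit-reproducible.
//
// init: 0 = all broken, 1 = all formed, 2 = stationary draw per bond using
// the independent-bond occupancy k_form/(k_form+k_break).
// [[Rcpp::export]]
IntegerMatrix simulate_hb_chain_cpp(int n_frames, int n_bonds,
                                    double k_form, double k_break,
                                    double cooperativity, double dt_us,
                                    int init) {
  IntegerMatrix states(n_frames, n_bonds);
  std::vector<int> cur(n_bonds), prev(n_bonds);
  RNGScope scope;

  double denom = k_form + k_break;
  double p_stat = denom > 0.0 ? k_form / denom : 1.0;
  for (int b = 0; b < n_bonds; ++b) {
    if (init == 0) cur[b] = 0;
    else if (init == 1) cur[b] = 1;
    else cur[b] = (unif_rand() < p_stat) ? 1 : 0;
  }

  const double p_break  = 1.0 - std::exp(-k_break * dt_us);
  const double p_form0  = 1.0 - std::exp(-k_form * dt_us);
  const double p_form1  = 1.0 - std::exp(-k_form * cooperativity * dt_us);
  const bool coop = (cooperativity != 1.0) && (n_bonds > 1);

  for (int t = 0; t < n_frames; ++t) {
    for (int b = 0; b < n_bonds; ++b) states(t, b) = cur[b];
    if (t == n_frames - 1) break;
    prev = cur;
    for (int b = 0; b < n_bonds; ++b) {
      double u = unif_rand();
      if (prev[b] == 1) {
        if (u < p_break) cur[b] = 0;
      } else {
        double pf = p_form0;
        if (coop) {
          bool neigh = (b > 0 && prev[b - 1] == 1) ||
                       (b + 1 < n_bonds && prev[b + 1] == 1);
          if (neigh) pf = p_form1;
        }
        if (u < pf) cur[b] = 1;
      }
    }
  }
  return states;
}
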