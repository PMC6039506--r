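#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method for a small mass-action network.
// reactants/changes: (reactions x species) stoichiometry matrices.
// Samples the state every `interval` time units after `burn_in`,
// using R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerMatrix reactants, IntegerMatrix changes,
                          NumericVector rates, IntegerVector init,
                          double burn_in, int n_samples, double interval) {
  const int n_re = reactants.nrow();
  const int n_sp = reactants.ncol();
  std::vector<long long> x(init.begin(), init.end());
  IntegerMatrix out(n_samples, n_sp);
  std::vector<double> a(n_re);

  double t = 0.0;
  double next_sample = burn_in;
  int recorded = 0;

  while (recorded < n_samples) {
    double a0 = 0.0;
    for (int r = 0; r < n_re; ++r) {
      double prop = rates[r];
      for (int j = 0; j < n_sp; ++j) {
        int s = reactants(r, j);
        for (int k = 0; k < s; ++k) prop *= (double)(x[j] - k);
      }
      if (prop < 0.0) prop = 0.0;
      a[r] = prop;
      a0 += prop;
    }
    if (a0 <= 0.0) {
      // absorbing state: record it for all remaining samples
      while (recorded < n_samples) {
        for (int j = 0; j < n_sp; ++j) out(recorded, j) = (int)x[j];
        ++recorded;
      }
      break;
    }
    double dt = R::exp_rand() / a0;
    double t_new = t + dt;
    while (recorded < n_samples && next_sample <= t_new) {
      for (int j = 0; j < n_sp; ++j) out(recorded, j) = (int)x[j];
      ++recorded;
      next_sample += interval;
    }
    t = t_new;
    double u = R::unif_rand() * a0;
    double cum = 0.0;
    int pick = n_re - 1;
    for (int r = 0; r < n_re; ++r) {
      cum += a[r];
      if (u <= cum) { pick = r; break; }
    }
    for (int j = 0; j < n_sp; ++j) x[j] += changes(pick, j);
  }
  return out;
}
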