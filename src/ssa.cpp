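#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time simulation (Gillespie) of a two-channel birth-death
// chain with state-indexed aggregate propensities. Uses R's RNG so that
// set.seed() in R governs reproducibility.
// [[Rcpp::export]]
List ssa_core(NumericVector birth, NumericVector death, int n0, double t_max,
              int max_events) {
  int n = n0;
  double t = 0.0;
  std::vector<double> times;
  std::vector<int> states;
  times.push_back(0.0);
  states.push_back(n);
  bool absorbed = false;
  while (true) {
    double tot = birth[n] + death[n];
    if (tot <= 0.0) {
      absorbed = true;
      break;
    }
    t += R::exp_rand() / tot;
    if (t > t_max) break;
    if (unif_rand() * tot < birth[n]) {
      n += 1;
    } else {
      n -= 1;
    }
    times.push_back(t);
    states.push_back(n);
    if ((int)times.size() >= max_events)
      stop("SSA event cap exceeded; raise max_events or lower t_max");
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["absorbed"] = absorbed);
}
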