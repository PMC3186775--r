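#include <Rcpp.h>
using namespace Rcpp;

// Event-level birth-death simulation on a lineage table.
//
// A lineage i is a row: parent[i] (0-based, NA for the origin), tb[i] = birth
// time, td[i] = death/split time (NA while alive).  A speciation closes the
// parent lineage (its td becomes the split time) and opens two child rows, so
// every row has 0 or 2 children and split times are recoverable as the td of
// rows that have children.  Times run forward from the origin (t = 0).
//
// Uses R's RNG (Rcpp attributes wrap calls in RNGScope), so set.seed() on the
// R side governs reproducibility.

// Advance all live lineages by `duration` under constant per-lineage rates.
// Stops early (status "capped") if the live count exceeds n_cap -- used by
// the rejection sampler to abandon proposals whose diversity has exploded.
// [[Rcpp::export]]
List bd_phase_cpp(IntegerVector parent0, NumericVector tb0, NumericVector td0,
                  double t0, double lambda, double mu, double duration,
                  int n_cap) {
  std::vector<int> parent(parent0.begin(), parent0.end());
  std::vector<double> tb(tb0.begin(), tb0.end());
  std::vector<double> td(td0.begin(), td0.end());
  std::vector<int> alive;
  for (int i = 0; i < (int)td.size(); ++i)
    if (ISNA(td[i])) alive.push_back(i);

  const double total = lambda + mu;
  const double t_end = t0 + duration;
  double t = t0;
  bool capped = false;

  if (total > 0.0) {
    while (!alive.empty()) {
      const double rate = total * (double)alive.size();
      t += R::rexp(1.0 / rate);
      if (t >= t_end) break;
      int j = (int)(unif_rand() * (double)alive.size());
      if (j >= (int)alive.size()) j = (int)alive.size() - 1;
      const int node = alive[j];
      if (unif_rand() * total < lambda) {
        td[node] = t;
        parent.push_back(node); tb.push_back(t); td.push_back(NA_REAL);
        parent.push_back(node); tb.push_back(t); td.push_back(NA_REAL);
        alive[j] = (int)parent.size() - 2;
        alive.push_back((int)parent.size() - 1);
        if ((int)alive.size() > n_cap) { capped = true; break; }
      } else {
        td[node] = t;
        alive[j] = alive.back();
        alive.pop_back();
      }
    }
  }

  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["t_birth"] = NumericVector(tb.begin(), tb.end()),
    _["t_death"] = NumericVector(td.begin(), td.end()),
    _["n_alive"] = (int)alive.size(),
    _["capped"] = capped);
}

// Grow a clade from a single origin lineage until the live count first
// reaches n_stop.  With complete_last = true the clock keeps running past the
// n_stop-th attainment until the *next* event would fire; that event is not
// executed and its time becomes the present, so the final internode interval
// is the full Exp(n_stop * (lambda + mu)) waiting time (the standard
// n-conditioned sample).  Returns status "extinct" if the clade dies first;
// the caller rejects and retries.
// [[Rcpp::export]]
List bd_grow_to_n_cpp(double lambda, double mu, int n_stop,
                      bool complete_last) {
  std::vector<int> parent(1, NA_INTEGER);
  std::vector<double> tb(1, 0.0);
  std::vector<double> td(1, NA_REAL);
  std::vector<int> alive(1, 0);

  const double total = lambda + mu;
  double t = 0.0;
  bool extinct = false;

  while (true) {
    if ((int)alive.size() >= n_stop) {
      if (complete_last)
        t += R::rexp(1.0 / (total * (double)alive.size()));
      break;
    }
    if (alive.empty()) { extinct = true; break; }
    const double rate = total * (double)alive.size();
    t += R::rexp(1.0 / rate);
    int j = (int)(unif_rand() * (double)alive.size());
    if (j >= (int)alive.size()) j = (int)alive.size() - 1;
    const int node = alive[j];
    if (unif_rand() * total < lambda) {
      td[node] = t;
      parent.push_back(node); tb.push_back(t); td.push_back(NA_REAL);
      parent.push_back(node); tb.push_back(t); td.push_back(NA_REAL);
      alive[j] = (int)parent.size() - 2;
      alive.push_back((int)parent.size() - 1);
    } else {
      td[node] = t;
      alive[j] = alive.back();
      alive.pop_back();
    }
  }

  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["t_birth"] = NumericVector(tb.begin(), tb.end()),
    _["t_death"] = NumericVector(td.begin(), td.end()),
    _["present_time"] = t,
    _["extinct"] = extinct);
}
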